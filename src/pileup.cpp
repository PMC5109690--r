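#include <Rcpp.h>
#include <cstdlib>
using namespace Rcpp;

// Decode SAMtools mpileup lines (single-sample dialect with per-base base
// quality, mapping quality and within-read position columns) into one
// observation per aligned read base.
//
// Column layout: CHROM POS REF DEPTH BASES BASE-QUALS MAP-QUALS READ-POS
// Quality strings are ASCII-33 phred; READ-POS is comma-separated 1-based
// integers, one per entry consumed from the quality strings.
//
// Grammar handled in the BASES column:
//   '^X'  read start; X encodes the read's mapping quality (consumed, the
//         following base gets is_start = TRUE)
//   '$'   read end marker attached to the preceding base
//   '+N<seq>' / '-N<seq>'  indel following a base (consumed, no allele)
//   '*'   deleted-base placeholder; '<' '>' reference skips -- each consumes
//         one entry of every per-base column but yields no observation
//   '.' ',' reference match on forward / reverse strand
//   'ACGTN' / 'acgtn'  mismatch on forward / reverse strand

static void parse_fail(int line_no, const char *col, const std::string &msg) {
  stop("mpileup parse error at line %d, column %s: %s", line_no, col, msg.c_str());
}

// strict non-negative integer parse; returns -1 on any non-digit content
static long parse_nonneg(const std::string &s) {
  if (s.empty() || s.size() > 10) return -1;
  long v = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') return -1;
    v = v * 10 + (s[i] - '0');
  }
  return v;
}

// [[Rcpp::export(name = ".cpp_parse_mpileup")]]
List cpp_parse_mpileup(CharacterVector lines) {
  int n = lines.size();

  std::vector<std::string> chrom(n);
  IntegerVector pos(n), depth(n), n_obs(n), n_skip(n);
  std::vector<std::string> ref(n);

  std::vector<int> o_site, o_bqv, o_mqv, o_rpos;
  std::vector<std::string> o_allele;
  std::vector<bool> o_fwd, o_start, o_end;

  for (int i = 0; i < n; ++i) {
    const char *raw = CHAR(STRING_ELT(lines, i));
    std::string line(raw);
    // split on tabs
    std::vector<std::string> f;
    size_t from = 0;
    while (true) {
      size_t tab = line.find('\t', from);
      if (tab == std::string::npos) { f.push_back(line.substr(from)); break; }
      f.push_back(line.substr(from, tab - from));
      from = tab + 1;
    }
    if (f.size() < 8)
      parse_fail(i + 1, "1-8", "expected >= 8 tab-separated columns, got " +
                 std::to_string(f.size()));

    chrom[i] = f[0];
    long p = parse_nonneg(f[1]);
    if (p < 1)
      parse_fail(i + 1, "2 (POS)", "non-numeric or non-positive position '" + f[1] + "'");
    pos[i] = (int)p;
    if (f[2].empty()) parse_fail(i + 1, "3 (REF)", "empty reference base");
    ref[i] = f[2];
    long d = parse_nonneg(f[3]);
    if (d < 0)
      parse_fail(i + 1, "4 (DEPTH)", "non-numeric depth '" + f[3] + "'");
    depth[i] = (int)d;

    const std::string &bases = f[4], &bq = f[5], &mq = f[6];

    // read positions: comma separated integers
    std::vector<int> rpos;
    if (!(f[7] == "*" && bq == "*")) {  // samtools writes '*' for zero depth
      size_t s = 0;
      while (s < f[7].size()) {
        size_t c = f[7].find(',', s);
        std::string tok = (c == std::string::npos) ? f[7].substr(s) : f[7].substr(s, c - s);
        long rp = parse_nonneg(tok);
        if (rp < 1)
          parse_fail(i + 1, "8 (READ-POS)", "bad read position '" + tok + "'");
        rpos.push_back((int)rp);
        if (c == std::string::npos) break;
        s = c + 1;
      }
    }
    bool empty_quals = (bq == "*" && d == 0);
    size_t nq = empty_quals ? 0 : bq.size();
    if (!empty_quals && mq.size() != nq)
      parse_fail(i + 1, "7 (MAP-QUALS)", "length " + std::to_string(mq.size()) +
                 " differs from base-quality length " + std::to_string(nq));
    if (rpos.size() != nq)
      parse_fail(i + 1, "8 (READ-POS)", std::to_string(rpos.size()) +
                 " entries for " + std::to_string(nq) + " per-base quality entries");

    if (d == 0 && bases == "*") {  // samtools placeholder for zero coverage
      n_obs[i] = 0; n_skip[i] = 0;
      continue;
    }

    char refb = toupper(ref[i][0]);
    size_t qi = 0;          // index into quality strings / read positions
    bool pending_start = false;
    int last_obs = -1;      // index into o_* of last emitted observation
    bool last_was_skip = false;
    int emitted = 0, skipped = 0;

    for (size_t j = 0; j < bases.size(); ++j) {
      char c = bases[j];
      if (c == '^') {
        if (j + 1 >= bases.size())
          parse_fail(i + 1, "5 (BASES)", "dangling '^' at end of base string");
        ++j;  // mapping-quality character of the read start
        pending_start = true;
        continue;
      }
      if (c == '$') {
        if (last_obs >= 0 && !last_was_skip) o_end[last_obs] = true;
        continue;
      }
      if (c == '+' || c == '-') {
        size_t k = j + 1, len = 0;
        if (k >= bases.size() || !isdigit(bases[k]))
          parse_fail(i + 1, "5 (BASES)", "indel marker without length");
        while (k < bases.size() && isdigit(bases[k])) {
          len = len * 10 + (bases[k] - '0');
          ++k;
        }
        if (k + len > bases.size())
          parse_fail(i + 1, "5 (BASES)", "indel length " + std::to_string(len) +
                     " overruns base string");
        j = k + len - 1;
        continue;
      }
      // every remaining symbol consumes one per-base column entry
      if (qi >= nq)
        parse_fail(i + 1, "5 (BASES)", "more base symbols than quality entries");
      if (c == '*' || c == '<' || c == '>') {
        ++qi; ++skipped;
        pending_start = false;
        last_was_skip = true;
        continue;
      }
      std::string allele;
      bool fwd;
      if (c == '.')       { allele = std::string(1, refb); fwd = true;  }
      else if (c == ',')  { allele = std::string(1, refb); fwd = false; }
      else if (strchr("ACGTN", c)) { allele = std::string(1, c); fwd = true; }
      else if (strchr("acgtn", c)) { allele = std::string(1, (char)toupper(c)); fwd = false; }
      else
        parse_fail(i + 1, "5 (BASES)", std::string("unexpected character '") + c + "'");

      o_site.push_back(i + 1);
      o_allele.push_back(allele);
      o_fwd.push_back(fwd);
      o_bqv.push_back((int)bq[qi] - 33);
      o_mqv.push_back((int)mq[qi] - 33);
      o_rpos.push_back(rpos[qi]);
      o_start.push_back(pending_start);
      o_end.push_back(false);
      last_obs = (int)o_site.size() - 1;
      last_was_skip = false;
      pending_start = false;
      ++qi; ++emitted;
    }
    if (qi != nq)
      parse_fail(i + 1, "5 (BASES)", "decoded " + std::to_string(qi) +
                 " read symbols but quality strings have " + std::to_string(nq));
    n_obs[i] = emitted;
    n_skip[i] = skipped;
  }

  int m = (int)o_site.size();
  IntegerVector site(m), bqv(m), mqv(m), rp(m);
  CharacterVector allele(m);
  LogicalVector fwd(m), is_start(m), is_end(m);
  for (int k = 0; k < m; ++k) {
    site[k] = o_site[k];
    allele[k] = o_allele[k];
    fwd[k] = o_fwd[k];
    bqv[k] = o_bqv[k];
    mqv[k] = o_mqv[k];
    rp[k] = o_rpos[k];
    is_start[k] = o_start[k];
    is_end[k] = o_end[k];
  }
  return List::create(
    _["chrom"] = chrom, _["pos"] = pos, _["ref"] = ref, _["depth"] = depth,
    _["n_obs"] = n_obs, _["n_skip"] = n_skip,
    _["site"] = site, _["allele"] = allele, _["fwd"] = fwd,
    _["bqv"] = bqv, _["mqv"] = mqv, _["read_pos"] = rp,
    _["is_start"] = is_start, _["is_end"] = is_end);
}
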
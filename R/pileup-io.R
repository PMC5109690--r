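#' Read a SAMtools mpileup file into a pileup object
#'
#' Parses a single-sample mpileup file produced with per-base base-quality,
#' mapping-quality and within-read-position columns (e.g.
#' `samtools mpileup -B -s -O -f ref.fa sample.bam`). The base column grammar
#' is consumed in full: read-start markers (`^` plus mapping-quality
#' character), read-end markers (`$`), indel segments (`+N<seq>` / `-N<seq>`),
#' deleted-base placeholders (`*`) and reference skips (`<`, `>`). Placeholders
#' and skips consume their per-base column entries but yield no observation;
#' indels contribute no SNV allele.
#'
#' @param path Path to an mpileup file; plain or gzip-compressed.
#' @return A `pileup` object: a list with a `sites` table (`chrom`, `pos`,
#'   `ref`, `depth`, `n_obs`, `n_skip`) and an `obs` table holding one row per
#'   decoded read base (`site` index, `allele` after reference resolution,
#'   `fwd` strand flag, `bqv`, `mqv`, `read_pos`, `is_start`, `is_end`).
#' @examples
#' p <- parse_mpileup_lines("chr1\t100\tA\t5\t..,,.\tIIIII\t]]]]]\t1,2,3,4,5")
#' p$sites
#' @export
read_mpileup <- function(path) {
  if (!file.exists(path)) stop("mpileup file not found: ", path)
  parse_mpileup_lines(readLines(path))
}

#' Parse mpileup lines already in memory
#'
#' @param lines Character vector of tab-separated mpileup lines
#'   (CHROM, POS, REF, DEPTH, BASES, BASE-QUALS, MAP-QUALS, READ-POSITIONS;
#'   quality strings ASCII-33 phred).
#' @return A `pileup` object (see [read_mpileup()]).
#' @export
parse_mpileup_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  raw <- .cpp_parse_mpileup(lines)
  sites <- data.table::data.table(
    chrom = raw$chrom, pos = raw$pos, ref = toupper(raw$ref),
    depth = raw$depth, n_obs = raw$n_obs, n_skip = raw$n_skip
  )
  obs <- data.table::data.table(
    site = raw$site, allele = raw$allele, fwd = raw$fwd,
    bqv = raw$bqv, mqv = raw$mqv, read_pos = raw$read_pos,
    is_start = raw$is_start, is_end = raw$is_end
  )
  structure(list(sites = sites, obs = obs), class = "pileup")
}

#' Parse one mpileup line into a single-site record
#'
#' @param line One tab-separated mpileup line.
#' @return A `pileup_record`: list with `chrom`, `pos`, `ref`, `depth` and an
#'   `observations` data.table (one decoded read base per row).
#' @export
parse_mpileup_line <- function(line) {
  p <- parse_mpileup_lines(line)
  pileup_record(p, 1L)
}

#' Extract one site of a pileup as a record
#'
#' @param pileup A `pileup` object.
#' @param i Site index (row of `pileup$sites`).
#' @return A `pileup_record` (see [parse_mpileup_line()]).
#' @export
pileup_record <- function(pileup, i) {
  stopifnot(inherits(pileup, "pileup"), i >= 1, i <= nrow(pileup$sites))
  s <- pileup$sites[i]
  structure(list(
    chrom = s$chrom, pos = s$pos, ref = s$ref, depth = s$depth,
    observations = pileup$obs[site == i][, -"site"]
  ), class = "pileup_record")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d sites, %d observations, %d contig(s)\n",
              nrow(x$sites), nrow(x$obs), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Serialize a pileup object back to mpileup text
#'
#' Inverse of [parse_mpileup_lines()] for records without indels or
#' placeholders: re-parsing the output reproduces the object field for field.
#' The depth column is written as the observation count (placeholders are not
#' retained by the parser).
#'
#' @param pileup A `pileup` object.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the mpileup lines.
#' @export
write_mpileup <- function(pileup, path = NULL) {
  stopifnot(inherits(pileup, "pileup"))
  s <- pileup$sites
  o <- pileup$obs
  ref_per_obs <- s$ref[o$site]
  base <- ifelse(o$allele == ref_per_obs,
                 ifelse(o$fwd, ".", ","),
                 ifelse(o$fwd, o$allele, tolower(o$allele)))
  mq_chr <- intToUtf8(o$mqv + 33L, multiple = TRUE)
  bq_chr <- intToUtf8(o$bqv + 33L, multiple = TRUE)
  tok <- paste0(ifelse(o$is_start, paste0("^", mq_chr), ""), base,
                ifelse(o$is_end, "$", ""))
  f <- factor(o$site, levels = seq_len(nrow(s)))
  bases_col <- vapply(split(tok, f), paste0, "", collapse = "")
  bq_col <- vapply(split(bq_chr, f), paste0, "", collapse = "")
  mq_col <- vapply(split(mq_chr, f), paste0, "", collapse = "")
  rp_col <- vapply(split(as.character(o$read_pos), f), paste0, "", collapse = ",")
  empty <- s$n_obs == 0L
  bases_col[empty] <- "*"; bq_col[empty] <- "*"; mq_col[empty] <- "*"
  rp_col[empty] <- "*"
  lines <- paste(s$chrom, s$pos, s$ref, s$n_obs, bases_col, bq_col, mq_col,
                 rp_col, sep = "\t")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Pair matched tumor and normal pileups by locus
#'
#' Intersects the two site lists on (chrom, pos): only loci present in both
#' pileups are retained, in input order. Both inputs must be coordinate-sorted
#' with a shared contig order; a position decrease within a contig raises an
#' ordering error, as does a reference-base disagreement at a shared locus.
#'
#' @param tumor,normal `pileup` objects for the tumor and matched normal
#'   sample.
#' @return A `paired_pileup`: list with the two pileups and the paired site
#'   index vectors `t_idx`, `n_idx`.
#' @export
pair_pileups <- function(tumor, normal) {
  stopifnot(inherits(tumor, "pileup"), inherits(normal, "pileup"))
  check_sorted <- function(s, label) {
    if (nrow(s) < 2) return(invisible())
    same <- s$chrom[-1] == s$chrom[-nrow(s)]
    bad <- which(same & diff(s$pos) <= 0)
    if (length(bad))
      stop(sprintf("%s mpileup not coordinate-sorted: position %d follows %d on %s (line %d)",
                   label, s$pos[bad[1] + 1], s$pos[bad[1]], s$chrom[bad[1]], bad[1] + 1L))
  }
  check_sorted(tumor$sites, "tumor")
  check_sorted(normal$sites, "normal")
  tk <- paste(tumor$sites$chrom, tumor$sites$pos)
  nk <- paste(normal$sites$chrom, normal$sites$pos)
  t_idx <- which(tk %in% nk)
  n_idx <- match(tk[t_idx], nk)
  mism <- tumor$sites$ref[t_idx] != normal$sites$ref[n_idx]
  if (any(mism)) {
    i <- t_idx[which(mism)[1]]
    stop("reference base disagreement between tumor and normal at ",
         tumor$sites$chrom[i], ":", tumor$sites$pos[i])
  }
  structure(list(tumor = tumor, normal = normal,
                 t_idx = t_idx, n_idx = n_idx),
            class = "paired_pileup")
}

#' @export
print.paired_pileup <- function(x, ...) {
  cat(sprintf("<paired_pileup> %d shared loci (tumor %d, normal %d sites)\n",
              length(x$t_idx), nrow(x$tumor$sites), nrow(x$normal$sites)))
  invisible(x)
}
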
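#' Pairwise tag alignment
#'
#' Needleman--Wunsch global alignment with linear gap penalty. GBS tags at a
#' locus share an anchored 5' start (the cut-site remnant) but differ in
#' length at the 3' end, so trailing gaps are free by default.
#'
#' @param a,b Sequences to align.
#' @param match,mismatch,gap Scoring scheme (defaults +2 / -1 / -3).
#' @param free_end_gaps Leave trailing gaps unpenalised.
#' @return List with `score` and the two gapped strings `a`, `b`.
#' @export
align_pair <- function(a, b, match = 2, mismatch = -1, gap = -3,
                       free_end_gaps = TRUE) {
  nw_align_cpp(a, b, match, mismatch, gap, free_end_gaps)
}

#' Multiple sequence alignment of the tags at a TagLocus
#'
#' Progressive centre-star alignment: the guide tag (highest count, ties by
#' canonical tag order) is aligned pairwise against every other member and
#' the pairwise gap patterns are merged into a common frame, so that indels
#' among tags from the same cut site are placed consistently. For a locus of
#' two tags the result is exactly the optimal pairwise alignment. Trailing
#' gaps arise from length differences and carry no information (tags simply
#' end); they are distinguished from internal gaps downstream.
#'
#' @param tags Character vector of member tag sequences (unique).
#' @param counts Optional experiment-wide tag counts used to pick the guide
#'   tag; defaults to equal counts.
#' @inheritParams align_pair
#' @return Object of class `gbs_msa`: list with `rows` (gapped strings, one
#'   per input tag, equal width, in input order), `width`, `center` (guide
#'   index), and `pair_scores` (pairwise score of each member against the
#'   guide; `NA` for the guide itself).
#' @export
align_tag_locus <- function(tags, counts = NULL, match = 2, mismatch = -1,
                            gap = -3) {
  stopifnot(length(tags) >= 1L)
  n <- length(tags)
  if (is.null(counts)) counts <- rep(1, n)
  if (n == 1L) {
    return(structure(list(rows = tags, width = nchar(tags), center = 1L,
                          pair_scores = NA_real_),
                     class = "gbs_msa"))
  }
  ## guide order: most frequent first, canonical tag order breaks ties
  guide <- order(-counts, tag_order(tags))[1]
  center <- tags[guide]
  others <- setdiff(seq_len(n), guide)
  alns <- lapply(tags[others], function(t) align_pair(center, t,
                                                      match, mismatch, gap))
  lc <- nchar(center)
  ## insertions relative to the centre: gaps in the centre row, indexed by
  ## the centre base they precede (lc + 1 = trailing)
  ins_of <- function(center_aln) {
    chars <- strsplit(center_aln, "", fixed = TRUE)[[1]]
    ins <- integer(lc + 1L)
    ci <- 1L
    for (ch in chars) {
      if (ch == "-") ins[ci] <- ins[ci] + 1L else ci <- ci + 1L
    }
    ins
  }
  ins_k <- lapply(alns, function(al) ins_of(al$a))
  ins <- Reduce(pmax, ins_k, integer(lc + 1L))

  rebuild <- function(center_aln, tag_aln, ins_this) {
    ca <- strsplit(center_aln, "", fixed = TRUE)[[1]]
    ta <- strsplit(tag_aln, "", fixed = TRUE)[[1]]
    out <- character(0)
    pos <- 1L  # position in pairwise alignment
    for (ci in seq_len(lc + 1L)) {
      ## insertion block before centre base ci
      k <- ins_this[ci]
      if (k > 0L) {
        out <- c(out, ta[pos:(pos + k - 1L)])
        pos <- pos + k
      }
      if (ins[ci] > k) out <- c(out, rep("-", ins[ci] - k))
      if (ci <= lc) {  # the centre base column itself
        out <- c(out, ta[pos])
        pos <- pos + 1L
      }
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  ## centre row in the merged frame
  cen_chars <- strsplit(center, "", fixed = TRUE)[[1]]
  cen_row <- character(0)
  for (ci in seq_len(lc + 1L)) {
    if (ins[ci] > 0L) cen_row <- c(cen_row, rep("-", ins[ci]))
    if (ci <= lc) cen_row <- c(cen_row, cen_chars[ci])
  }
  rows[guide] <- paste(cen_row, collapse = "")
  for (k in seq_along(others)) {
    rows[others[k]] <- rebuild(alns[[k]]$a, alns[[k]]$b, ins_k[[k]])
  }
  scores <- rep(NA_real_, n)
  scores[others] <- vapply(alns, `[[`, numeric(1), "score")
  structure(list(rows = rows, width = nchar(rows[1]), center = guide,
                 pair_scores = scores),
            class = "gbs_msa")
}

#' Character matrix of an alignment with trailing gaps marked missing
#'
#' Trailing gaps (a gap run extending to the end of a row) come from tags of
#' different lengths and mean "no data", not a deletion allele; they are
#' returned as `NA`. Internal gaps are the GAP allele `"-"`.
#' @param msa A `gbs_msa`.
#' @return Character matrix, rows = member tags, columns = alignment
#'   columns.
#' @keywords internal
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  for (i in seq_len(nrow(m))) {
    j <- ncol(m)
    while (j >= 1L && m[i, j] == "-") {
      m[i, j] <- NA_character_
      j <- j - 1L
    }
  }
  m
}
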
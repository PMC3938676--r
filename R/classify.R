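#' Classify raw reads into good, barcoded reads
#'
#' A *good, barcoded read* starts with a perfect match to exactly one key
#' barcode, immediately followed by a cut-site remnant of the enzyme, has no
#' `N` in the `trim_length` bases after the barcode, and yields a tag of at
#' least `min_tag_length` bases after trimming. Trimming removes the
#' barcode, truncates to `trim_length` (64 bp by default), and then
#' truncates at the first internal restriction-site pattern if one occurs
#' after the leading remnant (chimera trim: the bases on the remnant side
#' are kept, the new site onward is dropped).
#'
#' Every read receives exactly one status; failures are classifications, not
#' errors. Because lane barcodes are prefix-free, the classification never
#' depends on key row order.
#'
#' @param reads Character vector of upper-case read sequences.
#' @param key Barcode key rows for this flowcell/lane (see
#'   [read_barcode_key()]); all rows must belong to one lane.
#' @param enzyme Enzyme model from [gbs_enzyme()].
#' @param trim_length Maximum tag length in bases (<= 64).
#' @param min_tag_length Minimum post-trim tag length for a GOOD read.
#' @param check_remnant Require the cut-site remnant immediately after the
#'   barcode. Disable for protocols whose barcodes already include the
#'   remnant.
#' @return Tibble with one row per read: `status` (factor GOOD / NO_BARCODE /
#'   CONTAINS_N / TOO_SHORT), `taxon`, `tag`, `tag_length`,
#'   `chimera_trimmed`. `tag` is non-missing iff `status == "GOOD"`.
#' @export
classify_reads <- function(reads, key, enzyme, trim_length = 64L,
                           min_tag_length = 20L, check_remnant = TRUE) {
  stopifnot(trim_length >= 1L, trim_length <= 64L,
            min_tag_length >= 1L, min_tag_length <= trim_length)
  key <- key_for_lane(key)
  taxa <- key_taxa(key)
  n <- length(reads)
  if (n == 0L) {
    return(tibble::tibble(
      status = factor(character(),
                      levels = c("GOOD", "NO_BARCODE", "CONTAINS_N",
                                 "TOO_SHORT")),
      taxon = character(), tag = character(), tag_length = integer(),
      chimera_trimmed = logical()))
  }
  status <- rep("NO_BARCODE", n)
  taxon <- rep(NA_character_, n)
  tag <- rep(NA_character_, n)
  chimera <- rep(FALSE, n)
  bc_len <- rep(NA_integer_, n)

  ## barcode match: exact prefix, one pass per barcode length present
  reads <- toupper(reads)
  for (L in sort(unique(nchar(key$barcode)))) {
    rows <- which(nchar(key$barcode) == L)
    hit <- match(substr(reads, 1L, L), key$barcode[rows])
    take <- !is.na(hit) & is.na(bc_len)  # prefix-freeness: at most one match
    bc_len[take] <- L
    taxon[take] <- taxa[rows][hit[take]]
  }
  matched <- !is.na(bc_len)

  ## cut-site remnant immediately after the barcode
  rem_len <- rep(NA_integer_, n)
  post <- ifelse(matched,
                 substr(reads, bc_len + 1L, bc_len + trim_length),
                 NA_character_)
  for (r in enzyme$remnants) {
    ok <- matched & is.na(rem_len) & startsWith(post, r)
    rem_len[ok] <- nchar(r)
  }
  if (check_remnant) {
    matched <- matched & !is.na(rem_len)
  } else {
    rem_len[matched & is.na(rem_len)] <- 0L
  }
  taxon[!matched] <- NA_character_

  has_n <- matched & grepl("N", post, fixed = TRUE)
  status[matched & has_n] <- "CONTAINS_N"
  cand <- matched & !has_n

  ## chimera trim: first internal cut pattern after the leading remnant
  if (any(cand)) {
    rx <- enzyme_internal_regex(enzyme)
    scan_from <- substr(post[cand], rem_len[cand] + 1L, trim_length)
    hit <- regexpr(rx, scan_from)
    tg <- post[cand]
    trimmed <- hit > 0L
    tg[trimmed] <- substr(tg[trimmed],
                          1L, rem_len[cand][trimmed] + hit[trimmed] - 1L)
    chim <- trimmed
    keep_len <- nchar(tg)
    good <- keep_len >= min_tag_length
    idx <- which(cand)
    status[idx[good]] <- "GOOD"
    status[idx[!good]] <- "TOO_SHORT"
    tag[idx[good]] <- tg[good]
    chimera[idx] <- chim
  }
  taxon[status %in% c("NO_BARCODE")] <- NA_character_

  tibble::tibble(
    status = factor(status,
                    levels = c("GOOD", "NO_BARCODE", "CONTAINS_N", "TOO_SHORT")),
    taxon = taxon,
    tag = tag,
    tag_length = ifelse(is.na(tag), NA_integer_, nchar(tag)),
    chimera_trimmed = chimera
  )
}

#' Tabulate a classification report
#' @param cls Result of [classify_reads()].
#' @return Named integer vector of read counts by status plus `total`.
#' @keywords internal
classification_report <- function(cls) {
  counts <- table(cls$status)
  c(stats::setNames(as.integer(counts), names(counts)),
    total = nrow(cls))
}
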
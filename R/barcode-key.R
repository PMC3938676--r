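#' Barcode key files
#'
#' The barcode key maps `(flowcell, lane, barcode)` to a sample name, one
#' row per barcoded sample per lane; a sample may appear on multiple lanes
#' (replicate sequencing of the same library prep). Within a single
#' flowcell/lane, barcodes must be unique and prefix-free (no barcode may be
#' a prefix of another), which makes barcode matching order-independent.
#'
#' @param path Tab-delimited file with a header row and at least the columns
#'   `Flowcell`, `Lane`, `Barcode`, `Sample`; `LibraryPrepID` is optional and
#'   extra columns are ignored.
#' @return A tibble of class `gbs_key` with columns `flowcell`, `lane`,
#'   `barcode`, `sample`, `prep_id`.
#' @export
read_barcode_key <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  need <- c("Flowcell", "Lane", "Barcode", "Sample")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("barcode key is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  barcode_key(
    flowcell = df$Flowcell,
    lane = df$Lane,
    barcode = toupper(df$Barcode),
    sample = df$Sample,
    prep_id = if ("LibraryPrepID" %in% names(df)) df$LibraryPrepID else NA_character_
  )
}

#' @param flowcell,lane,barcode,sample,prep_id Key fields (recycled to a
#'   common length).
#' @rdname read_barcode_key
#' @export
barcode_key <- function(flowcell, lane, barcode, sample,
                        prep_id = NA_character_) {
  key <- tibble::tibble(
    flowcell = as.character(flowcell),
    lane = as.character(lane),
    barcode = toupper(as.character(barcode)),
    sample = as.character(sample),
    prep_id = as.character(prep_id)
  )
  validate_barcode_key(key)
  class(key) <- c("gbs_key", class(key))
  key
}

validate_barcode_key <- function(key) {
  if (any(grepl("[^ACGT]", key$barcode))) {
    stop("barcodes must contain only A/C/G/T")
  }
  bl <- nchar(key$barcode)
  if (any(bl < 4L | bl > 16L)) stop("barcode lengths must be in [4, 16]")
  for (grp in split(key$barcode, paste(key$flowcell, key$lane, sep = "\r"))) {
    if (anyDuplicated(grp)) {
      stop("duplicate barcode within one flowcell/lane: ",
           grp[duplicated(grp)][1])
    }
    ## prefix-freeness: pairwise check within the lane
    srt <- sort(grp, method = "radix")
    if (length(srt) > 1L) {
      pre <- startsWith(srt[-1L], srt[-length(srt)])
      if (any(pre)) {
        stop("barcode '", srt[-length(srt)][pre][1], "' is a prefix of '",
             srt[-1L][pre][1], "' in the same lane")
      }
    }
  }
  invisible(key)
}

#' Restrict a key to one flowcell/lane
#' @param key A `gbs_key`.
#' @param flowcell,lane Lane identifiers; `NULL` keeps all (valid only if the
#'   key covers a single lane).
#' @return A `gbs_key` for exactly one lane.
#' @keywords internal
key_for_lane <- function(key, flowcell = NULL, lane = NULL) {
  sub <- key
  if (!is.null(flowcell)) sub <- sub[sub$flowcell == flowcell, ]
  if (!is.null(lane)) sub <- sub[sub$lane == lane, ]
  lanes <- unique(paste(sub$flowcell, sub$lane, sep = ":"))
  if (nrow(sub) == 0L) stop("no barcode key entries for the requested lane")
  if (length(lanes) > 1L) {
    stop("key covers multiple lanes (", paste(lanes, collapse = ", "),
         "); specify flowcell and lane")
  }
  sub
}

#' Taxon names for key rows
#'
#' A taxon is a sample from a particular library prep: when `LibraryPrepID`
#' is present and non-missing the taxon name is `sample:prep_id`, otherwise
#' the sample name alone. Replicate lanes of the same taxon are tallied
#' together (depths summed, saturating at the depth cap).
#' @param key A `gbs_key`.
#' @return Character vector of taxon names, one per key row.
#' @export
key_taxa <- function(key) {
  ifelse(is.na(key$prep_id) | key$prep_id == "",
         key$sample, paste(key$sample, key$prep_id, sep = ":"))
}
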
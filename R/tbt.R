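#' Tags by taxa (TBT): per-taxon observed tag depths
#'
#' The TBT records how many times each master tag was observed in each
#' taxon, with depth stored as a saturating byte capped at 127. At the low
#' sequencing depths the pipeline is designed for, the matrix is mostly
#' zeros, which the run-length-encoded persistence exploits.
#'
#' `build_tbt()` re-reads the FASTQ files, classifies each read, and for
#' every good read whose tag is in the master list increments
#' `depth[tag, taxon]` (saturating at the cap). Good reads whose tags are
#' not in the master list are counted in the report but not stored.
#'
#' @param fastqs Character vector of FASTQ paths.
#' @param key Barcode key covering the lanes of these files.
#' @param master Master tag list (`gbs_tagcounts`).
#' @param enzyme Enzyme model.
#' @param lanes Optional tibble `fastq`, `flowcell`, `lane` assigning each
#'   file to a key lane; may be omitted when the key covers one lane.
#' @param taxa Optional taxa list; defaults to the key's taxa. A key taxon
#'   missing from this list is an error.
#' @inheritParams classify_reads
#' @param depth_cap Saturation depth (default 127).
#' @return Object of class `gbs_tbt`: list with `tags` (master order),
#'   `taxa`, integer `depth` matrix (tags x taxa), and `report` (per-taxon
#'   matched read counts, unmatched-good counts, reads by status).
#' @export
build_tbt <- function(fastqs, key, master, enzyme, lanes = NULL,
                      taxa = NULL, trim_length = 64L, min_tag_length = 20L,
                      check_remnant = TRUE, depth_cap = 127L) {
  if (is.null(taxa)) taxa <- unique(key_taxa(key))
  depth <- matrix(0L, nrow = nrow(master), ncol = length(taxa),
                  dimnames = list(NULL, taxa))
  unmatched <- 0L
  status_totals <- integer(0)
  matched_by_taxon <- setNames(numeric(length(taxa)), taxa)
  for (f in fastqs) {
    if (!is.null(lanes)) {
      row <- lanes[lanes$fastq == f, ]
      if (nrow(row) != 1L) stop("no unique lane assignment for ", f)
      lane_key <- key_for_lane(key, row$flowcell, row$lane)
    } else {
      lane_key <- key_for_lane(key)
    }
    bad <- setdiff(key_taxa(lane_key), taxa)
    if (length(bad)) {
      stop("taxon in key absent from requested taxa list: ", bad[1])
    }
    cls <- classify_reads(read_fastq(f)$seq, lane_key, enzyme,
                          trim_length = trim_length,
                          min_tag_length = min_tag_length,
                          check_remnant = check_remnant)
    rep_f <- classification_report(cls)
    status_totals <- merge_counts(status_totals, rep_f)
    good <- cls[cls$status == "GOOD", c("taxon", "tag")]
    ti <- match(good$tag, master$tag)
    unmatched <- unmatched + sum(is.na(ti))
    good <- good[!is.na(ti), ]
    ti <- ti[!is.na(ti)]
    if (nrow(good)) {
      ci <- match(good$taxon, taxa)
      tal <- dplyr::count(tibble::tibble(i = ti, j = ci), .data$i, .data$j)
      cell <- cbind(tal$i, tal$j)
      depth[cell] <- pmin(depth_cap, depth[cell] + tal$n)
      mt <- tapply(rep(1L, nrow(good)), factor(good$taxon, levels = taxa),
                   sum, default = 0L)
      matched_by_taxon <- matched_by_taxon + as.numeric(mt)
    }
  }
  new_tbt(master$tag, taxa, depth,
          report = list(matched_by_taxon = matched_by_taxon,
                        unmatched_good = unmatched,
                        reads_by_status = status_totals))
}

merge_counts <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(integer(length(keys)), keys)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

new_tbt <- function(tags, taxa, depth, report = NULL, depth_cap = 127L) {
  stopifnot(nrow(depth) == length(tags), ncol(depth) == length(taxa),
            !anyDuplicated(taxa), all(depth >= 0L), all(depth <= depth_cap))
  structure(list(tags = tags, taxa = taxa,
                 depth = matrix(as.integer(depth), nrow = length(tags),
                                dimnames = list(NULL, taxa)),
                 report = report),
            class = "gbs_tbt", depth_cap = depth_cap)
}

#' Merge replicate taxa in a TBT
#'
#' Replicate taxa (the same sample from the same or different library
#' preps/lanes) are tallied together: the merged depth is the sum of the
#' member depths, saturating at the cap.
#'
#' @param tbt A `gbs_tbt`.
#' @param groups Named character vector mapping taxon name -> merged taxon
#'   name; taxa not named keep their own column.
#' @return A `gbs_tbt` with merged columns (first-occurrence order).
#' @export
merge_taxa <- function(tbt, groups) {
  stopifnot(!is.null(names(groups)))
  unknown <- setdiff(names(groups), tbt$taxa)
  if (length(unknown)) stop("unknown taxa in groups: ", unknown[1])
  new_names <- ifelse(tbt$taxa %in% names(groups),
                      groups[tbt$taxa], tbt$taxa)
  out_taxa <- unique(new_names)
  cap <- attr(tbt, "depth_cap")
  depth <- matrix(0L, nrow = length(tbt$tags), ncol = length(out_taxa),
                  dimnames = list(NULL, out_taxa))
  for (j in seq_along(tbt$taxa)) {
    col <- new_names[j]
    depth[, col] <- pmin(cap, depth[, col] + tbt$depth[, j])
  }
  new_tbt(tbt$tags, out_taxa, depth, report = tbt$report, depth_cap = cap)
}

#' Run-length-encoded TBT persistence
#'
#' Little-endian binary: magic `"GBT1"`, version, dimensions, the tag
#' dictionary (packed 2-bit payload + length byte), taxa names, then one
#' run-length-encoded row per tag: a zero byte followed by an 8-bit run
#' length (1-255; longer runs are chunked) encodes a run of zero depths;
#' bytes 1..127 are literal depths. A whole-matrix checksum guards the
#' stream. Round-trips are exact.
#'
#' @param tbt A `gbs_tbt`.
#' @param path Output path.
#' @return `write_tbt()` invisibly returns byte accounting (`payload_bytes`
#'   = RLE depth stream, `raw_bytes` = uncompressed matrix size);
#'   `read_tbt()` returns the `gbs_tbt`.
#' @export
write_tbt <- function(tbt, path) {
  n_tags <- length(tbt$tags)
  n_taxa <- length(tbt$taxa)
  if (n_taxa > 65535L) stop("more than 65535 taxa not supported")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GBT1"), con)
  writeBin(1L, con, size = 1L)
  writeBin(n_tags, con, size = 4L, endian = "little")
  writeBin(n_taxa, con, size = 4L, endian = "little")
  if (n_tags > 0L) {
    enc <- encode_tags(tbt$tags)
    payload <- hex_to_raw(enc$packed)
    dim(payload) <- c(16L, n_tags)
    for (i in seq_len(n_tags)) {
      writeBin(payload[, i], con)
      writeBin(enc$length[i], con, size = 1L)
    }
  }
  for (tx in tbt$taxa) {
    r <- charToRaw(tx)
    writeBin(length(r), con, size = 2L, endian = "little")
    writeBin(r, con)
  }
  payload_bytes <- 0L
  for (i in seq_len(n_tags)) {
    row <- tbt$depth[i, ]
    r <- rle(row == 0L)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      L <- r$lengths[k]
      if (r$values[k]) {
        while (L > 0L) {
          chunk <- min(L, 255L)
          writeBin(as.raw(c(0L, chunk)), con)
          payload_bytes <- payload_bytes + 2L
          L <- L - chunk
        }
      } else {
        writeBin(as.raw(row[pos:(pos + L - 1L)]), con)
        payload_bytes <- payload_bytes + L
      }
      pos <- pos + r$lengths[k]
    }
  }
  writeBin(tbt_checksum(tbt$depth), con, size = 8L, endian = "little")
  payload_bytes <- payload_bytes + 8L
  invisible(list(path = path, payload_bytes = payload_bytes,
                 raw_bytes = n_tags * n_taxa))
}

tbt_checksum <- function(depth) {
  if (!length(depth)) return(0)
  sum(as.numeric(depth) * (1 + (seq_along(depth) - 1) %% 97))
}

#' @rdname write_tbt
#' @export
read_tbt <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "GBT1") {
    stop("not a gbstag TBT file: ", path)
  }
  ver <- readBin(con, "integer", 1L, size = 1L)
  if (ver != 1L) stop("unsupported TBT version: ", ver)
  n_tags <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_taxa <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tags <- character(n_tags)
  if (n_tags > 0L) {
    packed <- character(n_tags); lens <- integer(n_tags)
    for (i in seq_len(n_tags)) {
      packed[i] <- paste(format(readBin(con, "raw", 16L)), collapse = "")
      lens[i] <- readBin(con, "integer", 1L, size = 1L)
    }
    tags <- decode_tags(packed, lens)
  }
  taxa <- character(n_taxa)
  for (j in seq_len(n_taxa)) {
    L <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    taxa[j] <- rawToChar(readBin(con, "raw", L))
  }
  depth <- matrix(0L, nrow = n_tags, ncol = n_taxa,
                  dimnames = list(NULL, taxa))
  for (i in seq_len(n_tags)) {
    filled <- 0L
    row <- integer(n_taxa)
    while (filled < n_taxa) {
      b <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      if (length(b) == 0L) stop("truncated TBT stream: ", path)
      if (b == 0L) {
        L <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
        filled <- filled + L
      } else {
        row[filled + 1L] <- b
        filled <- filled + 1L
      }
    }
    if (filled != n_taxa) stop("corrupted TBT row (overrun): ", path)
    depth[i, ] <- row
  }
  chk <- readBin(con, "double", 1L, size = 8L, endian = "little")
  if (!isTRUE(all.equal(chk, tbt_checksum(depth)))) {
    stop("TBT checksum mismatch (corrupted stream): ", path)
  }
  new_tbt(tags, taxa, depth)
}

#' Flag taxa with unexpectedly high depth for blank controls
#'
#' Blank negative controls are ordinary taxa in a build; this report flags
#' any taxon whose total matched depth exceeds what a blank should show,
#' and conversely lists near-empty taxa (failed samples or true blanks).
#'
#' @param tbt A `gbs_tbt`.
#' @param max_blank_depth Total matched depth above which a supposed blank
#'   would be suspicious (default 50).
#' @return Tibble: `taxon`, `total_depth`, `blank_like` (depth at or below
#'   the threshold).
#' @export
tbt_blank_report <- function(tbt, max_blank_depth = 50) {
  depth <- unname(colSums(tbt$depth))
  tibble::tibble(taxon = tbt$taxa, total_depth = as.numeric(depth),
                 blank_like = depth <= max_blank_depth)
}
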
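#' Collapse a FASTQ file into a tag-count table
#'
#' First Discovery step: every good, barcoded read in the file increments
#' the count of its trimmed tag, producing one sorted tag-count table per
#' input FASTQ file. The table is a key-value map keyed by `(sequence,
#' length)`; iteration order is the canonical tag order (see [tag_order()]).
#'
#' @param fastq Path to a FASTQ file (`.gz` allowed).
#' @param key Barcode key (see [read_barcode_key()]).
#' @param enzyme Enzyme model from [gbs_enzyme()].
#' @param flowcell,lane Lane of this file within `key`; may be omitted when
#'   the key covers a single lane.
#' @inheritParams classify_reads
#' @return A tibble of class `gbs_tagcounts` with columns `tag`, `count`,
#'   sorted by tag; attributes `report` (read accounting by status) and
#'   `source` (the FASTQ path).
#' @export
count_tags <- function(fastq, key, enzyme, trim_length = 64L,
                       min_tag_length = 20L, check_remnant = TRUE,
                       flowcell = NULL, lane = NULL) {
  key <- key_for_lane(key, flowcell, lane)
  reads <- read_fastq(fastq)$seq
  cls <- classify_reads(reads, key, enzyme, trim_length = trim_length,
                        min_tag_length = min_tag_length,
                        check_remnant = check_remnant)
  tc <- tag_count_table(cls$tag[cls$status == "GOOD"])
  attr(tc, "report") <- classification_report(cls)
  attr(tc, "source") <- fastq
  tc
}

#' Build a tag-count table from a vector of tag observations
#' @param tags Character vector of tag sequences (one per GOOD read).
#' @return `gbs_tagcounts` tibble.
#' @export
tag_count_table <- function(tags) {
  if (length(tags) == 0L) {
    out <- tibble::tibble(tag = character(), count = numeric())
  } else {
    agg <- table(tags)
    out <- tibble::tibble(tag = names(agg), count = as.numeric(agg))
    out <- out[tag_order(out$tag), ]
  }
  class(out) <- c("gbs_tagcounts", class(out))
  out
}

#' Merge tag-count tables into a master tag list
#'
#' Counts are summed across tables and only tags occurring at or above the
#' experiment-wide minimum count are retained in the master tag list. The
#' minimum count is the pipeline's quality filter at this stage: the more
#' often a tag was observed, the less likely it contains a sequencing error.
#'
#' @param tables List of `gbs_tagcounts` tables (or a single table).
#' @param min_count Experiment-wide minimum read count, >= 1 (default 5).
#' @return `gbs_tagcounts` tibble sorted by tag, with attribute
#'   `min_count`.
#' @export
merge_tag_counts <- function(tables, min_count = 5) {
  stopifnot(min_count >= 1)
  if (inherits(tables, "gbs_tagcounts")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  all <- dplyr::bind_rows(lapply(tables, function(t) t[c("tag", "count")]))
  merged <- dplyr::summarise(dplyr::group_by(all, .data$tag),
                             count = sum(.data$count), .groups = "drop")
  merged <- merged[merged$count >= min_count, ]
  merged <- merged[tag_order(merged$tag), ]
  out <- tibble::as_tibble(merged)
  class(out) <- c("gbs_tagcounts", class(out))
  attr(out, "min_count") <- min_count
  out
}

#' Export a master tag list as FASTQ for external alignment
#'
#' Tags are written at their true length (not padded) with a uniform high
#' quality score; the record identifier encodes the tag's index in the
#' master list and its count (`tag%06d_count%d`) so that SAM alignments can
#' be resolved back to master tags by [import_sam()].
#'
#' @param master `gbs_tagcounts` master list (non-empty).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
export_master_fastq <- function(master, path) {
  stopifnot(nrow(master) > 0L)
  ids <- sprintf("tag%06d_count%d", seq_len(nrow(master)), master$count)
  write_fastq(master$tag, ids, path)
}

#' Resolve exported read IDs back to master indices
#' @keywords internal
parse_master_read_id <- function(id) {
  idx <- suppressWarnings(as.integer(sub("^tag([0-9]+)_count.*$", "\\1", id)))
  if (anyNA(idx)) {
    stop("SAM read ID(s) not in master export format 'tagNNNNNN_countK': ",
         id[which(is.na(idx))[1]])
  }
  idx
}

#' Persist tag-count tables
#'
#' Two interchangeable forms: a tab-separated text table (`format = "tsv"`)
#' and a documented little-endian binary (`format = "binary"`): magic
#' `"GBTC"`, version byte, record count (int32), then one 25-byte record per
#' tag — 16 bytes of packed two-bit sequence, 1 length byte, and the count
#' as an IEEE-754 double (exact for counts below 2^53). Round-trips are
#' content-identical.
#'
#' @param x `gbs_tagcounts` table.
#' @param path Output path.
#' @param format `"binary"` or `"tsv"`.
#' @return `read_tag_counts()` returns the `gbs_tagcounts` tibble.
#' @export
write_tag_counts <- function(x, path, format = c("binary", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data.frame(tag = x$tag, count = x$count),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GBTC"), con)
  writeBin(1L, con, size = 1L)
  writeBin(nrow(x), con, size = 4L, endian = "little")
  if (nrow(x) > 0L) {
    enc <- encode_tags(x$tag)
    payload <- hex_to_raw(enc$packed)
    dim(payload) <- c(16L, nrow(x))
    for (i in seq_len(nrow(x))) {
      writeBin(payload[, i], con)
      writeBin(enc$length[i], con, size = 1L)
      writeBin(as.double(x$count[i]), con, size = 8L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path, format = c("binary", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    out <- tibble::tibble(tag = df$tag, count = as.numeric(df$count))
    class(out) <- c("gbs_tagcounts", class(out))
    return(out)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "GBTC") {
    stop("not a gbstag TagCounts binary file: ", path)
  }
  ver <- readBin(con, "integer", 1L, size = 1L)
  if (ver != 1L) stop("unsupported TagCounts version: ", ver)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tag <- character(n)
  count <- numeric(n)
  if (n > 0L) {
    packed <- character(n)
    lens <- integer(n)
    for (i in seq_len(n)) {
      packed[i] <- paste(format(readBin(con, "raw", 16L)), collapse = "")
      lens[i] <- readBin(con, "integer", 1L, size = 1L)
      count[i] <- readBin(con, "double", 1L, size = 8L, endian = "little")
    }
    tag <- decode_tags(packed, lens)
  }
  out <- tibble::tibble(tag = tag, count = count)
  class(out) <- c("gbs_tagcounts", class(out))
  out
}
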
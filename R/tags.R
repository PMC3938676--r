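#' Two-bit tag sequence encoding
#'
#' GBS sequence tags (unique trimmed reads of at most 64 bases, barcode
#' excluded) are stored in a packed two-bit-per-base code: `A = 00`,
#' `C = 01`, `G = 10`, `T = 11`, first base in the most significant bits,
#' unused trailing positions zero-padded (so a 64-base tag occupies exactly
#' 128 bits / 16 bytes of payload). Because the padding base (`A`) is a legal
#' base, the tag length is stored explicitly alongside the packed payload and
#' the pair `(packed, length)` is the identity of a tag: two tags are equal
#' iff both sequence and length are equal.
#'
#' @param seq Character vector of A/C/G/T sequences, lengths 1--64.
#' @return `encode_tags()` returns a tibble with columns `packed` (32
#'   lowercase hex characters = 16 bytes) and `length`. `decode_tags()`
#'   returns the character vector of sequences.
#' @examples
#' enc <- encode_tags(c("ACGT", "TTTT"))
#' decode_tags(enc$packed, enc$length)
#' @export
encode_tags <- function(seq) {
  check_tag_seq(seq)
  n <- length(seq)
  if (n == 0L) {
    return(tibble::tibble(packed = character(), length = integer()))
  }
  len <- nchar(seq)
  padded <- stringr::str_pad(seq, 64L, side = "right", pad = "A")
  codes <- match(unlist(strsplit(padded, "", fixed = TRUE)),
                 c("A", "C", "G", "T")) - 1L
  dim(codes) <- c(64L, n)
  hexval <- codes[seq(1L, 63L, 2L), , drop = FALSE] * 4L +
    codes[seq(2L, 64L, 2L), , drop = FALSE]
  hexchr <- c(0:9, letters[1:6])[hexval + 1L]
  dim(hexchr) <- c(32L, n)
  packed <- do.call(paste0, lapply(seq_len(32L), function(i) hexchr[i, ]))
  tibble::tibble(packed = packed, length = as.integer(len))
}

#' @param packed Character vector of 32-hex-character packed payloads.
#' @param length Integer vector of tag lengths in bases.
#' @rdname encode_tags
#' @export
decode_tags <- function(packed, length) {
  stopifnot(length(packed) == length(length))
  if (length(packed) == 0L) return(character())
  if (any(nchar(packed) != 32L)) {
    stop("packed payloads must be 32 hex characters (16 bytes)")
  }
  if (any(length < 1L | length > 64L)) stop("tag lengths must be in [1, 64]")
  n <- length(packed)
  vals <- match(unlist(strsplit(tolower(packed), "", fixed = TRUE)),
                c(0:9, letters[1:6])) - 1L
  if (anyNA(vals)) stop("packed payloads must be hex characters")
  dim(vals) <- c(32L, n)
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = 64L, ncol = n)
  out[seq(1L, 63L, 2L), ] <- bases[vals %/% 4L + 1L]
  out[seq(2L, 64L, 2L), ] <- bases[vals %% 4L + 1L]
  full <- do.call(paste0, lapply(seq_len(64L), function(i) out[i, ]))
  substr(full, 1L, length)
}

check_tag_seq <- function(seq) {
  if (length(seq) == 0L) return(invisible(seq))
  bad_len <- nchar(seq) < 1L | nchar(seq) > 64L
  if (any(bad_len)) {
    stop("tag sequences must be 1-64 bases long (got length ",
         nchar(seq)[which(bad_len)[1]], ")")
  }
  if (any(grepl("[^ACGT]", seq))) {
    stop("tag sequences may contain only A/C/G/T ",
         "(ambiguous bases such as N are rejected)")
  }
  invisible(seq)
}

#' Canonical tag ordering
#'
#' The total order over tags is the lexicographic order of the packed
#' two-bit payload (equivalently, of the sequence padded to 64 bases with
#' `A`), ties broken by tag length. This ordering is deterministic, does not
#' depend on locale, and is the iteration order of every tag-keyed table in
#' the pipeline.
#'
#' @param seq Character vector of tag sequences.
#' @return `tag_order()` returns an integer permutation (as [order()]);
#'   `sort_tags()` the sorted sequences.
#' @export
tag_order <- function(seq) {
  key <- stringr::str_pad(chartr("ACGT", "0123", seq), 64L,
                          side = "right", pad = "0")
  order(key, nchar(seq), method = "radix")
}

#' @rdname tag_order
#' @export
sort_tags <- function(seq) seq[tag_order(seq)]

hex_to_raw <- function(hex) {
  ## one concatenated raw vector, 16 bytes per element of `hex`
  pairs <- unlist(strsplit(gsub("(..)", "\\1 ", paste(hex, collapse = "")),
                           " ", fixed = TRUE))
  as.raw(strtoi(pairs[pairs != ""], 16L))
}

raw_to_hex <- function(raw) {
  hx <- format(raw)  # two lowercase hex chars per byte
  apply(matrix(hx, nrow = 16L), 2L, paste, collapse = "")
}
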
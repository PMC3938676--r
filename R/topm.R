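#' Tags on the physical map (TOPM)
#'
#' The TOPM holds one entry for every master tag: the tag itself, its
#' alignment status (`UNIQUE` / `MULTIPLE` / `UNALIGNED`), and for uniquely
#' placed tags the reference position of the cut-site end of the tag. All
#' master tags are retained, even unplaced ones, so positional evidence can
#' be added later. After SNP discovery each useful tag also carries its
#' variants (alignment offset + allele). The table is sorted by tag and acts
#' as a key-value map; a position-ordered view over the `UNIQUE` entries is
#' available through [topm_by_position()].
#'
#' `import_sam()` builds a TOPM from a SAM file of master-tag alignments
#' (read IDs as written by [export_master_fastq()]). A tag is `UNIQUE` iff
#' its primary alignment is mapped with MAPQ >= `mapq_min` and no secondary
#' alignment achieves an equal alignment score (`AS`/`XS` tags when the
#' aligner emits them; with no score tags, MAPQ 0 on a mapped record means
#' `MULTIPLE`). For minus-strand alignments the recorded `cut_pos` is the
#' rightmost aligned reference coordinate, so the cut site that starts every
#' tag maps to a consistent coordinate on either strand.
#'
#' @param sam Path to a SAM file (with header) covering the master tags.
#' @param master The exported master tag list (`gbs_tagcounts`).
#' @param mapq_min Minimum MAPQ for a unique placement (default 0).
#' @param max_variants Maximum variants recorded per tag (default 8).
#' @return A `gbs_topm`: tibble with columns `tag`, `status`, `chrom`,
#'   `strand`, `cut_pos`, `variants` (list of tibbles `offset`, `allele`),
#'   sorted by tag; attribute `sites` carries the SNP registry after
#'   discovery.
#' @export
import_sam <- function(sam, master, mapq_min = 0L, max_variants = 8L) {
  stopifnot(nrow(master) > 0L)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    tag = c("AS", "XS")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  qidx <- parse_master_read_id(rec$qname)
  if (any(qidx < 1L | qidx > nrow(master))) {
    stop("SAM read ID refers to a tag index outside the master list")
  }
  flag <- rec$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L

  n <- nrow(master)
  status <- rep("UNALIGNED", n)
  chrom <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  cut_pos <- rep(NA_integer_, n)

  prim <- which(!secondary & mapped)
  sec_idx <- which(secondary & mapped)
  sec_map <- split(sec_idx, qidx[sec_idx])
  for (i in prim) {
    t <- qidx[i]
    mq <- rec$mapq[i]
    as_score <- rec$tag$AS[i]
    xs_score <- rec$tag$XS[i]
    if (!is.null(as_score) && !is.na(as_score) &&
        !is.null(xs_score) && !is.na(xs_score) && xs_score >= as_score) {
      status[t] <- "MULTIPLE"
      next
    }
    ## equal-score secondary records for the same tag => MULTIPLE
    sec <- sec_map[[as.character(t)]]
    if (!is.null(as_score) && !is.na(as_score) && length(sec)) {
      sec_as <- rec$tag$AS[sec]
      if (any(!is.na(sec_as) & sec_as >= as_score)) {
        status[t] <- "MULTIPLE"
        next
      }
    }
    if ((is.null(as_score) || is.na(as_score)) && !is.na(mq) && mq == 0L) {
      status[t] <- "MULTIPLE"
      next
    }
    if (!is.na(mq) && mq < mapq_min) next  # stays UNALIGNED
    status[t] <- "UNIQUE"
    chrom[t] <- as.character(rec$rname[i])
    str <- as.character(rec$strand[i])
    strand[t] <- str
    rw <- cigar_ref_width(rec$cigar[i])
    cut_pos[t] <- if (str == "-") rec$pos[i] + rw - 1L else rec$pos[i]
  }
  new_topm(tibble::tibble(
    tag = master$tag, status = status, chrom = chrom,
    strand = strand, cut_pos = cut_pos,
    variants = rep(list(empty_variants()), n)
  ), max_variants = max_variants)
}

empty_variants <- function() tibble::tibble(offset = integer(),
                                            allele = character())

new_topm <- function(entries, max_variants = 8L, sites = NULL) {
  entries <- entries[tag_order(entries$tag), ]
  structure(entries,
            class = c("gbs_topm", class(tibble::as_tibble(entries))),
            max_variants = max_variants, sites = sites)
}

cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) return(0L)
  len <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("[0-9]+", "", ops)
  as.integer(sum(len[op %in% c("M", "D", "N", "=", "X")]))
}

#' @param topm A `gbs_topm`.
#' @param tags Tag sequences to look up (exact match on sequence + length).
#' @return `topm_lookup()` returns the matching entries (zero rows for
#'   misses; a miss is not an error). `topm_by_position()` returns the
#'   `UNIQUE` entries ordered by `(chrom, cut_pos, strand)`.
#' @rdname import_sam
#' @export
topm_lookup <- function(topm, tags) {
  idx <- match(tags, topm$tag)
  tibble::as_tibble(topm)[idx[!is.na(idx)], ]
}

#' @rdname import_sam
#' @export
topm_by_position <- function(topm) {
  uni <- tibble::as_tibble(topm)[topm$status == "UNIQUE", ]
  uni[order(uni$chrom, uni$cut_pos, uni$strand, method = "radix"), ]
}

#' Record the variants carried by a tag
#'
#' For each retained SNP, the allele represented by each tag in the
#' corresponding TagLocus is recorded in the TOPM together with its relative
#' position (0-based alignment column) in the locus. Re-annotating a tag
#' replaces its variant list.
#'
#' @param topm A `gbs_topm`.
#' @param tag A single tag sequence with `UNIQUE` status.
#' @param variants Tibble/data frame with columns `offset` (0-based,
#'   strictly increasing) and `allele` (one of A, C, G, T, `-`).
#' @return The updated `gbs_topm`.
#' @export
annotate_variants <- function(topm, tag, variants) {
  i <- match(tag, topm$tag)
  if (is.na(i)) stop("tag not present in the TOPM")
  if (topm$status[i] != "UNIQUE") {
    stop("variants can only be annotated on UNIQUE tags (tag is ",
         topm$status[i], ")")
  }
  variants <- tibble::as_tibble(variants)[, c("offset", "allele")]
  maxv <- attr(topm, "max_variants")
  if (nrow(variants) > maxv) {
    stop("too many variants for one tag (", nrow(variants), " > ",
         maxv, ")")
  }
  if (nrow(variants) > 1L && any(diff(variants$offset) <= 0L)) {
    stop("variant offsets must be strictly increasing")
  }
  if (!all(variants$allele %in% c("A", "C", "G", "T", "-"))) {
    stop("alleles must be A, C, G, T or '-'")
  }
  variants$offset <- as.integer(variants$offset)
  topm$variants[[i]] <- variants
  topm
}

STATUS_CODES <- c(UNIQUE = 1L, MULTIPLE = 2L, UNALIGNED = 3L)
ALLELE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L, `-` = 4L)

#' Persist a TOPM
#'
#' Three content-identical, round-trippable forms: tab-separated text
#' (`"tsv"`; variants encoded `offset:allele` joined by `;`, the site
#' registry in a `<path>.sites` companion file), a documented little-endian
#' binary (`"binary"`), and a structured serialized container (`"rds"`).
#'
#' @param topm A `gbs_topm`.
#' @param path Output path.
#' @param format `"binary"`, `"tsv"` or `"rds"`.
#' @return `read_topm()` returns the `gbs_topm`.
#' @export
write_topm <- function(topm, path, format = c("binary", "tsv", "rds")) {
  format <- match.arg(format)
  sites <- attr(topm, "sites")
  if (format == "rds") {
    saveRDS(list(entries = tibble::as_tibble(topm),
                 max_variants = attr(topm, "max_variants"),
                 sites = sites), path)
    return(invisible(path))
  }
  if (format == "tsv") {
    var_str <- vapply(topm$variants, function(v) {
      if (nrow(v) == 0L) "" else paste(v$offset, v$allele,
                                       sep = ":", collapse = ";")
    }, character(1))
    df <- data.frame(tag = topm$tag, status = topm$status,
                     chrom = ifelse(is.na(topm$chrom), "", topm$chrom),
                     strand = ifelse(is.na(topm$strand), "", topm$strand),
                     cut_pos = ifelse(is.na(topm$cut_pos), "", topm$cut_pos),
                     variants = var_str)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sites)) {
      utils::write.table(as.data.frame(sites), paste0(path, ".sites"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GBTM"), con)
  writeBin(1L, con, size = 1L)
  writeBin(as.integer(attr(topm, "max_variants")), con, size = 1L)
  writeBin(nrow(topm), con, size = 4L, endian = "little")
  enc <- encode_tags(topm$tag)
  payload <- hex_to_raw(enc$packed)
  dim(payload) <- c(16L, nrow(topm))
  wstr <- function(s) {
    r <- charToRaw(if (is.na(s)) "" else s)
    writeBin(length(r), con, size = 1L)
    if (length(r)) writeBin(r, con)
  }
  for (i in seq_len(nrow(topm))) {
    writeBin(payload[, i], con)
    writeBin(enc$length[i], con, size = 1L)
    writeBin(STATUS_CODES[[topm$status[i]]], con, size = 1L)
    wstr(topm$chrom[i])
    st <- topm$strand[i]
    writeBin(if (is.na(st)) 0L else if (st == "+") 1L else 2L, con, size = 1L)
    writeBin(if (is.na(topm$cut_pos[i])) -1L else topm$cut_pos[i], con,
             size = 4L, endian = "little")
    v <- topm$variants[[i]]
    writeBin(nrow(v), con, size = 1L)
    if (nrow(v)) {
      for (j in seq_len(nrow(v))) {
        writeBin(v$offset[j], con, size = 1L)
        writeBin(ALLELE_CODES[[v$allele[j]]], con, size = 1L)
      }
    }
  }
  ## site registry
  if (is.null(sites)) {
    writeBin(-1L, con, size = 4L, endian = "little")
  } else {
    writeBin(nrow(sites), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(sites))) {
      wstr(sites$chrom[i])
      writeBin(if (sites$strand[i] == "+") 1L else 2L, con, size = 1L)
      writeBin(as.integer(sites$cut_pos[i]), con, size = 4L, endian = "little")
      writeBin(as.integer(sites$offset[i]), con, size = 1L)
      writeBin(as.integer(sites$pos[i]), con, size = 4L, endian = "little")
      wstr(sites$alleles[i])
    }
  }
  invisible(path)
}

#' @rdname write_topm
#' @export
read_topm <- function(path, format = c("binary", "tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    return(new_topm(x$entries, max_variants = x$max_variants,
                    sites = x$sites))
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    variants <- lapply(df$variants, function(s) {
      if (is.na(s) || s == "") return(empty_variants())
      parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      tibble::tibble(offset = as.integer(vapply(parts, `[`, "", 1L)),
                     allele = vapply(parts, `[`, "", 2L))
    })
    sites <- NULL
    sp <- paste0(path, ".sites")
    if (file.exists(sp)) {
      sites <- tibble::as_tibble(utils::read.delim(sp,
                                                   stringsAsFactors = FALSE))
      sites$site_id <- as.character(sites$site_id)
    }
    return(new_topm(tibble::tibble(
      tag = df$tag, status = df$status,
      chrom = ifelse(df$chrom == "", NA_character_, df$chrom),
      strand = ifelse(df$strand == "", NA_character_, df$strand),
      cut_pos = suppressWarnings(as.integer(df$cut_pos)),
      variants = variants
    ), sites = sites))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "GBTM") {
    stop("not a gbstag TOPM binary file: ", path)
  }
  ver <- readBin(con, "integer", 1L, size = 1L)
  if (ver != 1L) stop("unsupported TOPM version: ", ver)
  maxv <- readBin(con, "integer", 1L, size = 1L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rstr <- function() {
    L <- readBin(con, "integer", 1L, size = 1L)
    if (L == 0L) NA_character_ else rawToChar(readBin(con, "raw", L))
  }
  tag <- character(n); status <- character(n); chrom <- character(n)
  strand <- character(n); cut_pos <- integer(n); variants <- vector("list", n)
  for (i in seq_len(n)) {
    packed <- paste(format(readBin(con, "raw", 16L)), collapse = "")
    len <- readBin(con, "integer", 1L, size = 1L)
    tag[i] <- decode_tags(packed, len)
    status[i] <- names(STATUS_CODES)[readBin(con, "integer", 1L, size = 1L)]
    chrom[i] <- rstr()
    sc <- readBin(con, "integer", 1L, size = 1L)
    strand[i] <- if (sc == 0L) NA_character_ else c("+", "-")[sc]
    cp <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    cut_pos[i] <- if (cp < 0L) NA_integer_ else cp
    nv <- readBin(con, "integer", 1L, size = 1L)
    if (nv > 0L) {
      off <- integer(nv); all <- character(nv)
      for (j in seq_len(nv)) {
        off[j] <- readBin(con, "integer", 1L, size = 1L)
        all[j] <- names(ALLELE_CODES)[readBin(con, "integer", 1L,
                                              size = 1L) + 1L]
      }
      variants[[i]] <- tibble::tibble(offset = off, allele = all)
    } else {
      variants[[i]] <- empty_variants()
    }
  }
  ns <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sites <- NULL
  if (ns >= 0L) {
    sites <- tibble::tibble(chrom = character(ns), strand = character(ns),
                            cut_pos = integer(ns), offset = integer(ns),
                            pos = integer(ns), alleles = character(ns))
    for (i in seq_len(ns)) {
      sites$chrom[i] <- rstr()
      sites$strand[i] <- c("+", "-")[readBin(con, "integer", 1L, size = 1L)]
      sites$cut_pos[i] <- readBin(con, "integer", 1L, size = 4L,
                                  endian = "little")
      sites$offset[i] <- readBin(con, "integer", 1L, size = 1L)
      sites$pos[i] <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      sites$alleles[i] <- rstr()
    }
    sites <- finish_site_registry(sites)
  }
  new_topm(tibble::tibble(tag = tag, status = status, chrom = chrom,
                          strand = strand, cut_pos = cut_pos,
                          variants = variants),
           max_variants = maxv, sites = sites)
}

## derive the redundant registry columns (ids, major/minor) from the core
finish_site_registry <- function(sites) {
  al <- strsplit(sites$alleles, ",", fixed = TRUE)
  sites$major <- vapply(al, `[`, "", 1L)
  sites$minor <- vapply(al, `[`, "", 2L)
  sites$site_id <- paste0("S", sites$chrom, "_", sites$pos)
  sites
}
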
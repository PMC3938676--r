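#' Genotype tables
#'
#' The final product of either pipeline: taxa x sites genotype calls plus
#' the allele depths they were called from. Genotypes are stored as integer
#' codes relative to the site's allele pair (0 = homozygous major, 1 =
#' heterozygous, 2 = homozygous minor, `NA` = missing); sites are sorted by
#' `(chrom, pos)` and a genotype is missing iff its total called-allele
#' depth is zero.
#'
#' @param sites Tibble with columns `site_id`, `chrom`, `pos`, `major`,
#'   `minor`, `alleles`.
#' @param taxa Character vector of taxon names.
#' @param geno Integer matrix `[site, taxon]` of codes 0/1/2/NA.
#' @param d_major,d_minor Numeric matrices `[site, taxon]` of allele read
#'   depths (optional).
#' @param report Optional bookkeeping list.
#' @return Object of class `gbs_genotypes`.
#' @export
new_genotypes <- function(sites, taxa, geno, d_major = NULL, d_minor = NULL,
                          report = NULL) {
  sites <- tibble::as_tibble(sites)
  ord <- order(sites$chrom, sites$pos, method = "radix")
  sites <- sites[ord, ]
  geno <- matrix(as.integer(geno), nrow = nrow(geno), ncol = ncol(geno),
                 dimnames = list(NULL, taxa))[ord, , drop = FALSE]
  norm_depth <- function(d) {
    if (is.null(d)) return(NULL)
    matrix(as.numeric(d), nrow = nrow(d), ncol = ncol(d),
           dimnames = list(NULL, taxa))[ord, , drop = FALSE]
  }
  d_major <- norm_depth(d_major)
  d_minor <- norm_depth(d_minor)
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == length(taxa))
  structure(list(sites = sites, taxa = taxa, geno = geno,
                 d_major = d_major, d_minor = d_minor, report = report),
            class = "gbs_genotypes")
}

#' @export
print.gbs_genotypes <- function(x, ...) {
  cat("<gbs_genotypes> ", nrow(x$sites), " sites x ", length(x$taxa),
      " taxa; call rate ",
      sprintf("%.3f", mean(!is.na(x$geno))), "\n", sep = "")
  invisible(x)
}

#' Allele-pair representation of genotype calls
#'
#' Character matrix `[site, taxon]` of sorted allele pairs (`"A/G"`), `NA`
#' for missing — a representation independent of which allele happens to be
#' major, used to compare genotype tables across formats.
#' @param gt A `gbs_genotypes`.
#' @return Character matrix.
#' @export
genotype_alleles <- function(gt) {
  out <- matrix(NA_character_, nrow(gt$geno), ncol(gt$geno),
                dimnames = dimnames(gt$geno))
  for (i in seq_len(nrow(gt$geno))) {
    a <- gt$sites$major[i]; b <- gt$sites$minor[i]
    pair <- function(x, y) paste(sort(c(x, y)), collapse = "/")
    map <- c(pair(a, a), pair(a, b), pair(b, b))
    g <- gt$geno[i, ]
    out[i, !is.na(g)] <- map[g[!is.na(g)] + 1L]
  }
  out
}

IUPAC_HET <- c("A/C" = "M", "A/G" = "R", "A/T" = "W", "C/G" = "S",
               "C/T" = "Y", "G/T" = "K")

#' Write genotypes in HapMap format
#'
#' Standard 11 metadata columns (`rs#`, `alleles`, `chrom`, `pos`,
#' `strand`, `assembly#`, `center`, `protLSID`, `assayLSID`, `panelLSID`,
#' `QCcode`) followed by one single-letter genotype column per taxon:
#' homozygotes as the allele letter, heterozygotes as the IUPAC ambiguity
#' code, missing as `N`. Indel alleles use `+` (present) / `-` (deleted)
#' with `0` for the heterozygote.
#'
#' @param gt A `gbs_genotypes`.
#' @param path Output path (`.gz` allowed).
#' @return `path` invisibly; `read_hapmap()` returns a `gbs_genotypes`
#'   (without depths).
#' @export
write_hapmap <- function(gt, path) {
  stopifnot(nrow(gt$sites) > 0L)
  n_sites <- nrow(gt$sites)
  calls <- matrix("N", n_sites, length(gt$taxa))
  for (i in seq_len(n_sites)) {
    a <- gt$sites$major[i]; b <- gt$sites$minor[i]
    indel <- a == "-" || b == "-"
    if (indel) {
      base_sym <- function(x) if (x == "-") "-" else "+"
      map <- c(base_sym(a), "0", base_sym(b))
    } else {
      het <- IUPAC_HET[[paste(sort(c(a, b)), collapse = "/")]]
      map <- c(a, het, b)
    }
    g <- gt$geno[i, ]
    calls[i, !is.na(g)] <- map[g[!is.na(g)] + 1L]
  }
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              gt$taxa)
  meta <- cbind(gt$sites$site_id,
                paste(gt$sites$major, gt$sites$minor, sep = "/"),
                gt$sites$chrom, gt$sites$pos, "+", "NA", "NA", "NA", "NA",
                "NA", "NA")
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(cbind(meta, calls), 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_hapmap
#' @export
read_hapmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  taxa <- names(df)[-(1:11)]
  alleles <- strsplit(df$alleles, "/", fixed = TRUE)
  major <- vapply(alleles, `[`, "", 1L)
  minor <- vapply(alleles, `[`, "", 2L)
  geno <- matrix(NA_integer_, nrow(df), length(taxa))
  for (i in seq_len(nrow(df))) {
    a <- major[i]; b <- minor[i]
    if (a == "-" || b == "-") {
      sym <- function(x) if (x == "-") "-" else "+"
      map <- setNames(c(0L, 1L, 2L), c(sym(a), "0", sym(b)))
    } else {
      het <- IUPAC_HET[[paste(sort(c(a, b)), collapse = "/")]]
      map <- setNames(c(0L, 1L, 2L), c(a, het, b))
    }
    g <- unlist(df[i, -(1:11)], use.names = FALSE)
    geno[i, ] <- unname(map[g])
  }
  new_genotypes(
    tibble::tibble(site_id = df[[1]], chrom = df$chrom,
                   pos = as.integer(df$pos), major = major, minor = minor,
                   alleles = paste(major, minor, sep = ",")),
    taxa, geno)
}

#' Write genotypes in VCF 4.2 format with allele depths
#'
#' One sample field per taxon with `GT:AD`. The REF allele is taken from
#' the reference base at the site when a reference is supplied, otherwise
#' the major allele is used as REF (recorded in the header). Indel sites
#' are emitted anchored at the preceding reference base (anchor `N` when no
#' reference is available).
#'
#' @param gt A `gbs_genotypes` with depths.
#' @param path Output path (`.gz` allowed).
#' @param ref Optional reference (FASTA path or named character vector).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path, ref = NULL) {
  stopifnot(nrow(gt$sites) > 0L)
  refv <- if (!is.null(ref)) read_reference(ref) else NULL
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gbstag",
           sprintf("##gbstagRefSource=%s",
                   if (is.null(refv)) "major_allele" else "reference_fasta"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
                  'Description="Allelic depths (ref,alt)">'))
  if (!is.null(refv)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(refv),
                          nchar(refv)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gt$taxa),
                      collapse = "\t"))
  n_sites <- nrow(gt$sites)
  lines <- character(n_sites)
  dM <- gt$d_major
  dm <- gt$d_minor
  if (is.null(dM)) dM <- matrix(0L, n_sites, length(gt$taxa))
  if (is.null(dm)) dm <- matrix(0L, n_sites, length(gt$taxa))
  for (i in seq_len(n_sites)) {
    a <- gt$sites$major[i]; b <- gt$sites$minor[i]
    chrom <- gt$sites$chrom[i]; pos <- gt$sites$pos[i]
    indel <- a == "-" || b == "-"
    if (!indel) {
      rb <- if (!is.null(refv)) substr(refv[[chrom]], pos, pos) else a
      swap <- rb == b      # minor allele is the reference base
      refa <- if (swap) b else a
      alta <- if (swap) a else b
      out_pos <- pos
    } else {
      anchor <- if (!is.null(refv) && pos > 1L) {
        substr(refv[[chrom]], pos - 1L, pos - 1L)
      } else "N"
      base <- if (a == "-") b else a
      del_is_major <- a == "-"
      ## reference carries the base (deletions are derived alleles here)
      refa <- paste0(anchor, base)
      alta <- anchor
      swap <- del_is_major  # major allele (deletion) is ALT
      out_pos <- pos - 1L
    }
    g <- gt$geno[i, ]
    gt_str <- rep("./.", length(g))
    map <- if (!swap) c("0/0", "0/1", "1/1") else c("1/1", "0/1", "0/0")
    gt_str[!is.na(g)] <- map[g[!is.na(g)] + 1L]
    ad <- if (!swap) {
      paste(dM[i, ], dm[i, ], sep = ",")
    } else {
      paste(dm[i, ], dM[i, ], sep = ",")
    }
    lines[i] <- paste(c(chrom, out_pos, gt$sites$site_id[i], refa, alta,
                        ".", "PASS", ".", "GT:AD",
                        paste(gt_str, ad, sep = ":")),
                      collapse = "\t")
  }
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  writeLines(c(hdr, lines), con)
  close(con)
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' Parses with the vcfR package; biallelic records only. REF is taken as
#' the major allele and ALT as the minor (the orientation information of
#' the writer is not reconstructed).
#'
#' @param path VCF path (`.gz` allowed).
#' @return A `gbs_genotypes` with depths when `AD` is present.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops dims
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- t(gt_raw)
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                     error = function(e) NULL)
  if (!is.null(ad_raw) && is.null(dim(ad_raw))) ad_raw <- t(ad_raw)
  taxa <- colnames(gt_raw)
  code <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  code[gt_raw %in% c("0/0", "0|0")] <- 0L
  code[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt_raw %in% c("1/1", "1|1")] <- 2L
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  pos <- as.integer(fix[, "POS"])
  major <- ref; minor <- alt
  ## undo indel anchoring: REF "Nx"/ALT "N" style pairs
  indel <- nchar(ref) > 1L | nchar(alt) > 1L
  if (any(indel)) {
    for (i in which(indel)) {
      if (nchar(ref[i]) > nchar(alt[i])) {  # deletion allele in ALT
        major[i] <- substr(ref[i], 2L, 2L)
        minor[i] <- "-"
        pos[i] <- pos[i] + 1L
      } else {
        major[i] <- "-"
        minor[i] <- substr(alt[i], 2L, 2L)
        pos[i] <- pos[i] + 1L
      }
    }
  }
  d_major <- d_minor <- NULL
  if (!is.null(ad_raw)) {
    sp <- strsplit(ad_raw, ",", fixed = TRUE)
    d_major <- matrix(as.numeric(vapply(sp, `[`, "", 1L)), nrow(gt_raw))
    d_minor <- matrix(as.numeric(vapply(sp, `[`, "", 2L)), nrow(gt_raw))
  }
  new_genotypes(
    tibble::tibble(site_id = fix[, "ID"], chrom = fix[, "CHROM"],
                   pos = pos, major = major, minor = minor,
                   alleles = paste(major, minor, sep = ",")),
    taxa, code, d_major, d_minor)
}
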
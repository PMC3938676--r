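#' Tidiers for pipeline objects
#'
#' `tidy()` returns a long tibble of the object's content; `glance()` a
#' one-row summary.
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name gbstag-tidiers
NULL

#' @rdname gbstag-tidiers
#' @export
tidy.gbs_tbt <- function(x, ...) {
  nz <- which(x$depth > 0L, arr.ind = TRUE)
  tibble::tibble(tag = x$tags[nz[, 1L]], taxon = x$taxa[nz[, 2L]],
                 depth = x$depth[nz])
}

#' @rdname gbstag-tidiers
#' @export
glance.gbs_tbt <- function(x, ...) {
  tibble::tibble(
    n_tags = length(x$tags), n_taxa = length(x$taxa),
    total_depth = sum(x$depth), sparsity = mean(x$depth == 0L),
    max_depth = if (length(x$depth)) max(x$depth) else NA_integer_)
}

#' @rdname gbstag-tidiers
#' @export
tidy.gbs_genotypes <- function(x, ...) {
  g <- x$geno
  out <- tibble::tibble(
    site_id = rep(x$sites$site_id, times = ncol(g)),
    taxon = rep(x$taxa, each = nrow(g)),
    genotype = as.integer(g))
  if (!is.null(x$d_major)) {
    out$depth_major <- as.numeric(x$d_major)
    out$depth_minor <- as.numeric(x$d_minor)
  }
  out
}

#' @rdname gbstag-tidiers
#' @export
glance.gbs_genotypes <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites), n_taxa = length(x$taxa),
    call_rate = mean(!is.na(x$geno)),
    het_rate = mean(x$geno == 1L, na.rm = TRUE))
}

#' @rdname gbstag-tidiers
#' @export
tidy.gbs_discovery <- function(x, ...) x$sites

#' @rdname gbstag-tidiers
#' @export
glance.gbs_discovery <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$report),
    n_candidates = nrow(x$sites),
    n_retained = sum(x$sites$retained),
    mean_maf = mean(x$sites$maf[x$sites$retained], na.rm = TRUE),
    mean_f_it = mean(x$sites$f_it[x$sites$retained], na.rm = TRUE))
}

#' @rdname gbstag-tidiers
#' @export
tidy.gbs_error_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname gbstag-tidiers
#' @export
glance.gbs_error_report <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(mean_rate = s$mean_rate, median_rate = s$median_rate,
                 pooled_rate = s$pooled_rate, n_snps_rated = s$n_snps_rated)
}

#' @export
print.gbs_topm <- function(x, ...) {
  cat("<gbs_topm> ", nrow(x), " tags (",
      sum(x$status == "UNIQUE"), " UNIQUE, ",
      sum(x$status == "MULTIPLE"), " MULTIPLE, ",
      sum(x$status == "UNALIGNED"), " UNALIGNED); ",
      sum(vapply(x$variants, nrow, 0L)), " variants\n", sep = "")
  invisible(x)
}

#' @export
print.gbs_tbt <- function(x, ...) {
  cat("<gbs_tbt> ", length(x$tags), " tags x ", length(x$taxa),
      " taxa; ", sprintf("%.1f%%", 100 * mean(x$depth == 0L)),
      " zero cells\n", sep = "")
  invisible(x)
}

#' @export
print.gbs_discovery <- function(x, ...) {
  cat("<gbs_discovery> ", nrow(x$sites), " candidate SNPs, ",
      sum(x$sites$retained), " retained across ", nrow(x$report),
      " tag loci\n", sep = "")
  invisible(x)
}
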
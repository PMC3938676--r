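#' Exact binomial test against 1:1 segregation
#'
#' Two-sided exact binomial test of a minor-allele count against the 1:1
#' segregation expected in a biparental family, computed by doubling the
#' smaller tail probability and capping at 1:
#' `p = min(1, 2 * P(X <= min(n_minor, n - n_minor)))` with
#' `X ~ Binomial(n, 1/2)`.
#'
#' @param n_minor Integer vector of minor-allele counts (0 <= n_minor <= n).
#' @param n Integer vector of family sizes (n >= 1).
#' @return Numeric vector of p-values.
#' @examples
#' binomial_segregation_test(0, 19)   # 2 * 0.5^19
#' binomial_segregation_test(10, 20)  # 1: perfect 1:1
#' @export
binomial_segregation_test <- function(n_minor, n) {
  if (any(n < 1) || any(n_minor < 0) || any(n_minor > n)) {
    stop("need 0 <= n_minor <= n and n >= 1")
  }
  k <- pmin(n_minor, n - n_minor)
  pmin(1, 2 * pbinom(k, n, 0.5))
}

#' Estimate per-SNP genotyping error rates from biparental families
#'
#' In an F2-derived RIL family a truly segregating SNP shows ~1:1 allele
#' frequencies, while a non-segregating SNP should be monomorphic; minor
#' allele calls at SNPs that are weakly polymorphic within a family *and*
#' significantly distorted from 1:1 are therefore genotyping errors. For
#' every SNP x family with at least `min_n` non-missing calls, the
#' family-specific allele frequency is computed from the calls
#' (heterozygotes count half toward each allele) and the minor-genotype
#' count `round(MAF * n)` is tested against `Binomial(n, 1/2)`.
#' Minor-allele calls are classified as errors iff `0 < MAF < maf_upper`
#' and the family deviates from 1:1 at `p < alpha`; the SNP's error rate is
#' the total number of error calls divided by the total number of calls in
#' deviating families (monomorphic families included — zero MAF trivially
#' deviates at the default `min_n`).
#'
#' @param gt A `gbs_genotypes`.
#' @param families Tibble `taxon`, `family` (see [read_family_file()]) or a
#'   named character vector (names = taxa).
#' @param min_n Minimum non-missing calls per SNP x family (default 19).
#' @param maf_upper Family MAF upper bound for error classification
#'   (default 0.25).
#' @param alpha Segregation-distortion significance level (default 0.001).
#' @return Object of class `gbs_error_report`: tibble with one row per SNP
#'   (`site_id`, `n_families_tested`, `n_error_calls`,
#'   `n_total_calls_deviating`, `error_rate`; rate `NA` when no family
#'   deviates); attributes `summary` (mean/median/pooled rates) and
#'   `segregating_by_family` (per-family counts of SNPs with family allele
#'   frequency in [0.25, 0.75]).
#' @export
estimate_error_rates <- function(gt, families, min_n = 19L,
                                 maf_upper = 0.25, alpha = 0.001) {
  if (is.data.frame(families)) {
    fam <- setNames(as.character(families$family), families$taxon)
  } else {
    fam <- families
  }
  unknown <- setdiff(names(fam), gt$taxa)
  if (length(unknown)) {
    stop("family assignment names taxa absent from the genotype table: ",
         unknown[1])
  }
  fam_levels <- unique(unname(fam))
  cols <- lapply(fam_levels, function(f) match(names(fam)[fam == f], gt$taxa))
  n_sites <- nrow(gt$sites)
  n_err <- integer(n_sites)
  n_denom <- integer(n_sites)
  n_tested <- integer(n_sites)
  seg_count <- setNames(integer(length(fam_levels)), fam_levels)
  any_qualifying <- FALSE
  for (fi in seq_along(fam_levels)) {
    g <- gt$geno[, cols[[fi]], drop = FALSE]
    n <- rowSums(!is.na(g))
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    ok <- n >= min_n
    if (!any(ok)) next
    any_qualifying <- TRUE
    n_tested[ok] <- n_tested[ok] + 1L
    f2 <- (2 * n2 + n1) / (2 * n)           # family freq of the site minor
    maf <- pmin(f2, 1 - f2)
    m <- as.integer(round(maf * n))
    p <- rep(NA_real_, n_sites)
    p[ok] <- binomial_segregation_test(m[ok], n[ok])
    deviating <- ok & !is.na(p) & p < alpha
    ## calls carrying the family-specific minor allele
    minor_calls <- ifelse(f2 <= 0.5, n2 + n1, n0 + n1)
    err <- deviating & maf > 0 & maf < maf_upper
    n_err[err] <- n_err[err] + minor_calls[err]
    n_denom[deviating] <- n_denom[deviating] + n[deviating]
    seg_count[fi] <- sum(ok & f2 >= 0.25 & f2 <= 0.75)
  }
  if (!any_qualifying) {
    stop("no SNP x family combination reaches min_n = ", min_n)
  }
  rate <- ifelse(n_denom > 0L, n_err / n_denom, NA_real_)
  out <- tibble::tibble(
    site_id = gt$sites$site_id,
    n_families_tested = n_tested,
    n_error_calls = as.integer(n_err),
    n_total_calls_deviating = as.integer(n_denom),
    error_rate = rate
  )
  class(out) <- c("gbs_error_report", class(out))
  attr(out, "summary") <- list(
    mean_rate = mean(rate, na.rm = TRUE),
    median_rate = median(rate, na.rm = TRUE),
    pooled_rate = if (sum(n_denom) > 0) sum(n_err) / sum(n_denom) else NA_real_,
    n_snps_rated = sum(!is.na(rate))
  )
  attr(out, "segregating_by_family") <- seg_count
  out
}

#' Read a family assignment file
#' @param path Tab-delimited file with header columns `Taxon`, `Family`.
#' @return Tibble `taxon`, `family`.
#' @export
read_family_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("Taxon", "Family") %in% names(df))) {
    stop("family file must have columns Taxon and Family")
  }
  tibble::tibble(taxon = df$Taxon, family = df$Family)
}

#' Write an error-rate report as TSV
#' @param report A `gbs_error_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- attr(report, "summary")
  cat(sprintf("# mean_rate\t%.6g\n# median_rate\t%.6g\n# pooled_rate\t%.6g\n",
              s$mean_rate, s$median_rate, s$pooled_rate),
      file = path, append = TRUE)
  invisible(path)
}
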
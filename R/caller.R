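#' Binomial likelihood-ratio genotype calling
#'
#' Quantitative SNP calling from the depths of the two most frequent
#' alleles at a site. Three hypotheses are compared with exact binomial
#' likelihoods at `n = depth_major + depth_minor`:
#' homozygous-major (`L = Binom(depth_minor | n, e)` — minor reads are
#' sequencing errors), homozygous-minor (`L = Binom(depth_major | n, e)`),
#' and heterozygous (`L = Binom(depth_major | n, 1/2)`), where `e` is the
#' per-base sequencing error rate. The maximum-likelihood genotype is
#' called; when the best homozygous likelihood is within a factor
#' `lr_threshold` of the heterozygous likelihood the heterozygote is called
#' (the conservative choice; the default `lr_threshold = 1` is pure maximum
#' likelihood with ties going to the heterozygote). Zero total depth is a
#' missing call.
#'
#' @param depth_major,depth_minor Non-negative integer vectors of read
#'   depths for the major and minor allele (recycled to a common length).
#' @param err Per-base sequencing error rate, in (0, 0.5).
#' @param lr_threshold Likelihood-ratio threshold favouring heterozygote
#'   calls (>= 1).
#' @return Integer vector of genotype codes: `0` homozygous major, `1`
#'   heterozygous, `2` homozygous minor, `NA` missing.
#' @examples
#' call_genotypes(5, 0)   # homozygous major
#' call_genotypes(3, 3)   # heterozygous
#' call_genotypes(0, 0)   # missing
#' @export
call_genotypes <- function(depth_major, depth_minor, err = 0.01,
                           lr_threshold = 1) {
  if (any(depth_major < 0) || any(depth_minor < 0)) {
    stop("depths must be non-negative")
  }
  stopifnot(err > 0, err < 0.5, lr_threshold >= 1)
  k <- vctrs_recycle(depth_major, depth_minor)
  dM <- k[[1]]; dm <- k[[2]]
  n <- dM + dm
  ll_homM <- dbinom(dm, n, err, log = TRUE)
  ll_homm <- dbinom(dM, n, err, log = TRUE)
  ll_het <- dbinom(dM, n, 0.5, log = TRUE)
  ll_hom_best <- pmax(ll_homM, ll_homm)
  out <- ifelse(ll_hom_best <= ll_het + log(lr_threshold), 1L,
                ifelse(ll_homM >= ll_homm, 0L, 2L))
  out[n == 0] <- NA_integer_
  as.integer(out)
}

vctrs_recycle <- function(a, b) {
  n <- max(length(a), length(b))
  list(rep_len(a, n), rep_len(b, n))
}
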
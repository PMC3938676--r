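mk_tag <- function(body) paste0("CAGC", body)

loose_filters <- discovery_filters(min_maf = 0.001, min_fit = -Inf,
                                   min_locus_coverage = 0)

test_that("tag loci partition UNIQUE tags by (chrom, strand, cut_pos)", {
  tags <- sort_tags(c(mk_tag(strrep("A", 16)), mk_tag(strrep("C", 16)),
                      mk_tag(strrep("G", 16)), mk_tag(strrep("T", 16)),
                      mk_tag("ACACACACACACACAC"),
                      mk_tag("GTGTGTGTGTGTGTGT"),
                      mk_tag("AACCAACCAACCAACC"),
                      mk_tag("TTGGTTGGTTGGTTGG"),
                      mk_tag("AGAGAGAGAGAGAGAG"),
                      mk_tag("CTCTCTCTCTCTCTCT")))
  topm <- make_topm(
    tags,
    status = c(rep("UNIQUE", 8), "MULTIPLE", "UNALIGNED"),
    chrom = c(rep("ctg", 8), NA, NA),
    strand = c(rep("+", 5), "-", "+", "+", NA, NA),
    cut_pos = c(rep(100L, 5), 100L, 300L, 300L, NA, NA))
  loci <- group_tag_loci(topm)
  expect_identical(nrow(loci), 3L)
  expect_identical(sort(lengths(loci$tags)), c(1L, 2L, 5L))
  # same cut position, opposite strand: distinct loci
  expect_identical(sum(loci$cut_pos == 100L), 2L)
  # non-UNIQUE tags appear in no locus
  expect_false(any(c(tags[9], tags[10]) %in% unlist(loci$tags)))
})

test_that("discovery calls genotypes from summed member-tag depths", {
  body1 <- "AAAATTTTCCCCGGGG"
  body2 <- "AAAATTTTCCACGGGG"  # one substitution (offset 14 in the tag)
  tags <- sort_tags(c(mk_tag(body1), mk_tag(body2)))
  topm <- make_topm(tags, "UNIQUE", "ctg", "+", 100L)
  depth <- matrix(0L, 2, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  depth[match(mk_tag(body1), tags), ] <- c(4L, 0L, 2L)
  depth[match(mk_tag(body2), tags), ] <- c(0L, 4L, 2L)
  tbt <- make_tbt(tags, c("t1", "t2", "t3"), depth)
  disc <- run_discovery(topm, tbt, filters = loose_filters)
  expect_identical(nrow(disc$sites), 1L)
  s <- disc$sites
  expect_identical(s$offset, 14L)
  expect_identical(s$pos, 114L)
  g <- disc$genotypes$geno[1, ]
  hom1 <- g[["t1"]]; hom2 <- g[["t2"]]
  expect_identical(sort(c(hom1, hom2)), c(0L, 2L))  # opposite homozygotes
  expect_identical(g[["t3"]], 1L)
  # allele-depth conservation per taxon
  tot <- disc$genotypes$d_major[1, ] + disc$genotypes$d_minor[1, ]
  expect_identical(unname(tot), unname(as.numeric(colSums(depth))))
})

test_that("a locus of identical tag content yields no candidates", {
  tags <- mk_tag(strrep("A", 16))
  topm <- make_topm(tags, "UNIQUE", "ctg", "+", 100L)
  tbt <- make_tbt(tags, c("t1", "t2"),
                  matrix(c(3L, 4L), 1, 2, dimnames = list(NULL,
                                                          c("t1", "t2"))))
  disc <- run_discovery(topm, tbt, filters = loose_filters)
  expect_identical(nrow(disc$sites), 0L)
})

test_that("triallelic columns keep all alleles but call on the top two", {
  bodies <- c("AAAATTTTCCCCGGGG", "AAAATTTTCACCGGGG", "AAAATTTTCGCCGGGG")
  tags <- sort_tags(mk_tag(bodies))
  topm <- make_topm(tags, "UNIQUE", "ctg", "+", 100L)
  depth <- matrix(0L, 3, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  depth[match(mk_tag(bodies[1]), tags), ] <- c(6L, 0L, 0L)
  depth[match(mk_tag(bodies[2]), tags), ] <- c(0L, 4L, 0L)
  depth[match(mk_tag(bodies[3]), tags), ] <- c(0L, 0L, 2L)
  tbt <- make_tbt(tags, c("t1", "t2", "t3"), depth)
  disc <- run_discovery(topm, tbt, filters = loose_filters)
  expect_identical(nrow(disc$sites), 1L)
  alleles <- strsplit(disc$sites$alleles, ",")[[1]]
  expect_length(alleles, 3L)
  expect_identical(alleles[1:2], c("C", "A"))  # by depth: 6, 4, 2
  g <- disc$genotypes$geno[1, ]
  expect_identical(unname(g), c(0L, 2L, NA_integer_))  # third allele only
})

test_that("site statistics reproduce the defining arithmetic", {
  # 8 inbreds: 6 hom-major, 2 hom-minor, no het
  s <- compute_site_stats(c(rep(0L, 6), rep(2L, 2)), rep(5, 8),
                          inbred = rep(TRUE, 8))
  expect_equal(s$maf, 0.25)
  expect_equal(s$ho, 0)
  expect_equal(s$f_it, 1)

  # 1 het + 1 deep minor homozygote + 2 hom-major:
  # score = 1 / (1 + 1 + 0.5) = 0.4
  s2 <- compute_site_stats(c(0L, 0L, 1L, 2L), c(5, 5, 4, 3),
                           inbred = rep(TRUE, 4))
  expect_identical(s2$n_inbred_hets, 1L)
  expect_identical(s2$n_inbreds_gt1_homo_min, 1L)
  expect_equal(s2$inbred_het_score, 0.4)
  # a depth-1 minor homozygote does not enter the score denominator
  s3 <- compute_site_stats(c(0L, 0L, 1L, 2L), c(5, 5, 4, 1),
                           inbred = rep(TRUE, 4))
  expect_identical(s3$n_inbreds_gt1_homo_min, 0L)

  # Hardy-Weinberg genotypes: Ho == He, F_IT = 0
  s4 <- compute_site_stats(c(0L, 1L, 1L, 2L), rep(5, 4),
                           inbred = rep(TRUE, 4))
  expect_equal(s4$f_it, 0)

  # a monomorphic subpopulation has undefined F_IT
  s5 <- compute_site_stats(rep(0L, 5), rep(5, 5), inbred = rep(TRUE, 5))
  expect_true(is.na(s5$f_it))
})

test_that("the filter clauses use the stated strict/non-strict forms", {
  base <- tibble::tibble(
    locus_coverage = 0.5, maf = 0.25, ho = 0, he = 0.375, f_it = 1,
    inbred_coverage = 0.5, n_inbred_hets = 0L, n_inbreds_gt1_homo_min = 2L,
    inbred_het_score = 0, n_called = 10L)
  flt <- discovery_filters()

  ok <- filter_snps(base, flt, has_pedigree = TRUE)
  expect_true(ok$retained)

  low_maf <- base; low_maf$maf <- 0.0005
  expect_false(filter_snps(low_maf, flt, TRUE)$retained)
  expect_match(filter_snps(low_maf, flt, TRUE)$reject_reason, "maf")
  # MAF exactly at the threshold passes (>=)
  at_maf <- base; at_maf$maf <- 0.001
  expect_true(filter_snps(at_maf, flt, TRUE)$retained)

  # paralog-like site: Ho = 1 at q = 0.5 gives F_IT = -1
  para <- base; para$maf <- 0.5; para$ho <- 1; para$he <- 0.5
  para$f_it <- 1 - 1 / 0.5
  expect_match(filter_snps(para, flt, TRUE)$reject_reason, "f_it")

  # inbred coverage is strict >; het score strict <
  at_cov <- base; at_cov$inbred_coverage <- 0.15
  expect_match(filter_snps(at_cov, flt, TRUE)$reject_reason,
               "inbred_coverage")
  at_score <- base; at_score$inbred_het_score <- 0.21
  expect_match(filter_snps(at_score, flt, TRUE)$reject_reason,
               "inbred_het_score")

  # undefined F_IT fails by convention
  nofit <- base; nofit$f_it <- NA_real_
  expect_false(filter_snps(nofit, flt, TRUE)$retained)

  # with every threshold at its weakest, everything is retained
  weak <- discovery_filters(min_maf = 0, min_fit = -Inf,
                            min_inbred_coverage = -Inf,
                            max_inbred_het_score = Inf,
                            min_locus_coverage = 0)
  expect_true(all(filter_snps(rbind(base, low_maf, para, at_cov, at_score),
                              weak, TRUE)$retained))
})

test_that("tightening any single threshold retains a subset", {
  set.seed(51)
  n <- 200
  stats <- tibble::tibble(
    locus_coverage = runif(n), maf = runif(n, 0, 0.5), ho = runif(n),
    he = runif(n, 0.01, 0.5), f_it = runif(n, -1, 1),
    inbred_coverage = runif(n), n_inbred_hets = rpois(n, 1),
    n_inbreds_gt1_homo_min = rpois(n, 2),
    inbred_het_score = runif(n, 0, 0.9), n_called = 20L)
  base <- discovery_filters(min_maf = 0.1, min_fit = 0.2,
                            min_inbred_coverage = 0.2,
                            max_inbred_het_score = 0.5,
                            min_locus_coverage = 0.2)
  r0 <- filter_snps(stats, base, TRUE)$retained
  tighter <- list(
    discovery_filters(0.2, 0.2, 0.2, 0.5, 0.2),
    discovery_filters(0.1, 0.6, 0.2, 0.5, 0.2),
    discovery_filters(0.1, 0.2, 0.4, 0.5, 0.2),
    discovery_filters(0.1, 0.2, 0.2, 0.3, 0.2),
    discovery_filters(0.1, 0.2, 0.2, 0.5, 0.6))
  for (flt in tighter) {
    r1 <- filter_snps(stats, flt, TRUE)$retained
    expect_true(all(which(r1) %in% which(r0)))
  }
})

test_that("per-tag variant annotation respects the max_variants bound", {
  b1 <- strrep("A", 20)
  b2 <- strsplit(b1, "")[[1]]
  b2[seq(2, 18, 2)] <- "G"  # 9 substitutions
  b2 <- paste(b2, collapse = "")
  tags <- sort_tags(mk_tag(c(b1, b2)))
  topm <- make_topm(tags, "UNIQUE", "ctg", "+", 100L)
  depth <- matrix(5L, 2, 4, dimnames = list(NULL, paste0("t", 1:4)))
  depth[1, 1:2] <- 0L
  depth[2, 3:4] <- 0L
  tbt <- make_tbt(tags, paste0("t", 1:4), depth)
  disc <- run_discovery(topm, tbt, filters = loose_filters)
  expect_identical(nrow(disc$sites), 9L)
  expect_identical(sum(disc$sites$retained), 8L)
  expect_identical(disc$sites$reject_reason[!disc$sites$retained],
                   "max_variants")
  nvar <- vapply(disc$topm$variants, nrow, 0L)
  expect_true(all(nvar <= 8L))
})

test_that("a rejecting configuration leaves the TOPM without variants, and
          reruns are identical", {
  body1 <- "AAAATTTTCCCCGGGG"
  body2 <- "AAAATTTTCCACGGGG"
  tags <- sort_tags(mk_tag(c(body1, body2)))
  topm <- make_topm(tags, "UNIQUE", "ctg", "+", 100L)
  depth <- matrix(c(4L, 0L, 0L, 0L, 4L, 0L), 2, 3,
                  dimnames = list(NULL, c("t1", "t2", "t3")))
  tbt <- make_tbt(tags, c("t1", "t2", "t3"), depth)
  # t3 has no reads, so full locus coverage is unattainable
  reject_all <- discovery_filters(min_maf = 0.5, min_fit = 0.99,
                                  min_locus_coverage = 1)
  d0 <- run_discovery(topm, tbt, filters = reject_all)
  expect_identical(sum(d0$sites$retained), 0L)
  expect_true(all(vapply(d0$topm$variants, nrow, 0L) == 0L))

  d1 <- run_discovery(topm, tbt, filters = loose_filters)
  d2 <- run_discovery(topm, tbt, filters = loose_filters)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$genotypes$geno, d2$genotypes$geno)
  p1 <- tempfile(); p2 <- tempfile()
  write_topm(d1$topm, p1); write_topm(d2$topm, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("pedigree files define the inbred subset used by the filters", {
  p <- tempfile()
  writeLines(c("Taxon\tF", "a\t1", "b\t0.9", "c\t0.2"), p)
  ped <- read_pedigree(p)
  expect_identical(ped$taxon, c("a", "b", "c"))
  expect_equal(ped$F, c(1, 0.9, 0.2))
  writeLines(c("Taxon\tF", "a\t2"), p)
  expect_error(read_pedigree(p), "\\[0, 1\\]")
})
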
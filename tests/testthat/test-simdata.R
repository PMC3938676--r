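enz <- gbs_enzyme("ApeKI")

small_cfg <- function(...) {
  sim_config(seed = 71, ref_length = 40000, site_spacing = 1500,
             n_taxa = 12, n_snps = 15, mean_depth = 5, error_rate = 0, ...)
}

test_that("planted cut sites are exactly the scanned occurrences", {
  simref <- sim_reference(small_cfg())
  scan <- integer()
  for (pat in enz$internal_patterns) {
    m <- gregexpr(gbstag:::iupac_regex(pat), simref$ref[["ctg01"]])[[1]]
    if (m[1] != -1) scan <- c(scan, as.integer(m))
  }
  expect_identical(sort(scan), sort(simref$cut_sites$pos))
  expect_gt(nrow(simref$cut_sites), 5L)
})

test_that("the generator is a pure function of (config, seed)", {
  cfg <- small_cfg()
  r1 <- sim_reference(cfg)
  r2 <- sim_reference(cfg)
  expect_identical(r1$ref, r2$ref)
  p1 <- sim_population(cfg, r1)
  p2 <- sim_population(cfg, r2)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$snps, p2$snps)
  s1 <- sim_gbs_fastq(p1, tempfile())
  s2 <- sim_gbs_fastq(p2, tempfile())
  expect_identical(read_fastq(s1$fastqs$fastq[1]),
                   read_fastq(s2$fastqs$fastq[1]))
  # a different seed changes the output
  r3 <- sim_reference(sim_config(seed = 72, ref_length = 40000))
  expect_false(identical(r1$ref, r3$ref))
})

test_that("a reference can have zero cut sites", {
  cfg <- sim_config(seed = 71, ref_length = 3000, site_spacing = 1e7,
                    n_snps = 1L)
  simref <- sim_reference(cfg)
  expect_identical(nrow(simref$cut_sites), 0L)
  expect_false(grepl(gbstag:::iupac_regex("GCWGC"), simref$ref[[1]]))
})

test_that("fully inbred taxa have no heterozygous truth genotypes", {
  cfg <- small_cfg()
  pop <- sim_population(cfg, sim_reference(cfg))
  expect_false(any(pop$genotypes == 1L))
  expect_true(all(pop$pedigree$F == 1))
  # finite selfing leaves residual heterozygosity in expectation
  cfg2 <- small_cfg(selfing_generations = 1)
  pop2 <- sim_population(cfg2, sim_reference(cfg2))
  expect_gt(sum(pop2$genotypes == 1L), 0L)
})

test_that("RIL families segregate close to 1:1 where parents differ", {
  cfg <- sim_config(seed = 73, ref_length = 150000, n_snps = 60,
                    families = list(n = 1, size = 200,
                                    selfing_generations = 12))
  pop <- sim_population(cfg, sim_reference(cfg))
  G <- pop$genotypes
  seg <- which(apply(G, 2, function(g) any(g == 0) && any(g == 2)))
  expect_gt(length(seg), 5L)
  for (j in seg) {
    f <- mean(G[, j]) / 2
    se <- sqrt(0.25 / nrow(G))
    expect_lt(abs(f - 0.5), 4 * se)
  }
})

test_that("error-free reads classify with zero barcode rejections", {
  sim <- sim_gbs_fastq(sim_population(small_cfg(),
                                      sim_reference(small_cfg())),
                       tempfile())
  cls <- classify_reads(read_fastq(sim$fastqs$fastq[1])$seq,
                        sim$key, enz)
  expect_identical(sum(cls$status == "NO_BARCODE"), 0L)
  expect_identical(sum(cls$status == "CONTAINS_N"), 0L)
})

test_that("injected substitution errors appear at the configured rate", {
  cfg <- sim_config(seed = 74, ref_length = 80000, site_spacing = 1000,
                    n_taxa = 24, n_snps = 0L, mean_depth = 4,
                    error_rate = 0.01)
  pop <- sim_population(cfg, sim_reference(cfg))
  sim <- sim_gbs_fastq(pop, tempfile(), provenance = TRUE)
  reads <- read_fastq(sim$fastqs$fastq[1])
  prov <- sim$provenance
  expect_identical(prov$read_id, reads$id)
  # independent mismatch count: compare each read to its locus window
  # (no SNPs were planted, so the window is the truth haplotype; the
  # leading remnant is error-protected)
  bc_len <- nchar(sim$key$barcode[1])
  mism <- 0; bases <- 0
  for (lid in unique(prov$locus_id)) {
    locus <- pop$loci[pop$loci$locus_id == lid, ]
    win <- gbstag:::locus_window(pop$ref$ref, locus)
    idx <- which(prov$locus_id == lid)
    genomic <- substr(reads$seq[idx], bc_len + 1L, bc_len + nchar(win))
    d <- gbstag:::hamming_cpp(substr(genomic, 5L, nchar(win)),
                              rep(substr(win, 5L, nchar(win)),
                                  length(idx)))
    mism <- mism + sum(d)
    bases <- bases + length(idx) * (nchar(win) - 4L)
  }
  rate <- mism / bases
  se <- sqrt(0.01 * 0.99 / bases)
  expect_lt(abs(rate - 0.01), 4 * se)
  # observed mismatches track the injected error events (two events can
  # hit the same base, so the net count may be slightly lower)
  expect_lte(mism, sum(prov$n_errors))
  expect_gt(mism, 0.95 * sum(prov$n_errors))
})

test_that("blank negative controls produce no reads", {
  cfg <- small_cfg(n_blanks = 2L)
  sim <- sim_gbs_fastq(sim_population(cfg, sim_reference(cfg)), tempfile())
  expect_true(all(c("BLANK01", "BLANK02") %in% sim$key$sample))
  cls <- classify_reads(read_fastq(sim$fastqs$fastq[1])$seq, sim$key, enz)
  expect_false(any(cls$taxon %in% c("BLANK01", "BLANK02"), na.rm = TRUE))
})

test_that("written truth files and key round-trip through the readers", {
  dirn <- tempfile()
  sim <- sim_gbs_fastq(sim_population(small_cfg(),
                                      sim_reference(small_cfg())), dirn)
  key <- read_barcode_key(sim$key_path)
  expect_identical(key$barcode, sim$key$barcode)
  ped <- read_pedigree(file.path(dirn, "pedigree.tsv"))
  expect_identical(ped$taxon, sim$pop$taxa)
  ref <- read_reference(sim$ref_path)
  expect_identical(ref, sim$pop$ref$ref)
})

test_that("indel variants are carried through haplotype windows", {
  cfg <- small_cfg(indel_fraction = 0.3)
  pop <- sim_population(cfg, sim_reference(cfg))
  dels <- pop$snps[pop$snps$type == "del", ]
  expect_gt(nrow(dels), 0L)
  carrier <- which(pop$genotypes[, dels$snp_id[1]] == 2L)
  if (length(carrier)) {
    locus <- pop$loci[pop$loci$chrom == dels$chrom[1] &
                        pop$loci$cov_start <= dels$pos[1] &
                        pop$loci$cov_end >= dels$pos[1], ][1, ]
    hap <- sim_taxon_haplotypes(pop, locus$locus_id,
                                pop$taxa[carrier[1]])
    win <- gbstag:::locus_window(pop$ref$ref, locus)
    expect_identical(nchar(hap), nchar(win))
    expect_false(identical(hap, win))
  }
})
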
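enz <- gbs_enzyme("ApeKI")

# A compact end-to-end fixture shared by the production tests.
prod_fixture <- function(seed = 7) {
  cfg <- sim_config(seed = seed, ref_length = 60000, site_spacing = 1000,
                    n_taxa = 16, n_snps = 25, mean_depth = 8,
                    error_rate = 0)
  sim <- sim_gbs_experiment(cfg, tempfile())
  master <- merge_tag_counts(
    lapply(sim$fastqs$fastq, count_tags, key = sim$key, enzyme = enz), 5)
  sam <- tempfile(fileext = ".sam")
  align_tags(master, sim$ref_path, enz, sam)
  topm <- import_sam(sam, master)
  tbt <- build_tbt(sim$fastqs$fastq, sim$key, master, enz,
                   lanes = sim$fastqs)
  disc <- run_discovery(topm, tbt, pedigree = sim$pop$pedigree)
  list(sim = sim, disc = disc)
}

fx <- prod_fixture()

test_that("production on the discovery inputs reproduces discovery calls", {
  sim <- fx$sim; disc <- fx$disc
  prod <- run_production(sim$fastqs$fastq, sim$key, disc$topm, enz,
                         lanes = sim$fastqs)
  expect_identical(prod$sites$pos, disc$genotypes$sites$pos)
  expect_identical(prod$geno, disc$genotypes$geno)
  expect_identical(prod$d_major, disc$genotypes$d_major)
  expect_identical(prod$d_minor, disc$genotypes$d_minor)
})

test_that("reads matching no useful tag are counted but contribute nothing", {
  sim <- fx$sim; disc <- fx$disc
  # a lane of reads from an unrelated sequence
  alien <- paste0(sim$key$barcode[1], "CAGC", strrep("A", 60))
  fq <- write_fixture_fastq(rep(alien, 10))
  key1 <- sim$key[sim$key$barcode == sim$key$barcode[1], ]
  prod <- run_production(fq, key1, disc$topm, enz)
  expect_identical(prod$report$matched_reads, 0L)
  expect_identical(prod$report$unmatched_good, 10L)
  expect_true(all(is.na(prod$geno)))
})

test_that("replicate lanes of a sample are tallied before calling", {
  disc <- fx$disc
  registry <- attr(disc$topm, "sites")
  # pick a variant tag of the first registered site and synthesise reads
  vt <- tibble::as_tibble(disc$topm)
  vt <- vt[vapply(vt$variants, nrow, 0L) > 0L, ]
  lk <- paste(vt$chrom, vt$strand, vt$cut_pos) ==
    paste(registry$chrom[1], registry$strand[1], registry$cut_pos[1])
  tag <- vt$tag[lk][1]
  key2 <- barcode_key(flowcell = "FX", lane = c("1", "2"),
                      barcode = "ACGTAA", sample = "dup")
  f1 <- write_fixture_fastq(rep(paste0("ACGTAA", tag), 2))
  f2 <- write_fixture_fastq(rep(paste0("ACGTAA", tag), 3))
  lanes <- tibble::tibble(fastq = c(f1, f2), flowcell = "FX",
                          lane = c("1", "2"))
  prod <- run_production(c(f1, f2), key2, disc$topm, enz, lanes = lanes)
  i <- match(registry$site_id[1], prod$sites$site_id)
  expect_identical(unname(prod$d_major[i, "dup"] + prod$d_minor[i, "dup"]),
                   5)
  expect_false(is.na(prod$geno[i, "dup"]))
})

test_that("adding a taxon never changes existing taxa's calls", {
  sim <- fx$sim; disc <- fx$disc
  prod_all <- run_production(sim$fastqs$fastq, sim$key, disc$topm, enz,
                             lanes = sim$fastqs)
  # re-run with one taxon's reads removed from the key
  drop <- sim$key$sample[5]
  prod_sub <- run_production(sim$fastqs$fastq,
                             sim$key[sim$key$sample != drop, ],
                             disc$topm, enz, lanes = sim$fastqs)
  shared <- intersect(prod_sub$taxa, prod_all$taxa)
  expect_identical(prod_sub$geno[, shared], prod_all$geno[, shared])
})

test_that("HapMap output encodes heterozygotes as IUPAC codes", {
  gt <- new_genotypes(
    tibble::tibble(site_id = "S1_100", chrom = "1", pos = 100L,
                   major = "A", minor = "G", alleles = "A,G"),
    c("tx1", "tx2"),
    matrix(c(0L, 1L), 1, 2),
    matrix(c(4, 2), 1, 2), matrix(c(0, 2), 1, 2))
  p <- tempfile(fileext = ".hmp.txt")
  write_hapmap(gt, p)
  lines <- readLines(p)
  expect_length(lines, 2L)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[12:13], c("A", "R"))
  expect_identical(fields[2], "A/G")
})

test_that("HapMap round-trips the genotype matrix", {
  gt <- fx$disc$genotypes
  p <- tempfile(fileext = ".hmp.txt")
  write_hapmap(gt, p)
  back <- read_hapmap(p)
  expect_identical(back$taxa, gt$taxa)
  expect_identical(back$geno, gt$geno)
  expect_identical(back$sites$pos, gt$sites$pos)
  expect_identical(back$sites$major, gt$sites$major)
})

test_that("VCF records carry allelic depths and round-trip through vcfR", {
  gt <- new_genotypes(
    tibble::tibble(site_id = "S1_100", chrom = "1", pos = 100L,
                   major = "A", minor = "G", alleles = "A,G"),
    c("tx1", "tx2"),
    matrix(c(0L, 1L), 1, 2),
    matrix(c(4, 2), 1, 2), matrix(c(1, 2), 1, 2))
  p <- tempfile(fileext = ".vcf")
  write_vcf(gt, p)
  lines <- readLines(p)
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_identical(rec[10], "0/0:4,1")
  expect_identical(rec[11], "0/1:2,2")

  back <- read_vcf_genotypes(p)
  expect_identical(genotype_alleles(back), genotype_alleles(gt))
  expect_identical(back$d_major, gt$d_major)
})

test_that("HapMap and VCF emissions encode the same genotype matrix", {
  gt <- fx$disc$genotypes
  ph <- tempfile(fileext = ".hmp.txt")
  pv <- tempfile(fileext = ".vcf")
  write_hapmap(gt, ph)
  write_vcf(gt, pv)
  hm <- read_hapmap(ph)
  vc <- read_vcf_genotypes(pv)
  expect_identical(genotype_alleles(hm), genotype_alleles(vc))
})

test_that("VCF REF can be anchored on the reference FASTA", {
  sim <- fx$sim
  gt <- fx$disc$genotypes
  pv <- tempfile(fileext = ".vcf")
  write_vcf(gt, pv, ref = sim$ref_path)
  lines <- readLines(pv)
  recs <- lines[!startsWith(lines, "#")]
  ref <- read_reference(sim$ref_path)
  f <- strsplit(recs[1], "\t")[[1]]
  expect_identical(f[4], substr(ref[[f[1]]], as.integer(f[2]),
                                as.integer(f[2])))
})
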
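test_that("2-bit encoding round-trips and is injective", {
  set.seed(42)
  seqs <- vapply(1:2000, function(i) random_tag(), "")
  enc <- encode_tags(seqs)
  expect_identical(decode_tags(enc$packed, enc$length), seqs)
  key <- paste(enc$packed, enc$length)
  expect_identical(anyDuplicated(key[!duplicated(seqs)]), 0L)
})

test_that("a 64-base tag occupies exactly 16 bytes of packed payload", {
  s <- strrep("T", 64)
  enc <- encode_tags(s)
  expect_identical(nchar(enc$packed), 32L)  # 32 hex chars = 128 bits
  expect_identical(enc$packed, strrep("f", 32))
  expect_identical(encode_tags("ACGT")$packed,
                   paste0("1b", strrep("0", 30)))  # 00 01 10 11, zero pad
})

test_that("ambiguous bases and over-long sequences are rejected", {
  expect_error(encode_tags("ACNGT"), "A/C/G/T")
  expect_error(encode_tags(strrep("A", 65)), "1-64")
  expect_error(encode_tags(""), "1-64")
})

test_that("tag ordering is total, deterministic and padding-aware", {
  set.seed(7)
  tags <- unique(vapply(1:500, function(i) random_tag(), ""))
  s1 <- sort_tags(tags)
  s2 <- sort_tags(sample(tags))
  expect_identical(s1, s2)
  # shorter tag sorts before its extension with a non-A base, after with A
  expect_identical(sort_tags(c("ACGTT", "ACGT")), c("ACGT", "ACGTT"))
  expect_identical(sort_tags(c("ACGTA", "ACGT"))[2], "ACGTA")
})

test_that("classify_reads partitions reads into exactly one status each", {
  key <- fixture_key()
  enz <- gbs_enzyme("ApeKI")
  set.seed(1)
  reads <- c(
    fixture_read(),                                        # GOOD
    fixture_read(body = paste0(strrep("A", 5), "N", strrep("A", 54))),
    fixture_read(barcode = "AAAA"),                        # NO_BARCODE
    fixture_read(remnant = "TTTT"),                        # no remnant
    fixture_read(barcode = "TAGCA", body = strrep("C", 60)),
    fixture_read(body = paste0(strrep("G", 5), "GCTGC", strrep("T", 50)))
  )
  cls <- classify_reads(reads, key, enz)
  expect_false(anyNA(cls$status))
  expect_identical(sum(table(cls$status)), length(reads))
  expect_identical(sum(cls$status == "GOOD") +
                     sum(cls$status != "GOOD"), length(reads))
  expect_identical(is.na(cls$tag), cls$status != "GOOD")
})

test_that("good reads are trimmed per the barcode/remnant/chimera rules", {
  key <- fixture_key()
  enz <- gbs_enzyme("ApeKI")
  # barcode CTCC + remnant CAGC + 60 clean bases -> tag of 64
  r <- fixture_read(body = strrep("A", 70))
  cls <- classify_reads(r, key, enz)
  expect_identical(as.character(cls$status), "GOOD")
  expect_identical(cls$tag_length, 64L)
  expect_identical(cls$taxon, "tx1")
  expect_identical(substr(cls$tag, 1, 4), "CAGC")

  # an N after the barcode within the trim window
  rn <- fixture_read(body = paste0(strrep("A", 6), "N", strrep("A", 53)))
  expect_identical(as.character(classify_reads(rn, key, enz)$status),
                   "CONTAINS_N")

  # internal ApeKI site -> chimera trim keeps remnant-side bases
  rc <- fixture_read(body = paste0(strrep("A", 20), "GCAGC",
                                   strrep("T", 40)))
  cc <- classify_reads(rc, key, enz)
  expect_identical(as.character(cc$status), "GOOD")
  expect_true(cc$chimera_trimmed)
  expect_identical(cc$tag_length, 24L)  # remnant 4 + 20 bases before site
  expect_identical(cc$tag, paste0("CAGC", strrep("A", 20)))

  # trimming below min_tag_length
  rs <- fixture_read(body = paste0("AA", "GCTGC", strrep("T", 53)))
  expect_identical(as.character(classify_reads(rs, key, enz)$status),
                   "TOO_SHORT")

  # remnant check can be relaxed
  rr <- fixture_read(remnant = "TTTT", body = strrep("A", 60))
  expect_identical(as.character(classify_reads(rr, key, enz)$status),
                   "NO_BARCODE")
  expect_identical(
    as.character(classify_reads(rr, key, enz, check_remnant = FALSE)$status),
    "GOOD")
})

test_that("classification is invariant to barcode key row order", {
  enz <- gbs_enzyme("ApeKI")
  key <- fixture_key()
  set.seed(3)
  reads <- replicate(50, fixture_read(
    barcode = sample(c(key$barcode, "AAAA"), 1),
    body = random_tag(60)))
  a <- classify_reads(reads, key, enz)
  b <- classify_reads(reads, key[sample(nrow(key)), ], enz)
  expect_identical(a, b)
})

test_that("barcode key parsing validates structure", {
  path <- tempfile()
  writeLines(c("Flowcell\tLane\tBarcode\tSample",
               "FC1\t1\tACGT\ts1",
               "FC1\t1\tGGTT\ts2",
               "FC1\t2\tACGT\ts1"), path)
  key <- read_barcode_key(path)
  expect_identical(nrow(key), 3L)
  expect_s3_class(key, "gbs_key")

  writeLines(c("Flowcell\tLane\tBarcode\tSample",
               "FC1\t1\tACGT\ts1", "FC1\t1\tACGT\ts2"), path)
  expect_error(read_barcode_key(path), "duplicate")

  writeLines(c("Flowcell\tLane\tBarcode\tSample",
               "FC1\t1\tACGT\ts1", "FC1\t1\tACGTA\ts2"), path)
  expect_error(read_barcode_key(path), "prefix")

  writeLines(c("Flowcell\tLane\tBarcode",
               "FC1\t1\tACGT"), path)
  expect_error(read_barcode_key(path), "missing required column")

  expect_error(barcode_key("F", "1", "ACNT", "s"), "A/C/G/T")
  expect_error(barcode_key("F", "1", "ACG", "s"), "\\[4, 16\\]")
})

test_that("enzyme models carry remnants and IUPAC internal patterns", {
  e <- gbs_enzyme("ApeKI")
  expect_setequal(e$remnants, c("CAGC", "CTGC"))
  expect_identical(e$internal_patterns, "GCWGC")
  expect_error(gbs_enzyme("NoSuchEnzyme"), "unknown enzyme")

  cfgf <- tempfile()
  writeLines(c("Name\tRemnants\tInternalPatterns",
               "MyEnz\tCAGC,CTGC\tGCWGC"), cfgf)
  tab <- read_enzyme_config(cfgf)
  expect_identical(gbs_enzyme("myenz", tab)$remnants, c("CAGC", "CTGC"))
  writeLines(c("Name\tRemnants\tInternalPatterns",
               "Bad\tCAXC\tGCWGC"), cfgf)
  expect_error(read_enzyme_config(cfgf), "A/C/G/T")
})
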
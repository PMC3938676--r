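enz <- gbs_enzyme("ApeKI")

fixture_master <- function(tags) {
  m <- tag_count_table(rep(tags, each = 5))
  attr(m, "min_count") <- 5
  m
}

write_sam_fixture <- function(records, path = tempfile(fileext = ".sam"),
                              sq = "ctg\t1000") {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", sub("\t", "\tLN:", sq)),
               records), path)
  path
}

sam_line <- function(qname, flag, rname, pos, mapq, cigar, seq, tags = "") {
  paste0(paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, "*",
               sep = "\t"),
         if (nzchar(tags)) paste0("\t", tags) else "")
}

test_that("import_sam assigns UNIQUE/MULTIPLE/UNALIGNED per record evidence", {
  tags <- sort_tags(c(paste0("CAGC", strrep("A", 20)),
                      paste0("CAGC", strrep("C", 20)),
                      paste0("CAGC", strrep("G", 20)),
                      paste0("CTGC", strrep("T", 20))))
  master <- fixture_master(tags)
  id <- function(i) sprintf("tag%06d_count%d", i, master$count[i])
  sam <- write_sam_fixture(c(
    sam_line(id(1), 0, "ctg", 101, 42, "24M", master$tag[1]),   # unique
    sam_line(id(2), 4, "*", 0, 0, "*", master$tag[2]),          # unmapped
    sam_line(id(3), 0, "ctg", 201, 7, "24M", master$tag[3],
             "AS:i:40\tXS:i:40")                                # equal best
    # tag 4 absent entirely
  ))
  topm <- import_sam(sam, master)
  expect_identical(nrow(topm), 4L)
  st <- setNames(topm$status, topm$tag)
  expect_identical(unname(st[master$tag[1]]), "UNIQUE")
  expect_identical(unname(st[master$tag[2]]), "UNALIGNED")
  expect_identical(unname(st[master$tag[3]]), "MULTIPLE")
  expect_identical(unname(st[master$tag[4]]), "UNALIGNED")
  e1 <- topm_lookup(topm, master$tag[1])
  expect_identical(e1$chrom, "ctg")
  expect_identical(e1$strand, "+")
  expect_identical(e1$cut_pos, 101L)
})

test_that("minus-strand cut position is the rightmost aligned base", {
  tag <- paste0("CAGC", strrep("A", 26))
  master <- fixture_master(tag)
  sam <- write_sam_fixture(sam_line("tag000001_count5", 16, "ctg", 101, 42,
                                    "30M", rev_comp(tag)))
  topm <- import_sam(sam, master)
  expect_identical(topm$strand, "-")
  expect_identical(topm$cut_pos, 130L)  # 101 + 30 - 1
})

test_that("MAPQ 0 without score tags means MULTIPLE; mapq_min gates UNIQUE", {
  tag <- paste0("CAGC", strrep("A", 20))
  master <- fixture_master(tag)
  sam <- write_sam_fixture(sam_line("tag000001_count5", 0, "ctg", 11, 0,
                                    "24M", tag))
  expect_identical(import_sam(sam, master)$status, "MULTIPLE")
  sam2 <- write_sam_fixture(sam_line("tag000001_count5", 0, "ctg", 11, 3,
                                     "24M", tag))
  expect_identical(import_sam(sam2, master)$status, "UNIQUE")
  expect_identical(import_sam(sam2, master, mapq_min = 10)$status,
                   "UNALIGNED")
})

test_that("every master tag receives exactly one TOPM entry", {
  set.seed(21)
  tags <- sort_tags(unique(vapply(1:10, function(i) {
    paste0("CAGC", random_tag(30))
  }, "")))
  master <- fixture_master(tags)
  recs <- vapply(1:8, function(i) {
    sam_line(sprintf("tag%06d_count%d", i, master$count[i]), 0, "ctg",
             10 * i, 42, paste0(nchar(master$tag[i]), "M"), master$tag[i])
  }, "")
  topm <- import_sam(write_sam_fixture(recs), master)
  expect_identical(nrow(topm), 10L)
  expect_identical(sum(topm$status == "UNALIGNED"), 2L)
  expect_identical(sort_tags(topm$tag), topm$tag)
})

test_that("lookup is exact-match and misses return absent", {
  tags <- c(paste0("CAGC", strrep("A", 20)), paste0("CAGC", strrep("G", 20)))
  master <- fixture_master(sort_tags(tags))
  sam <- write_sam_fixture(vapply(1:2, function(i) {
    sam_line(sprintf("tag%06d_count%d", i, master$count[i]), 0, "ctg",
             10 * i, 42, "24M", master$tag[i])
  }, ""))
  topm <- import_sam(sam, master)
  expect_identical(nrow(topm_lookup(topm, tags[1])), 1L)
  expect_identical(nrow(topm_lookup(topm, "CAGCTTTT")), 0L)
  # a truncation of a stored tag is a different key
  expect_identical(nrow(topm_lookup(topm, substr(tags[1], 1, 23))), 0L)
})

test_that("position iteration visits UNIQUE entries in coordinate order", {
  set.seed(22)
  n <- 12
  tags <- sort_tags(unique(vapply(seq_len(n), function(i) {
    paste0("CAGC", random_tag(30))
  }, "")))
  master <- fixture_master(tags)
  pos <- sample(seq(10, 900, 10), length(tags))
  recs <- vapply(seq_along(tags), function(i) {
    sam_line(sprintf("tag%06d_count%d", i, master$count[i]), 0, "ctg",
             pos[i], 42, "34M", master$tag[i])
  }, "")
  topm <- import_sam(write_sam_fixture(sample(recs)), master)
  it <- topm_by_position(topm)
  expect_identical(it$cut_pos, as.integer(sort(pos)))
  expect_true(all(it$status == "UNIQUE"))
})

test_that("variant annotation validates, replaces, and persists", {
  tags <- c(paste0("CAGC", strrep("A", 28)), paste0("CAGC", strrep("G", 28)))
  master <- fixture_master(sort_tags(tags))
  sam <- write_sam_fixture(c(
    sam_line(sprintf("tag%06d_count5", 1), 0, "ctg", 50, 42, "32M",
             master$tag[1]),
    sam_line(sprintf("tag%06d_count5", 2), 4, "*", 0, 0, "*",
             master$tag[2])))
  topm <- import_sam(sam, master)
  uniq <- topm$tag[topm$status == "UNIQUE"]
  other <- topm$tag[topm$status != "UNIQUE"]

  v <- tibble::tibble(offset = c(12L, 30L), allele = c("A", "-"))
  topm <- annotate_variants(topm, uniq, v)
  expect_identical(topm_lookup(topm, uniq)$variants[[1]], v)
  # second annotation replaces the first
  v2 <- tibble::tibble(offset = 5L, allele = "T")
  topm <- annotate_variants(topm, uniq, v2)
  expect_identical(topm_lookup(topm, uniq)$variants[[1]], v2)

  expect_error(annotate_variants(topm, other, v), "UNIQUE")
  expect_error(annotate_variants(
    topm, uniq, tibble::tibble(offset = 0:8, allele = rep("A", 9))),
    "too many variants")
  expect_error(annotate_variants(
    topm, uniq, tibble::tibble(offset = c(3L, 3L), allele = c("A", "C"))),
    "strictly increasing")

  topm <- annotate_variants(topm, uniq, v)
  for (fmt in c("binary", "tsv", "rds")) {
    p <- tempfile()
    write_topm(topm, p, fmt)
    back <- read_topm(p, fmt)
    expect_identical(tibble::as_tibble(back), tibble::as_tibble(topm),
                     info = fmt)
  }
})

test_that("strand handling is self-consistent for simulated +/- tags", {
  # one recognition site in a known reference; the two orientations of the
  # assay anchor at the coordinates reported by cut_site_anchors()
  set.seed(23)
  left <- random_tag(60); right <- random_tag(60)
  ref <- c(ctg = gbstag:::disrupt_sites(paste0(left, "GCAGC", right),
                                        "GC[AT]GC", keep = 61L))
  anchors <- cut_site_anchors(ref, enz)
  expect_identical(nrow(anchors), 2L)
  plus_tag <- substr(ref, 62, 125)    # CAGC + downstream
  minus_tag <- rev_comp(substr(ref, 1, 64))  # ends GCAG -> starts CTGC
  master <- fixture_master(sort_tags(c(plus_tag, minus_tag)))
  sam <- tempfile(fileext = ".sam")
  align_tags(master, ref, enz, sam)
  topm <- import_sam(sam, master)
  pt <- topm_lookup(topm, plus_tag)
  mt <- topm_lookup(topm, minus_tag)
  expect_identical(pt$status, "UNIQUE")
  expect_identical(mt$status, "UNIQUE")
  expect_identical(pt$strand, "+")
  expect_identical(mt$strand, "-")
  expect_identical(pt$cut_pos,
                   anchors$cut_pos[anchors$strand == "+"])
  expect_identical(mt$cut_pos,
                   anchors$cut_pos[anchors$strand == "-"])
})
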
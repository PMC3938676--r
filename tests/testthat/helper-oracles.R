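# Independent oracles and fixture builders shared across test files.

# Plain-R Needleman-Wunsch DP (linear gap penalty, optionally free trailing
# gaps), written independently of the package's C++ implementation.
nw_oracle_score <- function(a, b, match = 2, mismatch = -1, gap = -3,
                            free_end = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- gap * (0:n)
  H[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(
        H[i, j] + if (av[i] == bv[j]) match else mismatch,
        H[i, j + 1] + gap,
        H[i + 1, j] + gap)
    }
  }
  if (free_end) max(H[, m + 1], H[n + 1, ]) else H[n + 1, m + 1]
}

# Score a gapped 2-row alignment under the same scheme (trailing gap
# columns in either row are free).
score_pair_alignment <- function(ra, rb, match = 2, mismatch = -1,
                                 gap = -3) {
  av <- strsplit(ra, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  last_a <- max(which(av != "-"))
  last_b <- max(which(bv != "-"))
  keep <- seq_len(min(max(last_a, last_b), length(av)))
  # columns after both sequences have ended cannot exist; columns after one
  # sequence's last base are free trailing gaps
  s <- 0
  for (k in keep) {
    if (k > last_a || k > last_b) next
    if (av[k] == "-" || bv[k] == "-") s <- s + gap
    else s <- s + if (av[k] == bv[k]) match else mismatch
  }
  s
}

# Direct three-likelihood genotype comparison (non-log, choose()-based),
# independent of the package's caller.
caller_oracle <- function(dM, dm, e = 0.01) {
  n <- dM + dm
  if (n == 0) return(NA_integer_)
  l_homM <- choose(n, dm) * e^dm * (1 - e)^dM
  l_homm <- choose(n, dM) * e^dM * (1 - e)^dm
  l_het <- choose(n, dM) * 0.5^n
  l_hom <- max(l_homM, l_homm)
  if (l_hom <= l_het * (1 + 1e-12)) return(1L)
  if (l_homM >= l_homm) 0L else 2L
}

# Exhaustive two-sided binomial tail probability.
binom_oracle <- function(m, n) {
  pm <- vapply(0:n, function(k) choose(n, k) * 0.5^n, 0)
  k <- min(m, n - m)
  min(1, 2 * sum(pm[seq_len(k + 1)]))
}

random_tag <- function(len = sample(1:64, 1)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A small single-lane key with ApeKI-compatible fixture reads.
fixture_key <- function() {
  barcode_key(flowcell = "FC1", lane = "1",
              barcode = c("CTCC", "TAGCA", "GGTT"),
              sample = c("tx1", "tx2", "tx3"))
}

fixture_read <- function(barcode = "CTCC", remnant = "CAGC",
                         body = strrep("A", 60)) {
  paste0(barcode, remnant, body)
}

write_fixture_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  if (length(reads) == 0L) {
    file.create(path)
    return(path)
  }
  writeLines(as.vector(rbind(paste0("@r", seq_along(reads)), reads,
                             "+", strrep("I", nchar(reads)))), path)
  path
}

# Hand-buildable TOPM for discovery tests (internal constructor).
make_topm <- function(tag, status, chrom = NA, strand = NA, cut_pos = NA,
                      max_variants = 8L) {
  n <- length(tag)
  gbstag:::new_topm(tibble::tibble(
    tag = tag, status = status,
    chrom = rep_len(chrom, n), strand = rep_len(strand, n),
    cut_pos = as.integer(rep_len(cut_pos, n)),
    variants = replicate(n, gbstag:::empty_variants(), simplify = FALSE)),
    max_variants = max_variants)
}

make_tbt <- function(tags, taxa, depth) {
  gbstag:::new_tbt(tags, taxa, depth)
}
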
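#' Production genotyping against a production-ready TOPM
#'
#' The single-step Production pipeline: classify every read in the input
#' FASTQ files, match each good read's trimmed tag exactly (sequence and
#' length, longest candidate tag first) against the variant-annotated tags
#' in the production-ready TOPM, tally per-taxon tag depths (replicate
#' lanes of the same taxon are summed, saturating at the depth cap, before
#' calling), convert tag depths to allele depths at every registered SNP,
#' and call genotypes with the binomial likelihood-ratio caller. Reads whose
#' tags match no useful tag contribute nothing and are counted in the
#' report.
#'
#' @param fastqs Character vector of FASTQ paths.
#' @param key Barcode key covering these files' lanes.
#' @param topm A production-ready `gbs_topm` (site registry attached, >= 1
#'   variant-annotated tag).
#' @param enzyme Enzyme model.
#' @param lanes Optional tibble `fastq`, `flowcell`, `lane` (as in
#'   [build_tbt()]).
#' @inheritParams classify_reads
#' @param err,lr_threshold Caller parameters ([call_genotypes()]).
#' @param depth_cap Per-tag per-taxon depth saturation (default 127).
#' @return A `gbs_genotypes`; `report` carries matched/unmatched read
#'   counts.
#' @export
run_production <- function(fastqs, key, topm, enzyme, lanes = NULL,
                           trim_length = 64L, min_tag_length = 20L,
                           check_remnant = TRUE, err = 0.01,
                           lr_threshold = 1, depth_cap = 127L) {
  registry <- attr(topm, "sites")
  has_var <- vapply(topm$variants, nrow, 0L) > 0L
  if (is.null(registry) || !any(has_var)) {
    stop("TOPM is not production-ready (no variant-annotated tags)")
  }
  vt <- tibble::as_tibble(topm)[has_var, ]
  taxa <- unique(key_taxa(key))
  depth <- matrix(0L, nrow = nrow(vt), ncol = length(taxa),
                  dimnames = list(NULL, taxa))
  lens <- sort(unique(nchar(vt$tag)), decreasing = TRUE)
  by_len <- lapply(lens, function(L) which(nchar(vt$tag) == L))
  names(by_len) <- lens
  n_matched <- 0L
  n_unmatched <- 0L
  for (f in fastqs) {
    lane_key <- if (!is.null(lanes)) {
      row <- lanes[lanes$fastq == f, ]
      if (nrow(row) != 1L) stop("no unique lane assignment for ", f)
      key_for_lane(key, row$flowcell, row$lane)
    } else key_for_lane(key)
    cls <- classify_reads(read_fastq(f)$seq, lane_key, enzyme,
                          trim_length = trim_length,
                          min_tag_length = min_tag_length,
                          check_remnant = check_remnant)
    good <- cls[cls$status == "GOOD", c("taxon", "tag")]
    hit <- rep(NA_integer_, nrow(good))
    for (L in lens) {
      todo <- which(is.na(hit) & nchar(good$tag) >= L)
      if (!length(todo)) next
      rows <- by_len[[as.character(L)]]
      m <- match(substr(good$tag[todo], 1L, L), vt$tag[rows])
      hit[todo[!is.na(m)]] <- rows[m[!is.na(m)]]
    }
    n_matched <- n_matched + sum(!is.na(hit))
    n_unmatched <- n_unmatched + sum(is.na(hit))
    ok <- !is.na(hit)
    if (any(ok)) {
      tal <- dplyr::count(
        tibble::tibble(i = hit[ok], j = match(good$taxon[ok], taxa)),
        .data$i, .data$j)
      cell <- cbind(tal$i, tal$j)
      depth[cell] <- pmin(depth_cap, depth[cell] + tal$n)
    }
  }

  ## tag depths -> allele depths at each registered site
  locus_key <- paste(vt$chrom, vt$strand, vt$cut_pos, sep = "\r")
  n_sites <- nrow(registry)
  geno <- matrix(NA_integer_, n_sites, length(taxa))
  dM <- matrix(0, n_sites, length(taxa))
  dm <- matrix(0, n_sites, length(taxa))
  for (i in seq_len(n_sites)) {
    lk <- paste(registry$chrom[i], registry$strand[i], registry$cut_pos[i],
                sep = "\r")
    members <- which(locus_key == lk)
    alleles <- strsplit(registry$alleles[i], ",", fixed = TRUE)[[1]]
    minus <- registry$strand[i] == "-"
    adep <- matrix(0, length(alleles), length(taxa),
                   dimnames = list(alleles, taxa))
    for (t in members) {
      v <- vt$variants[[t]]
      k <- which(v$offset == registry$offset[i])
      if (!length(k)) next
      al <- v$allele[k]
      if (minus) al <- unname(COMPLEMENT[al])
      if (al %in% alleles) {
        adep[al, ] <- adep[al, ] + depth[t, ]
      }
    }
    dM[i, ] <- adep[registry$major[i], ]
    dm[i, ] <- adep[registry$minor[i], ]
    geno[i, ] <- call_genotypes(dM[i, ], dm[i, ], err = err,
                                lr_threshold = lr_threshold)
  }
  new_genotypes(
    tibble::tibble(site_id = registry$site_id, chrom = registry$chrom,
                   pos = registry$pos, major = registry$major,
                   minor = registry$minor, alleles = registry$alleles),
    taxa, geno, dM, dm,
    report = list(matched_reads = n_matched, unmatched_good = n_unmatched))
}
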
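#' Configuration for the synthetic GBS experiment generator
#'
#' All generator output is a pure function of the configuration (including
#' its seed). The defaults are the desk-scale study conditions used
#' throughout the package: a 1 Mb single-contig reference with ApeKI-like
#' cut-site density (mean spacing 1000 bp), 96 fully inbred homozygous taxa
#' (an inbred-panel design, where the population-genetic filters have
#' maximal power), 500 true substitution SNPs with minor allele frequency
#' drawn uniformly from [0.05, 0.5], mean per-taxon per-locus depth 2 (the
#' low-coverage regime the pipeline targets), and a per-base substitution
#' error rate of 0.003. Errors are never injected into the barcode or the
#' cut-site remnant (switchable), so error-free runs classify with zero
#' barcode rejections.
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param ref_length,n_contigs Reference size and contig count.
#' @param enzyme Enzyme name (see [gbs_enzymes()]).
#' @param site_spacing Mean distance between planted cut sites (bp).
#' @param n_taxa Number of taxa (ignored when `families` is given).
#' @param inbred_fraction Fraction of taxa that are inbred lines.
#' @param selfing_generations Residual-heterozygosity control for inbred
#'   taxa: an inbred carries residual heterozygosity `0.5^g`; `Inf` means
#'   fully homozygous (F = 1).
#' @param families Optional biparental RIL design:
#'   `list(n = families, size = RILs each, selfing_generations = g)`;
#'   replaces the panel.
#' @param n_snps Number of true SNPs to plant in tag-covered positions.
#' @param maf_range Range of the per-SNP alternate allele frequency.
#' @param indel_fraction Fraction of true SNPs that are 1-bp deletions.
#' @param mean_depth Poisson mean of per-taxon per-locus read depth.
#' @param error_rate Per-base substitution sequencing error rate.
#' @param errors_in_barcode Also inject errors into barcode/remnant bases.
#' @param barcode_length Barcode length (equal-length barcodes are
#'   trivially prefix-free).
#' @param n_lanes Replicate lanes (every taxon appears on every lane).
#' @param n_blanks Blank negative-control taxa (barcoded, zero reads).
#' @param strands Which tag orientations each cut site emits
#'   (`"both"`, `"plus"`, `"minus"`).
#' @param n_paralog_loci Number of loci given an unassembled divergent
#'   duplicate (paralog) whose reads collapse onto the same TagLocus.
#' @param paralog_divergence Divergent bases per paralog copy.
#' @param trim_length,min_tag_length Read-trimming parameters (as in
#'   [classify_reads()]).
#' @param flowcell Flowcell name used in FASTQ/key output.
#' @return A validated list of class `gbs_sim_config`.
#' @export
sim_config <- function(seed = 1L, ref_length = 1e6, n_contigs = 1L,
                       enzyme = "ApeKI", site_spacing = 1000,
                       n_taxa = 96L, inbred_fraction = 1,
                       selfing_generations = Inf, families = NULL,
                       n_snps = 500L, maf_range = c(0.05, 0.5),
                       indel_fraction = 0, mean_depth = 2,
                       error_rate = 0.003, errors_in_barcode = FALSE,
                       barcode_length = 6L, n_lanes = 1L, n_blanks = 0L,
                       strands = "both", n_paralog_loci = 0L,
                       paralog_divergence = 3L, trim_length = 64L,
                       min_tag_length = 20L, flowcell = "SIMFC1") {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 1,
            inbred_fraction >= 0, inbred_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            all(maf_range >= 0), all(maf_range <= 1),
            barcode_length >= 4L, barcode_length <= 16L,
            strands %in% c("both", "plus", "minus"))
  cfg <- as.list(environment())
  class(cfg) <- "gbs_sim_config"
  cfg
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## disrupt every recognition-pattern occurrence not in `keep` (middle base
## swapped); repeats until the scan is clean
disrupt_sites <- function(seq, rxs, keep = integer(), pat_len = 5L) {
  for (iter in 1:25) {
    hits <- sort(unique(unlist(lapply(rxs, function(rx) {
      m <- gregexpr(rx, seq)[[1]]
      if (m[1] == -1L) integer() else as.integer(m)
    }))))
    bad <- setdiff(hits, keep)
    if (!length(bad)) return(seq)
    for (p in bad) {
      mid <- p + pat_len %/% 2L
      cur <- substr(seq, mid, mid)
      substr(seq, mid, mid) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  stop("could not produce a clean reference (pattern disruption failed)")
}

#' Generate a synthetic reference with planted cut sites
#'
#' Random sequence in which every recognition-site occurrence is planted
#' deliberately: spontaneous occurrences are disrupted, then sites are
#' planted at approximately exponentially distributed spacings (mean
#' `site_spacing`, minimum 30 bp), so the scanned cut-site list is exact by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `gbs_sim_reference`: list with `ref` (named
#'   character vector), `cut_sites` (tibble `chrom`, `pos` of each planted
#'   recognition-site start), `enzyme`, `config`.
#' @export
sim_reference <- function(cfg) {
  set.seed(cfg$seed)
  enzyme <- gbs_enzyme(cfg$enzyme)
  rxs <- vapply(enzyme$internal_patterns, iupac_regex, character(1))
  pat_len <- nchar(enzyme$internal_patterns[1])
  contig_len <- floor(cfg$ref_length / cfg$n_contigs)
  ref <- character(cfg$n_contigs)
  names(ref) <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
  sites <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    seq <- disrupt_sites(random_bases(contig_len), rxs, pat_len = pat_len)
    ## plant sites at ~exponential spacing
    pos <- integer()
    p <- 30L + as.integer(round(stats::rexp(1, 1 / cfg$site_spacing)))
    while (p + pat_len + 2L < contig_len - 30L) {
      pos <- c(pos, p)
      p <- p + pat_len +
        as.integer(pmax(30, round(stats::rexp(1, 1 / cfg$site_spacing))))
    }
    for (p0 in pos) {
      site <- paste(vapply(strsplit(enzyme$internal_patterns[1], "")[[1]],
                           function(ch) {
                             opts <- strsplit(gsub("\\[|\\]", "",
                                                   IUPAC_MAP[[ch]]), "")[[1]]
                             if (length(opts) == 1L) opts else sample(opts, 1L)
                           }, character(1)),
                    collapse = "")
      substr(seq, p0, p0 + pat_len - 1L) <- site
    }
    seq <- disrupt_sites(seq, rxs, keep = pos, pat_len = pat_len)
    ref[ci] <- seq
    sites[[ci]] <- tibble::tibble(chrom = names(ref)[ci], pos = pos)
  }
  structure(list(ref = ref, cut_sites = dplyr::bind_rows(sites),
                 enzyme = enzyme, config = cfg),
            class = "gbs_sim_reference")
}

#' Tag loci implied by a synthetic reference
#'
#' One locus per cut site and orientation, with the full read window (up to
#' `trim_length` bases from the cut) and the effective post-trim tag extent
#' (truncated where a neighbouring recognition site would chimera-trim the
#' read, mirroring the classifier's rule).
#'
#' @param simref A `gbs_sim_reference`.
#' @return Tibble: `locus_id`, `chrom`, `strand`, `cut_pos`, `win_len`
#'   (emitted read length), `eff_len` (post-trim tag length), `cov_start`,
#'   `cov_end` (reference extent covered by the post-trim tag).
#' @export
sim_loci <- function(simref) {
  cfg <- simref$config
  enzyme <- simref$enzyme
  pat_len <- nchar(enzyme$internal_patterns[1])
  rem_len <- nchar(enzyme$remnants[1])
  anchors <- cut_site_anchors(simref$ref, enzyme, strands = cfg$strands)
  out <- list()
  for (chrom in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == chrom, ]
    clen <- nchar(simref$ref[[chrom]])
    sites <- sort(unique(a$site_start))
    for (i in seq_len(nrow(a))) {
      cp <- a$cut_pos[i]
      if (a$strand[i] == "+") {
        win <- min(cfg$trim_length, clen - cp + 1L)
        nxt <- sites[sites > a$site_start[i]]
        ## a neighbouring site chimera-trims only when its full pattern
        ## lies inside the read window (mirrors the classifier's regex)
        eff <- win
        if (length(nxt) && nxt[1] + pat_len - 1L <= cp + win - 1L) {
          eff <- nxt[1] - cp
        }
      } else {
        win <- min(cfg$trim_length, cp)
        prv <- sites[sites < a$site_start[i]]
        eff <- win
        if (length(prv) && cp - max(prv) + 1L <= win) {
          eff <- cp - max(prv) - pat_len + 1L
        }
      }
      if (eff < cfg$min_tag_length) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = chrom, strand = a$strand[i], cut_pos = cp,
        win_len = win, eff_len = eff,
        cov_start = if (a$strand[i] == "+") cp else cp - eff + 1L,
        cov_end = if (a$strand[i] == "+") cp + eff - 1L else cp)
    }
  }
  loci <- dplyr::bind_rows(out)
  loci$locus_id <- sprintf("L%s_%d%s", loci$chrom, loci$cut_pos,
                           ifelse(loci$strand == "+", "F", "R"))
  loci[, c("locus_id", "chrom", "strand", "cut_pos", "win_len", "eff_len",
           "cov_start", "cov_end")]
}

creates_pattern <- function(contig, pos, new_base, rxs, pat_len,
                            deletion = FALSE) {
  lo <- max(1L, pos - pat_len + 1L)
  hi <- min(nchar(contig), pos + pat_len - 1L)
  ctx <- substr(contig, lo, hi)
  at <- pos - lo + 1L
  ctx <- if (deletion) {
    paste0(substr(ctx, 1L, at - 1L), substr(ctx, at + 1L, nchar(ctx)))
  } else {
    paste0(substr(ctx, 1L, at - 1L), new_base,
           substr(ctx, at + 1L, nchar(ctx)))
  }
  any(vapply(rxs, function(rx) grepl(rx, ctx), logical(1)))
}

#' Simulate a population with known truth genotypes
#'
#' Plants `n_snps` true variants at tag-covered reference positions
#' (never inside a recognition site, never creating a new one) and draws
#' genotypes: inbred taxa are homozygous apart from residual
#' heterozygosity `0.5^selfing_generations`; outbred taxa are
#' Hardy-Weinberg draws; RIL families segregate the parental alleles ~1:1
#' where the (independently drawn, fully homozygous) parents differ.
#' Optionally marks paralog loci: a divergent unassembled duplicate whose
#' reads will collapse onto the original locus, carried by every taxon.
#'
#' @param cfg A [sim_config()].
#' @param simref The matching [sim_reference()] result.
#' @return Object of class `gbs_sim_population`: list with `loci`, `snps`
#'   (truth table), `genotypes` (taxa x SNP matrix of alternate-allele
#'   dosage 0/1/2), `taxa`, `pedigree`, `families` (or `NULL`),
#'   `paralogs` (or `NULL`), `ref` and `config`.
#' @export
sim_population <- function(cfg, simref) {
  set.seed(cfg$seed + 1L)
  loci <- sim_loci(simref)
  enzyme <- simref$enzyme
  pat_len <- nchar(enzyme$internal_patterns[1])
  rxs <- vapply(enzyme$internal_patterns, iupac_regex, character(1))

  ## candidate positions: covered by a post-trim tag, outside every
  ## planted recognition pattern
  cand <- list()
  for (chrom in unique(loci$chrom)) {
    lc <- loci[loci$chrom == chrom, ]
    cov <- sort(unique(unlist(Map(seq.int, lc$cov_start, lc$cov_end))))
    pat_pos <- simref$cut_sites$pos[simref$cut_sites$chrom == chrom]
    inside <- unique(unlist(Map(seq.int, pat_pos, pat_pos + pat_len - 1L)))
    cand[[chrom]] <- setdiff(cov, inside)
  }
  n_cand <- sum(lengths(cand))
  if (cfg$n_snps > n_cand) {
    stop("n_snps exceeds available tag-covered positions (", n_cand, ")")
  }
  pool <- tibble::tibble(
    chrom = rep(names(cand), lengths(cand)),
    pos = unlist(cand, use.names = FALSE))
  pick <- sort(sample(nrow(pool), cfg$n_snps))
  snps <- pool[pick, ]
  n_indel <- round(cfg$indel_fraction * cfg$n_snps)
  snps$type <- sample(c(rep("del", n_indel),
                        rep("sub", cfg$n_snps - n_indel)))
  snps$ref <- substr(simref$ref[snps$chrom], snps$pos, snps$pos)
  snps$alt <- NA_character_
  drop <- logical(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    contig <- simref$ref[[snps$chrom[i]]]
    if (snps$type[i] == "del") {
      snps$alt[i] <- "-"
      if (creates_pattern(contig, snps$pos[i], "", rxs, pat_len,
                          deletion = TRUE)) drop[i] <- TRUE
      next
    }
    alts <- sample(setdiff(c("A", "C", "G", "T"), snps$ref[i]))
    ok <- FALSE
    for (a in alts) {
      if (!creates_pattern(contig, snps$pos[i], a, rxs, pat_len)) {
        snps$alt[i] <- a
        ok <- TRUE
        break
      }
    }
    if (!ok) drop[i] <- TRUE
  }
  snps <- snps[!drop, ]
  snps$freq <- runif(nrow(snps), cfg$maf_range[1], cfg$maf_range[2])
  snps$snp_id <- paste0("T", snps$chrom, "_", snps$pos)

  ## genotypes
  families <- NULL
  if (is.null(cfg$families)) {
    n_taxa <- cfg$n_taxa
    taxa <- sprintf("TX%03d", seq_len(n_taxa))
    n_inbred <- round(cfg$inbred_fraction * n_taxa)
    inbred <- seq_len(n_taxa) <= n_inbred
    rh <- if (is.finite(cfg$selfing_generations)) {
      0.5^cfg$selfing_generations
    } else 0
    G <- matrix(0L, n_taxa, nrow(snps))
    for (j in seq_len(nrow(snps))) {
      f <- snps$freq[j]
      a1 <- rbinom(n_taxa, 1L, f)
      a2 <- rbinom(n_taxa, 1L, f)
      g <- a1 + a2
      hz <- which(g == 1L & inbred)
      if (length(hz)) {
        collapse <- runif(length(hz)) >= rh
        pickA <- runif(length(hz)) < 0.5
        g[hz[collapse]] <- ifelse(pickA[collapse], 2L * a1[hz[collapse]],
                                  2L * a2[hz[collapse]])
      }
      G[, j] <- g
    }
    pedigree <- tibble::tibble(taxon = taxa,
                               F = ifelse(inbred, 1 - rh, 0))
  } else {
    fd <- cfg$families
    g_self <- if (is.null(fd$selfing_generations)) 5L else fd$selfing_generations
    rh <- 0.5^g_self
    taxa <- character(0)
    fam_id <- character(0)
    G <- NULL
    for (k in seq_len(fd$n)) {
      p1 <- rbinom(nrow(snps), 1L, snps$freq)
      p2 <- rbinom(nrow(snps), 1L, snps$freq)
      Gk <- matrix(0L, fd$size, nrow(snps))
      same <- p1 == p2
      Gk[, same] <- matrix(rep(2L * p1[same], each = fd$size), fd$size)
      for (j in which(!same)) {
        u <- runif(fd$size)
        Gk[, j] <- ifelse(u < rh, 1L,
                          ifelse(u < rh + (1 - rh) / 2, 2L * p1[j],
                                 2L * p2[j]))
      }
      nm <- sprintf("F%02d_RIL%03d", k, seq_len(fd$size))
      taxa <- c(taxa, nm)
      fam_id <- c(fam_id, rep(sprintf("F%02d", k), fd$size))
      G <- rbind(G, Gk)
    }
    families <- tibble::tibble(taxon = taxa, family = fam_id)
    pedigree <- tibble::tibble(taxon = taxa, F = 1 - rh)
  }
  dimnames(G) <- list(taxa, snps$snp_id)

  ## paralog-merged loci: divergent duplicate present in every taxon
  paralogs <- NULL
  if (cfg$n_paralog_loci > 0L) {
    eligible <- which(loci$eff_len >= 40L)
    pick <- sample(eligible, min(cfg$n_paralog_loci, length(eligible)))
    rem_len <- nchar(enzyme$remnants[1])
    rows <- list()
    for (li in pick) {
      l <- loci[li, ]
      win <- locus_window(simref$ref, l)
      snp_off <- snp_offsets_in_locus(snps, l)
      ## divergent bases sit in the distal tag region so the duplicate
      ## collapses onto the original locus (mimicking recent paralogs
      ## whose proximal sequence is conserved)
      avail <- setdiff(seq.int(26L, l$eff_len), snp_off$offset)
      offs <- sort(sample(avail, min(cfg$paralog_divergence, length(avail))))
      bases <- character(length(offs))
      for (z in seq_along(offs)) {
        cur <- substr(win, offs[z], offs[z])
        repeat {
          b <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
          trial <- win
          substr(trial, offs[z], offs[z]) <- b
          lo <- max(1L, offs[z] - pat_len + 1L)
          hi <- min(nchar(trial), offs[z] + pat_len - 1L)
          if (!any(vapply(rxs, function(rx) {
            grepl(rx, substr(trial, lo, hi))
          }, logical(1)))) {
            bases[z] <- b
            break
          }
        }
      }
      pos <- if (l$strand == "+") l$cut_pos + offs - 1L else l$cut_pos - offs + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = l$locus_id, offset = offs - 1L, pos = pos,
        shadow_base = bases)
    }
    paralogs <- dplyr::bind_rows(rows)
  }

  structure(list(loci = loci, snps = snps, genotypes = G, taxa = taxa,
                 pedigree = pedigree, families = families,
                 paralogs = paralogs, ref = simref, config = cfg),
            class = "gbs_sim_population")
}

## plus-orientation read window of a locus (the sequence a read reports,
## read coordinates: position 1 = cut-site end)
locus_window <- function(ref, locus) {
  contig <- ref[[locus$chrom]]
  if (locus$strand == "+") {
    substr(contig, locus$cut_pos, locus$cut_pos + locus$win_len - 1L)
  } else {
    rev_comp(substr(contig, locus$cut_pos - locus$win_len + 1L,
                    locus$cut_pos))
  }
}

## true SNPs falling in a locus window, as read-coordinate offsets
snp_offsets_in_locus <- function(snps, locus) {
  if (locus$strand == "+") {
    inw <- snps$chrom == locus$chrom &
      snps$pos >= locus$cut_pos & snps$pos <= locus$cut_pos + locus$win_len - 1L
    off <- snps$pos[inw] - locus$cut_pos + 1L
    ref <- snps$ref[inw]; alt <- snps$alt[inw]
  } else {
    inw <- snps$chrom == locus$chrom &
      snps$pos <= locus$cut_pos & snps$pos >= locus$cut_pos - locus$win_len + 1L
    off <- locus$cut_pos - snps$pos[inw] + 1L
    ref <- unname(COMPLEMENT[snps$ref[inw]])
    alt <- ifelse(snps$alt[inw] == "-", "-",
                  unname(COMPLEMENT[snps$alt[inw]]))
  }
  ord <- order(off)
  tibble::tibble(snp = which(inw)[ord], offset = off[ord],
                 ref = ref[ord], alt = alt[ord])
}

## apply alleles (read-coordinate substitutions/deletions) to a window;
## deletions pull in downstream reference so the read keeps its length
apply_alleles <- function(ref, locus, offsets, alleles) {
  contig <- ref[[locus$chrom]]
  pad <- 8L
  if (locus$strand == "+") {
    hi <- min(nchar(contig), locus$cut_pos + locus$win_len - 1L + pad)
    s <- substr(contig, locus$cut_pos, hi)
  } else {
    ## after rev_comp the first read base is the cut-site end (cut_pos)
    lo <- max(1L, locus$cut_pos - locus$win_len + 1L - pad)
    s <- rev_comp(substr(contig, lo, locus$cut_pos))
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  del <- rep(FALSE, length(chars))
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    if (alleles[k] == "-") del[o] <- TRUE else chars[o] <- alleles[k]
  }
  out <- paste(chars[!del], collapse = "")
  substr(out, 1L, locus$win_len)
}

#' Haplotype window sequences of a taxon at a locus
#'
#' The 1-2 read windows a taxon can emit at a locus given its truth
#' genotypes (2 when heterozygous for at least one in-window SNP). Used by
#' the generator and by truth-checking code.
#'
#' @param pop A `gbs_sim_population`.
#' @param locus_id Locus identifier from `pop$loci`.
#' @param taxon Taxon name.
#' @param phase Optional logical vector assigning each heterozygous
#'   in-window SNP's alternate allele to haplotype 1.
#' @return Character vector of 1 or 2 window sequences.
#' @export
sim_taxon_haplotypes <- function(pop, locus_id, taxon, phase = NULL) {
  locus <- pop$loci[pop$loci$locus_id == locus_id, ]
  stopifnot(nrow(locus) == 1L)
  so <- snp_offsets_in_locus(pop$snps, locus)
  g <- pop$genotypes[taxon, so$snp]
  if (!length(so$snp) || all(g == 0L)) {
    return(locus_window(pop$ref$ref, locus))
  }
  het <- g == 1L
  if (!any(het)) {
    k <- g == 2L
    return(apply_alleles(pop$ref$ref, locus, so$offset[k], so$alt[k]))
  }
  if (is.null(phase)) phase <- rep(TRUE, sum(het))
  a1 <- g == 2L; a2 <- g == 2L
  a1[which(het)[phase]] <- TRUE
  a2[which(het)[!phase]] <- TRUE
  c(apply_alleles(pop$ref$ref, locus, so$offset[a1], so$alt[a1]),
    apply_alleles(pop$ref$ref, locus, so$offset[a2], so$alt[a2]))
}

#' Simulate GBS FASTQ files with truth provenance
#'
#' Emits reads of the form `barcode + cut-site remnant + genomic sequence`
#' (the window starts at the remnant, which is part of the genomic
#' sequence), one FASTQ (gzipped) per lane, together with the barcode key
#' file, the reference FASTA and truth tables. Per-taxon per-locus read
#' counts are Poisson(`mean_depth`); substitution errors are injected at
#' `error_rate` per base outside the barcode/remnant (by default).
#'
#' @param pop A `gbs_sim_population`.
#' @param dir Output directory (created).
#' @param provenance Also return the per-read truth provenance tibble
#'   (`read_id`, `lane`, `taxon`, `locus_id`, `hap`, `n_errors`).
#' @return Object of class `gbs_sim`: list with `fastqs` (tibble `fastq`,
#'   `flowcell`, `lane`), `key`, `key_path`, `ref_path`, `pop`, `config`,
#'   and `provenance` (or `NULL`).
#' @export
sim_gbs_fastq <- function(pop, dir, provenance = FALSE) {
  cfg <- pop$config
  set.seed(cfg$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enzyme <- pop$ref$enzyme
  rem_len <- nchar(enzyme$remnants[1])
  loci <- pop$loci
  taxa <- pop$taxa
  n_taxa <- length(taxa)
  blanks <- if (cfg$n_blanks > 0L) sprintf("BLANK%02d", seq_len(cfg$n_blanks))
            else character()
  all_names <- c(taxa, blanks)

  ## barcodes per lane: distinct equal-length random barcodes
  all_bc <- function(n) {
    out <- character(0)
    while (length(out) < n) {
      out <- unique(c(out, vapply(seq_len(n), function(i) {
        random_bases(cfg$barcode_length)
      }, character(1))))
    }
    out[seq_len(n)]
  }
  key_rows <- list()
  fastq_rows <- list()
  prov <- list()
  for (ln in seq_len(cfg$n_lanes)) {
    bcs <- all_bc(length(all_names))
    key_rows[[ln]] <- tibble::tibble(
      flowcell = cfg$flowcell, lane = as.character(ln), barcode = bcs,
      sample = all_names, prep_id = NA_character_)
    depth <- matrix(rpois(nrow(loci) * n_taxa, cfg$mean_depth),
                    nrow(loci), n_taxa)
    shadow_depth <- NULL
    para_ids <- unique(pop$paralogs$locus_id)
    if (!is.null(pop$paralogs)) {
      shadow_depth <- matrix(rpois(length(para_ids) * n_taxa,
                                   cfg$mean_depth),
                             length(para_ids), n_taxa)
    }
    seqs <- vector("list", nrow(loci))
    taxon_of <- vector("list", nrow(loci))
    locus_of <- vector("list", nrow(loci))
    for (li in seq_len(nrow(loci))) {
      d <- depth[li, ]
      total <- sum(d)
      locus <- loci[li, ]
      sdl <- 0L
      if (!is.null(shadow_depth) && locus$locus_id %in% para_ids) {
        sdl <- shadow_depth[match(locus$locus_id, para_ids), ]
      }
      if (total == 0L && sum(sdl) == 0L) next
      so <- snp_offsets_in_locus(pop$snps, locus)
      win <- locus_window(pop$ref$ref, locus)
      if (!nrow(so)) {
        s <- rep(win, total)
        tx <- rep.int(seq_len(n_taxa), d)
      } else {
        g <- pop$genotypes[, so$snp, drop = FALSE]
        combo <- apply(g, 1L, paste, collapse = "")
        s <- character(0)
        tx <- integer(0)
        for (cb in unique(combo[d > 0L])) {
          members <- which(combo == cb & d > 0L)
          gk <- g[members[1], ]
          if (any(gk == 1L)) {
            ## heterozygous taxa: per-taxon phase, per-read haplotype
            for (m in members) {
              nh <- sum(gk == 1L)
              phase <- runif(nh) < 0.5
              haps <- sim_taxon_haplotypes(pop, locus$locus_id, taxa[m],
                                           phase = phase)
              pickh <- 1L + (runif(d[m]) < 0.5)
              s <- c(s, haps[pickh])
              tx <- c(tx, rep.int(m, d[m]))
            }
          } else {
            k <- gk == 2L
            hap <- if (any(k)) {
              apply_alleles(pop$ref$ref, locus, so$offset[k], so$alt[k])
            } else win
            nreads <- sum(d[members])
            s <- c(s, rep(hap, nreads))
            tx <- c(tx, rep.int(members, d[members]))
          }
        }
      }
      if (any(sdl > 0L)) {
        pl <- pop$paralogs[pop$paralogs$locus_id == locus$locus_id, ]
        shadow <- win
        for (z in seq_len(nrow(pl))) {
          substr(shadow, pl$offset[z] + 1L, pl$offset[z] + 1L) <-
            pl$shadow_base[z]
        }
        s <- c(s, rep(shadow, sum(sdl)))
        tx <- c(tx, rep.int(seq_len(n_taxa), sdl))
      }
      seqs[[li]] <- s
      taxon_of[[li]] <- tx
      locus_of[[li]] <- rep.int(li, length(s))
    }
    genomic <- unlist(seqs, use.names = FALSE)
    tx <- unlist(taxon_of, use.names = FALSE)
    lo <- unlist(locus_of, use.names = FALSE)
    n_reads <- length(genomic)
    n_err_vec <- integer(n_reads)
    if (cfg$error_rate > 0 && n_reads > 0L) {
      widths <- nchar(genomic)
      protect <- if (cfg$errors_in_barcode) 0L else rem_len
      n_err_vec <- rbinom(n_reads, pmax(0L, widths - protect),
                          cfg$error_rate)
      idx <- rep.int(seq_len(n_reads), n_err_vec)
      if (length(idx)) {
        posu <- protect + 1L +
          floor(runif(length(idx)) * (widths[idx] - protect))
        shift <- sample(1:3, length(idx), replace = TRUE)
        while (length(idx)) {
          take <- !duplicated(idx)
          i <- idx[take]; p <- posu[take]; sh <- shift[take]
          cur <- match(substr(genomic[i], p, p), c("A", "C", "G", "T")) - 1L
          nb <- c("A", "C", "G", "T")[(cur + sh) %% 4L + 1L]
          substr(genomic[i], p, p) <- nb
          idx <- idx[!take]; posu <- posu[!take]; shift <- shift[!take]
        }
      }
    }
    reads <- paste0(bcs[tx], genomic)
    ord <- sample.int(n_reads)
    reads <- reads[ord]
    ids <- sprintf("SIM_%s_%d_%07d", cfg$flowcell, ln, seq_len(n_reads))
    fq <- file.path(dir, sprintf("%s_%d.fastq.gz", cfg$flowcell, ln))
    write_fastq(reads, ids, fq)
    fastq_rows[[ln]] <- tibble::tibble(fastq = fq, flowcell = cfg$flowcell,
                                       lane = as.character(ln))
    if (provenance) {
      prov[[ln]] <- tibble::tibble(
        read_id = ids, lane = as.character(ln),
        taxon = all_names[tx[ord]], locus_id = loci$locus_id[lo[ord]],
        n_errors = n_err_vec[ord])
    }
  }
  key <- do.call(rbind, key_rows)
  key <- barcode_key(key$flowcell, key$lane, key$barcode, key$sample)
  key_path <- file.path(dir, "key.tsv")
  utils::write.table(
    data.frame(Flowcell = key$flowcell, Lane = key$lane,
               Barcode = key$barcode, Sample = key$sample),
    key_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ref_path <- file.path(dir, "reference.fa")
  x <- Biostrings::DNAStringSet(pop$ref$ref)
  Biostrings::writeXStringSet(x, ref_path)
  utils::write.table(as.data.frame(pop$snps),
                     file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(taxon = rownames(pop$genotypes), pop$genotypes,
               check.names = FALSE),
    file.path(dir, "truth_genotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(Taxon = pop$pedigree$taxon, F = pop$pedigree$F),
    file.path(dir, "pedigree.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(pop$families)) {
    utils::write.table(
      data.frame(Taxon = pop$families$taxon, Family = pop$families$family),
      file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  structure(list(fastqs = dplyr::bind_rows(fastq_rows), key = key,
                 key_path = key_path, ref_path = ref_path, pop = pop,
                 config = cfg,
                 provenance = if (provenance) dplyr::bind_rows(prov)
                              else NULL),
            class = "gbs_sim")
}

#' One-shot synthetic GBS experiment
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param provenance Keep per-read provenance.
#' @return A `gbs_sim` (see [sim_gbs_fastq()]).
#' @export
sim_gbs_experiment <- function(cfg, dir, provenance = FALSE) {
  simref <- sim_reference(cfg)
  pop <- sim_population(cfg, simref)
  sim_gbs_fastq(pop, dir, provenance = provenance)
}

#' Genotype table of the simulated truth
#'
#' Truth genotypes as a `gbs_genotypes` (major = reference allele,
#' minor = alternate), e.g. as input to [estimate_error_rates()].
#' @param pop A `gbs_sim_population`.
#' @return A `gbs_genotypes` (no depths).
#' @export
sim_truth_genotypes <- function(pop) {
  snps <- pop$snps
  geno <- t(pop$genotypes)  # sites x taxa
  new_genotypes(
    tibble::tibble(site_id = snps$snp_id, chrom = snps$chrom,
                   pos = snps$pos, major = snps$ref, minor = snps$alt,
                   alleles = paste(snps$ref, snps$alt, sep = ",")),
    pop$taxa, geno)
}

#' Inject genotype-call errors
#'
#' Flips each non-missing call with probability `rate`: homozygotes become
#' the opposite homozygote, heterozygotes a random homozygote — the
#' call-level error model used to exercise the family error-rate
#' estimator.
#' @param gt A `gbs_genotypes`.
#' @param rate Per-call error probability.
#' @param seed Seed.
#' @return The perturbed `gbs_genotypes`.
#' @export
inject_genotype_errors <- function(gt, rate, seed = 1L) {
  set.seed(seed)
  g <- gt$geno
  hit <- which(!is.na(g) & matrix(runif(length(g)) < rate, nrow(g)))
  if (length(hit)) {
    old <- g[hit]
    g[hit] <- ifelse(old == 0L, 2L,
                     ifelse(old == 2L, 0L,
                            sample(c(0L, 2L), length(old), replace = TRUE)))
  }
  gt$geno <- g
  gt
}

#' Truth SNPs expected to be discoverable from a master tag list
#'
#' A true SNP is discoverable by tag-based discovery iff two haplotype tag
#' windows that differ at the SNP both survive into the master tag list
#' (rare alleles can fall below the experiment-wide minimum tag count).
#' This computes, per truth SNP, whether that holds at any locus covering
#' it — the expected discovery set for an error-free run.
#'
#' @param pop A `gbs_sim_population`.
#' @param master A `gbs_tagcounts` master list.
#' @return The truth SNP table with logical columns `polymorphic` (in the
#'   sampled taxa) and `expected` (discoverable from this master list).
#' @export
sim_expected_discoveries <- function(pop, master) {
  snps <- pop$snps
  G <- pop$genotypes
  poly <- apply(G, 2L, function(g) length(unique(g)) > 1L)
  expected <- logical(nrow(snps))
  for (li in seq_len(nrow(pop$loci))) {
    locus <- pop$loci[li, ]
    so <- snp_offsets_in_locus(snps, locus)
    so <- so[so$offset <= locus$eff_len, ]
    if (!nrow(so)) next
    ## distinct haplotype windows present in the population: enumerate
    ## distinct genotype combinations (heterozygous combos contribute both
    ## phase arrangements)
    g <- G[, so$snp, drop = FALSE]
    combos <- unique(as.data.frame(g))
    haps <- list()
    for (r in seq_len(nrow(combos))) {
      gk <- as.integer(combos[r, ])
      if (any(gk == 1L)) {
        for (ph in list(gk >= 1L, gk == 2L)) {
          haps <- c(haps, apply_alleles(pop$ref$ref, locus,
                                        so$offset[ph], so$alt[ph]))
        }
      } else {
        k <- gk == 2L
        haps <- c(haps, apply_alleles(pop$ref$ref, locus, so$offset[k],
                                      so$alt[k]))
      }
    }
    ## post-trim tag of each haplotype = first eff_len bases
    tags <- unique(substr(unlist(haps), 1L, locus$eff_len))
    tags <- tags[tags %in% master$tag]
    if (length(tags) < 2L) next
    mat <- do.call(rbind, strsplit(tags, "", fixed = TRUE))
    for (k in seq_len(nrow(so))) {
      if (so$offset[k] > ncol(mat)) next
      if (length(unique(mat[, so$offset[k]])) > 1L) {
        expected[so$snp[k]] <- TRUE
      }
    }
  }
  snps$polymorphic <- poly
  snps$expected <- expected & poly
  snps
}

#' Compare a called genotype table against simulated truth
#'
#' Maps each called site to the truth table (non-truth sites — e.g.
#' paralog-derived or error-derived SNPs — are compared against a
#' homozygous-reference truth) and reports per-call concordance.
#'
#' @param gt A `gbs_genotypes`.
#' @param pop The `gbs_sim_population` truth.
#' @return List: `n_called`, `n_correct`, `error_rate` (1 - concordance
#'   among non-missing calls), and the per-site tibble `by_site`.
#' @export
sim_genotype_concordance <- function(gt, pop) {
  m <- match(paste(gt$sites$chrom, gt$sites$pos),
             paste(pop$snps$chrom, pop$snps$pos))
  n_called <- 0L
  n_correct <- 0L
  rows <- list()
  taxa <- intersect(gt$taxa, pop$taxa)
  ti <- match(taxa, gt$taxa)
  for (i in seq_len(nrow(gt$sites))) {
    called <- gt$geno[i, ti]
    ok <- !is.na(called)
    if (is.na(m[i])) {
      ## not a true variant site: truth is homozygous reference; any
      ## non-missing non-hom-ref call is an error. The reference allele at
      ## a fabricated site is taken as the major allele.
      correct <- sum(called[ok] == 0L)
    } else {
      tru <- pop$genotypes[taxa, m[i]]
      alt <- pop$snps$alt[m[i]]
      dos <- if (identical(gt$sites$minor[i], alt)) called
             else if (identical(gt$sites$major[i], alt)) 2L - called
             else rep(NA_integer_, length(called))  # allele mismatch
      correct <- sum(!is.na(dos) & dos == tru & ok)
    }
    rows[[i]] <- tibble::tibble(
      site_id = gt$sites$site_id[i], is_true_snp = !is.na(m[i]),
      n_called = sum(ok), n_correct = correct)
    n_called <- n_called + sum(ok)
    n_correct <- n_correct + correct
  }
  by_site <- dplyr::bind_rows(rows)
  list(n_called = n_called, n_correct = n_correct,
       error_rate = if (n_called > 0) 1 - n_correct / n_called else NA_real_,
       by_site = by_site)
}
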
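#' Group uniquely placed tags into TagLoci
#'
#' Tags that align to the exact same cut-site coordinate with the same
#' orientation (but not necessarily the same length) comprise a TagLocus —
#' the unit of SNP discovery. `MULTIPLE` and `UNALIGNED` tags belong to no
#' locus.
#'
#' @param topm A `gbs_topm`.
#' @return Tibble in position order: `locus_id`, `chrom`, `strand`,
#'   `cut_pos`, `tags` (list column of member tag sequences in canonical
#'   tag order).
#' @export
group_tag_loci <- function(topm) {
  uni <- topm_by_position(topm)
  if (nrow(uni) == 0L) {
    return(tibble::tibble(locus_id = character(), chrom = character(),
                          strand = character(), cut_pos = integer(),
                          tags = list()))
  }
  key <- paste(uni$chrom, uni$cut_pos, uni$strand, sep = "\r")
  grp <- split(uni$tag, factor(key, levels = unique(key)))
  first <- !duplicated(key)
  tibble::tibble(
    locus_id = sprintf("L%s_%d%s", uni$chrom[first], uni$cut_pos[first],
                       ifelse(uni$strand[first] == "+", "F", "R")),
    chrom = uni$chrom[first], strand = uni$strand[first],
    cut_pos = uni$cut_pos[first],
    tags = lapply(unname(grp), sort_tags)
  )
}

#' Filter thresholds for discovered SNPs
#'
#' The standard Discovery filters: minimum minor allele frequency, minimum
#' inbreeding coefficient `F_IT = 1 - Ho/He` (computed among designated
#' inbred taxa when a pedigree is supplied), minimum inbred coverage
#' (strict `>`), maximum inbred heterozygosity score (strict `<`), and
#' minimum proportion of all taxa covered by the TagLocus. Setting
#' `min_fit = -Inf` disables the F_IT clause (e.g. for a MAF-only filter);
#' the inbred coverage/heterozygosity clauses apply only when a pedigree is
#' supplied. `min_f` is the pedigree inbreeding coefficient at or above
#' which a taxon counts as inbred.
#'
#' @param min_maf Minimum minor allele frequency (`>=`, default 0.001).
#' @param min_fit Minimum F_IT (`>=`, default 0.8); `-Inf` disables.
#' @param min_inbred_coverage Minimum proportion of inbred taxa with a
#'   non-missing genotype (`>`, default 0.15).
#' @param max_inbred_het_score Maximum inbred heterozygosity score (`<`,
#'   default 0.21).
#' @param min_locus_coverage Minimum proportion of all taxa with reads at
#'   the TagLocus (`>=`, default 0.1).
#' @param min_f Minimum expected inbreeding coefficient defining an inbred
#'   taxon (default 0.8).
#' @return A list of class `gbs_filters`.
#' @export
discovery_filters <- function(min_maf = 0.001, min_fit = 0.8,
                              min_inbred_coverage = 0.15,
                              max_inbred_het_score = 0.21,
                              min_locus_coverage = 0.1, min_f = 0.8) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_inbred_coverage <= 1, max_inbred_het_score >= 0,
            min_locus_coverage >= 0, min_locus_coverage <= 1,
            min_f >= 0, min_f <= 1)
  structure(list(min_maf = min_maf, min_fit = min_fit,
                 min_inbred_coverage = min_inbred_coverage,
                 max_inbred_het_score = max_inbred_het_score,
                 min_locus_coverage = min_locus_coverage, min_f = min_f),
            class = "gbs_filters")
}

#' Population-genetic statistics of a called SNP
#'
#' Minor allele frequency `q`, observed heterozygosity `Ho`, expected
#' heterozygosity `He = 2q(1-q)` and `F_IT = 1 - Ho/He` are computed over
#' the designated subpopulation (the inbred taxa when `inbred` is supplied,
#' all taxa otherwise). The inbred-specific filter surface is computed over
#' the inbred taxa: coverage (proportion non-missing), `n_inbred_hets`
#' (inbreds called heterozygous), `n_inbreds_gt1_homo_min` (inbreds with
#' site depth > 1 called minor-allele homozygote), and the inbred
#' heterozygosity score
#' `nInbredHets / (nInbredsGT1ReadHomoMin + nInbredHets + 0.5)`.
#' A monomorphic subpopulation gives `He = 0` and an undefined `F_IT`
#' (`NA`), which fails the F_IT filter by convention.
#'
#' @param geno Integer genotype codes (0 hom-major / 1 het / 2 hom-minor /
#'   NA), one per taxon.
#' @param site_depth Total site depth (major + minor allele reads) per
#'   taxon.
#' @param inbred Logical vector designating inbred taxa, or `NULL` when no
#'   pedigree is available.
#' @return One-row tibble of the statistics.
#' @export
compute_site_stats <- function(geno, site_depth, inbred = NULL) {
  sub <- if (is.null(inbred)) rep(TRUE, length(geno)) else inbred
  g <- geno[sub]
  called <- !is.na(g)
  ntot <- sum(called)
  if (ntot > 0L) {
    n1 <- sum(g == 1L, na.rm = TRUE)
    f2 <- (2 * sum(g == 2L, na.rm = TRUE) + n1) / (2 * ntot)
    q <- min(f2, 1 - f2)
    ho <- n1 / ntot
    he <- 2 * q * (1 - q)
    fit <- if (he > 0) 1 - ho / he else NA_real_
  } else {
    q <- NA_real_; ho <- NA_real_; he <- NA_real_; fit <- NA_real_
  }
  if (!is.null(inbred) && any(inbred)) {
    gi <- geno[inbred]
    di <- site_depth[inbred]
    inbred_coverage <- mean(!is.na(gi))
    nih <- sum(gi == 1L, na.rm = TRUE)
    ngt1 <- sum(!is.na(gi) & gi == 2L & di > 1)
    score <- nih / (ngt1 + nih + 0.5)
  } else {
    inbred_coverage <- NA_real_; nih <- NA_integer_
    ngt1 <- NA_integer_; score <- NA_real_
  }
  tibble::tibble(
    maf = q, ho = ho, he = he, f_it = fit,
    inbred_coverage = inbred_coverage,
    n_inbred_hets = as.integer(nih),
    n_inbreds_gt1_homo_min = as.integer(ngt1),
    inbred_het_score = score,
    n_called = sum(!is.na(geno))
  )
}

#' Apply the Discovery SNP filters
#'
#' Retention rule: `locus_coverage >= min_locus_coverage` AND
#' `maf >= min_maf` AND `f_it >= min_fit` (undefined F_IT fails; clause
#' skipped when `min_fit = -Inf`) AND, when a pedigree was supplied,
#' `inbred_coverage > min_inbred_coverage` AND
#' `inbred_het_score < max_inbred_het_score`.
#'
#' @param stats Site table containing the columns produced by
#'   [compute_site_stats()] plus `locus_coverage`.
#' @param filters A [discovery_filters()] configuration.
#' @param has_pedigree Whether inbred-based clauses apply.
#' @return `stats` with logical column `retained` and character
#'   `reject_reason` (comma-joined failed clauses, `""` if retained).
#' @export
filter_snps <- function(stats, filters, has_pedigree = FALSE) {
  n <- nrow(stats)
  fail <- matrix(FALSE, n, 5,
                 dimnames = list(NULL, c("locus_coverage", "maf", "f_it",
                                         "inbred_coverage",
                                         "inbred_het_score")))
  fail[, "locus_coverage"] <- stats$locus_coverage < filters$min_locus_coverage
  fail[, "maf"] <- is.na(stats$maf) | stats$maf < filters$min_maf
  if (is.finite(filters$min_fit)) {
    fail[, "f_it"] <- is.na(stats$f_it) | stats$f_it < filters$min_fit
  }
  if (has_pedigree) {
    if (is.finite(filters$min_inbred_coverage)) {
      fail[, "inbred_coverage"] <- is.na(stats$inbred_coverage) |
        stats$inbred_coverage <= filters$min_inbred_coverage
    }
    if (is.finite(filters$max_inbred_het_score)) {
      fail[, "inbred_het_score"] <- is.na(stats$inbred_het_score) |
        stats$inbred_het_score >= filters$max_inbred_het_score
    }
  }
  stats$retained <- rowSums(fail) == 0L
  stats$reject_reason <- apply(fail, 1L, function(f) {
    paste(colnames(fail)[f], collapse = ",")
  })
  stats
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-")
ALLELE_LEVELS <- c("A", "C", "G", "T", "-")

## SNP candidates of one locus: polymorphic alignment columns with allele
## depths and genotype calls. Returns NULL when the locus is monomorphic.
discover_locus_snps <- function(locus, tag_depth, err = 0.01,
                                lr_threshold = 1) {
  tags <- locus$tags
  counts <- rowSums(tag_depth)
  msa <- align_tag_locus(tags, counts)
  mat <- msa_matrix(msa)
  n_taxa <- ncol(tag_depth)
  out <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    present <- !is.na(col)
    symbols <- unique(col[present])
    if (length(symbols) < 2L) next
    dep <- matrix(0, nrow = length(symbols), ncol = n_taxa,
                  dimnames = list(symbols, colnames(tag_depth)))
    for (s in symbols) {
      rows <- which(present & col == s)
      dep[s, ] <- colSums(tag_depth[rows, , drop = FALSE])
    }
    ord <- order(-rowSums(dep), match(symbols, ALLELE_LEVELS))
    symbols <- symbols[ord]
    dep <- dep[ord, , drop = FALSE]
    d_major <- dep[1L, ]
    d_minor <- dep[2L, ]
    geno <- call_genotypes(d_major, d_minor, err = err,
                           lr_threshold = lr_threshold)
    ## reported position and alleles are plus-strand oriented
    minus <- locus$strand == "-"
    pos <- if (minus) locus$cut_pos - (j - 1L) else locus$cut_pos + (j - 1L)
    alleles <- if (minus) unname(COMPLEMENT[symbols]) else symbols
    out[[length(out) + 1L]] <- list(
      offset = j - 1L, pos = as.integer(pos),
      alleles = alleles, aln_alleles = symbols,
      tag_allele = col,  # per member tag, alignment orientation
      d_major = d_major, d_minor = d_minor, geno = geno
    )
  }
  if (!length(out)) return(NULL)
  out
}

#' Run the Discovery SNP caller
#'
#' For every TagLocus: multiple-align the member tags, tally per-taxon
#' allele depths from the TBT at each polymorphic alignment column, call
#' genotypes with the binomial likelihood-ratio caller, compute the site
#' statistics, apply the filters, and write the retained variants (each
#' member tag's allele and alignment offset) into the TOPM. The result is a
#' production-ready TOPM plus the full site report.
#'
#' When the same reference position is discovered from both strands
#' (overlapping loci), only the copy with the greater total depth is
#' retained (ties favour the plus strand).
#'
#' @param topm A `gbs_topm` of master tags.
#' @param tbt The matching `gbs_tbt`.
#' @param pedigree Optional tibble `taxon`, `F` of expected inbreeding
#'   coefficients (see [read_pedigree()]); taxa with `F >= filters$min_f`
#'   are the inbred set used by the F_IT and inbred filters.
#' @param filters A [discovery_filters()] configuration.
#' @param err,lr_threshold Genotype caller parameters
#'   ([call_genotypes()]).
#' @return Object of class `gbs_discovery`: list with `topm` (production
#'   ready, site registry attached), `sites` (per-candidate statistics and
#'   retention), `genotypes` (a `gbs_genotypes` of the retained sites), and
#'   `report` (per-locus candidate/retained counts).
#' @export
run_discovery <- function(topm, tbt, pedigree = NULL,
                          filters = discovery_filters(), err = 0.01,
                          lr_threshold = 1) {
  loci <- group_tag_loci(topm)
  taxa <- tbt$taxa
  inbred <- NULL
  if (!is.null(pedigree)) {
    fval <- pedigree$F[match(taxa, pedigree$taxon)]
    inbred <- !is.na(fval) & fval >= filters$min_f
  }
  cand <- list()
  locus_report <- list()
  for (li in seq_len(nrow(loci))) {
    locus <- list(locus_id = loci$locus_id[li], chrom = loci$chrom[li],
                  strand = loci$strand[li], cut_pos = loci$cut_pos[li],
                  tags = loci$tags[[li]])
    rows <- match(locus$tags, tbt$tags)
    tag_depth <- tbt$depth[rows, , drop = FALSE]
    locus_coverage <- mean(colSums(tag_depth) > 0)
    snps <- discover_locus_snps(locus, tag_depth, err, lr_threshold)
    n_cand <- if (is.null(snps)) 0L else length(snps)
    locus_report[[li]] <- tibble::tibble(
      locus_id = locus$locus_id, n_tags = length(locus$tags),
      n_candidates = n_cand)
    if (is.null(snps)) next
    for (s in snps) {
      st <- compute_site_stats(s$geno, s$d_major + s$d_minor, inbred)
      cand[[length(cand) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          locus_id = locus$locus_id, chrom = locus$chrom,
          strand = locus$strand, cut_pos = locus$cut_pos,
          offset = s$offset, pos = s$pos,
          alleles = paste(s$alleles, collapse = ","),
          major = s$alleles[1], minor = s$alleles[2],
          locus_coverage = locus_coverage,
          total_depth = sum(s$d_major + s$d_minor)),
        st,
        tibble::tibble(data = list(s)))
    }
  }
  report <- dplyr::bind_rows(locus_report)
  if (!length(cand)) {
    sites <- empty_site_stats()
    gt <- new_genotypes(sites[0, ], taxa,
                        matrix(NA_integer_, 0, length(taxa)),
                        matrix(0, 0, length(taxa)),
                        matrix(0, 0, length(taxa)))
    return(structure(list(topm = topm, sites = sites, genotypes = gt,
                          report = report, filters = filters),
                     class = "gbs_discovery"))
  }
  sites <- dplyr::bind_rows(cand)
  sites <- filter_snps(sites, filters, has_pedigree = !is.null(pedigree))

  ## de-duplicate positions discovered from both strands (retained only)
  sites <- sites[order(sites$chrom, sites$pos, -sites$total_depth,
                       sites$strand, method = "radix"), ]
  key <- paste(sites$chrom, sites$pos, sep = "\r")
  ret_idx <- which(sites$retained)
  dup_in_ret <- ret_idx[duplicated(key[ret_idx])]
  sites$retained[dup_in_ret] <- FALSE
  sites$reject_reason[dup_in_ret] <- "duplicate_position"

  ## cap variants per tag: process retained sites per locus in offset
  ## order; a site whose annotation would push any member tag over the
  ## per-tag variant bound is dropped
  maxv <- attr(topm, "max_variants")
  var_count <- setNames(integer(nrow(topm)), topm$tag)
  keep_order <- order(sites$chrom, sites$cut_pos, sites$strand, sites$offset,
                      method = "radix")
  for (i in keep_order) {
    if (!sites$retained[i]) next
    s <- sites$data[[i]]
    member_tags <- loci$tags[[match(sites$locus_id[i], loci$locus_id)]]
    covering <- member_tags[!is.na(s$tag_allele)]
    if (any(var_count[covering] + 1L > maxv)) {
      sites$retained[i] <- FALSE
      sites$reject_reason[i] <- "max_variants"
      next
    }
    var_count[covering] <- var_count[covering] + 1L
  }

  retained <- sites[sites$retained, ]
  ## annotate the TOPM: per member tag, the allele at each retained site
  if (nrow(retained)) {
    per_tag <- list()
    for (i in seq_len(nrow(retained))) {
      s <- retained$data[[i]]
      member_tags <- loci$tags[[match(retained$locus_id[i], loci$locus_id)]]
      cov <- which(!is.na(s$tag_allele))
      for (k in cov) {
        tg <- member_tags[k]
        per_tag[[tg]] <- dplyr::bind_rows(
          per_tag[[tg]],
          tibble::tibble(offset = s$offset, allele = s$tag_allele[k]))
      }
    }
    for (tg in names(per_tag)) {
      v <- per_tag[[tg]][order(per_tag[[tg]]$offset), ]
      topm <- annotate_variants(topm, tg, v)
    }
  }

  registry <- finish_site_registry(tibble::tibble(
    chrom = retained$chrom, strand = retained$strand,
    cut_pos = retained$cut_pos, offset = retained$offset,
    pos = retained$pos, alleles = retained$alleles))
  attr(topm, "sites") <- registry

  ord <- order(retained$chrom, retained$pos, method = "radix")
  retained <- retained[ord, ]
  geno <- do.call(rbind, lapply(retained$data, `[[`, "geno"))
  dM <- do.call(rbind, lapply(retained$data, `[[`, "d_major"))
  dm <- do.call(rbind, lapply(retained$data, `[[`, "d_minor"))
  gt <- new_genotypes(
    tibble::tibble(site_id = paste0("S", retained$chrom, "_", retained$pos),
                   chrom = retained$chrom, pos = retained$pos,
                   major = retained$major, minor = retained$minor,
                   alleles = retained$alleles),
    taxa,
    if (is.null(geno)) matrix(NA_integer_, 0, length(taxa)) else geno,
    if (is.null(dM)) matrix(0, 0, length(taxa)) else dM,
    if (is.null(dm)) matrix(0, 0, length(taxa)) else dm)

  sites$data <- NULL
  report <- dplyr::left_join(
    report,
    dplyr::summarise(dplyr::group_by(
      tibble::tibble(locus_id = sites$locus_id, retained = sites$retained),
      .data$locus_id), n_retained = sum(.data$retained), .groups = "drop"),
    by = "locus_id")
  report$n_retained[is.na(report$n_retained)] <- 0L
  structure(list(topm = topm, sites = tibble::as_tibble(sites),
                 genotypes = gt, report = report, filters = filters),
            class = "gbs_discovery")
}

empty_site_stats <- function() {
  tibble::tibble(
    locus_id = character(), chrom = character(), strand = character(),
    cut_pos = integer(), offset = integer(), pos = integer(),
    alleles = character(), major = character(), minor = character(),
    locus_coverage = numeric(), total_depth = numeric(), maf = numeric(),
    ho = numeric(), he = numeric(), f_it = numeric(),
    inbred_coverage = numeric(), n_inbred_hets = integer(),
    n_inbreds_gt1_homo_min = integer(), inbred_het_score = numeric(),
    n_called = integer(), retained = logical(), reject_reason = character())
}

#' Read a pedigree file of expected inbreeding coefficients
#' @param path Tab-delimited file with header columns `Taxon`, `F`.
#' @return Tibble `taxon`, `F` (numeric in `[0, 1]`).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("Taxon", "F") %in% names(df))) {
    stop("pedigree file must have columns Taxon and F")
  }
  f <- as.numeric(df$F)
  if (any(is.na(f) | f < 0 | f > 1)) {
    stop("pedigree F values must be numeric in [0, 1]")
  }
  tibble::tibble(taxon = as.character(df$Taxon), F = f)
}
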
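#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Load a reference as a named character vector
#' @param ref Path to a FASTA file, or a named character vector of contigs.
#' @return Named character vector of upper-case contig sequences.
#' @export
read_reference <- function(ref) {
  if (is.character(ref) && length(ref) == 1L && is.null(names(ref)) &&
      file.exists(ref)) {
    x <- Biostrings::readDNAStringSet(ref)
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  stopifnot(!is.null(names(ref)))
  toupper(ref)
}

#' Cut-site anchors of a reference
#'
#' Scans the reference for the enzyme's recognition pattern and returns the
#' two tag anchors each occurrence generates: a plus-strand tag starting
#' just after the cut and a minus-strand tag ending at the mirrored cut
#' position on the other strand. `cut_pos` is the reference coordinate of
#' the cut-site end of the tag (leftmost tag base on `+`, rightmost on
#' `-`) — the coordinate a correctly placed tag reports in the TOPM.
#'
#' @param ref Reference (path or named character vector).
#' @param enzyme Enzyme model ([gbs_enzyme()]); the first remnant's length
#'   defines the cut offset within the recognition pattern.
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @return Tibble: `chrom`, `strand`, `cut_pos`, `site_start` (position of
#'   the recognition-pattern match).
#' @export
cut_site_anchors <- function(ref, enzyme, strands = "both") {
  ref <- read_reference(ref)
  rem_len <- nchar(enzyme$remnants[1])
  out <- list()
  for (chrom in names(ref)) {
    for (pat in enzyme$internal_patterns) {
      rx <- iupac_regex(pat)
      pat_len <- nchar(pat)
      m <- gregexpr(rx, ref[[chrom]])[[1]]
      if (m[1] == -1L) next
      p <- as.integer(m)
      if (strands %in% c("both", "plus")) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom, strand = "+",
          cut_pos = p + pat_len - rem_len, site_start = p)
      }
      if (strands %in% c("both", "minus")) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom, strand = "-",
          cut_pos = p + rem_len - 1L, site_start = p)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), strand = character(),
                          cut_pos = integer(), site_start = integer()))
  }
  anchors <- dplyr::bind_rows(out)
  anchors[order(anchors$chrom, anchors$cut_pos, anchors$strand,
                method = "radix"), ]
}

anchor_windows <- function(anchors, ref, max_len = 64L) {
  ref <- read_reference(ref)
  n <- nrow(anchors)
  win <- character(n)
  avail <- integer(n)
  for (i in seq_len(n)) {
    contig <- ref[[anchors$chrom[i]]]
    if (anchors$strand[i] == "+") {
      s <- anchors$cut_pos[i]
      e <- min(nchar(contig), s + max_len - 1L)
      win[i] <- substr(contig, s, e)
    } else {
      e <- anchors$cut_pos[i]
      s <- max(1L, e - max_len + 1L)
      win[i] <- rev_comp(substr(contig, s, e))
    }
    avail[i] <- nchar(win[i])
  }
  anchors$window <- win
  anchors$avail <- avail
  anchors
}

#' Place master tags on a reference and write SAM
#'
#' A lightweight tag aligner for restriction-site-anchored reads: every GBS
#' tag must begin at an enzyme cut site, so the candidate placements of a
#' tag are the scanned cut-site anchors whose first `prefix_len` reference
#' bases match the tag exactly. Candidates are scored by Hamming distance
#' (substitutions only); when no candidate is within `max_mismatch` and
#' `allow_indels` is set, a gapped alignment (free trailing gaps) against
#' the anchor window is tried. A tag is placed uniquely iff a single best
#' scoring candidate exists; equal-best candidates are reported as primary
#' plus secondary records with equal alignment scores (`AS`/`XS`), which
#' [import_sam()] classifies as `MULTIPLE`.
#'
#' @param master Master tag list (`gbs_tagcounts`).
#' @param ref Reference (FASTA path or named character vector).
#' @param enzyme Enzyme model.
#' @param sam_path Output SAM path.
#' @param max_mismatch Maximum Hamming distance for an ungapped placement.
#' @param allow_indels Try a gapped alignment when no ungapped placement
#'   fits.
#' @param prefix_len Anchor index prefix length (exact-match seed).
#' @return Invisibly, a placement summary tibble (`status` counts).
#' @export
align_tags <- function(master, ref, enzyme, sam_path, max_mismatch = 3L,
                       allow_indels = TRUE, prefix_len = 12L) {
  ref <- read_reference(ref)
  anchors <- anchor_windows(cut_site_anchors(ref, enzyme), ref)
  ## two alternative exact seeds, so one mismatch cannot hide a placement
  idx1 <- split(seq_len(nrow(anchors)), substr(anchors$window, 1L, prefix_len))
  idx2 <- split(seq_len(nrow(anchors)),
                substr(anchors$window, prefix_len + 1L, 2L * prefix_len))
  qname <- sprintf("tag%06d_count%d", seq_len(nrow(master)), master$count)
  recs <- vector("list", nrow(master))
  status <- character(nrow(master))

  min_gapped_score <- function(len) 2L * len - 12L

  for (t in seq_len(nrow(master))) {
    tag <- master$tag[t]
    len <- nchar(tag)
    cand <- idx1[[substr(tag, 1L, prefix_len)]]
    if (len >= 2L * prefix_len) {
      cand <- union(cand,
                    idx2[[substr(tag, prefix_len + 1L, 2L * prefix_len)]])
    }
    hits <- NULL
    if (length(cand)) {
      wins <- substr(anchors$window[cand], 1L, len)
      d <- hamming_cpp(rep(tag, length(cand)), wins)
      ok <- which(d <= max_mismatch)
      if (length(ok)) {
        score <- 2L * (len - d[ok]) - d[ok]
        hits <- tibble::tibble(anchor = cand[ok], score = score,
                               nm = d[ok], cigar = paste0(len, "M"),
                               ref_width = nchar(wins[ok]))
      } else if (allow_indels) {
        g <- lapply(cand, function(a) {
          al <- nw_align_cpp(tag, anchors$window[a])
          c(score = al$score, list(a = al$a, b = al$b))
        })
        sc <- vapply(g, function(z) z$score, numeric(1))
        ok2 <- which(sc >= min_gapped_score(len))
        if (length(ok2)) {
          cig <- lapply(g[ok2], function(z) alignment_cigar(z$a, z$b))
          hits <- tibble::tibble(
            anchor = cand[ok2], score = sc[ok2],
            nm = vapply(cig, `[[`, 0L, "nm"),
            cigar = vapply(cig, `[[`, "", "cigar"),
            ref_width = vapply(cig, `[[`, 0L, "ref_width"))
        }
      }
    }
    if (is.null(hits) || nrow(hits) == 0L) {
      status[t] <- "UNALIGNED"
      recs[[t]] <- data.frame(qname = qname[t], flag = 4L, rname = "*",
                              pos = 0L, mapq = 0L, cigar = "*", seq = tag,
                              opt = "")
      next
    }
    best <- max(hits$score)
    top <- hits[hits$score == best, , drop = FALSE]
    unique_best <- nrow(top) == 1L
    status[t] <- if (unique_best) "UNIQUE" else "MULTIPLE"
    xs <- if (unique_best) {
      rest <- hits$score[hits$score < best]
      if (length(rest)) max(rest) else NA_integer_
    } else best
    ord <- order(anchors$chrom[top$anchor], anchors$cut_pos[top$anchor],
                 anchors$strand[top$anchor], method = "radix")
    top <- top[ord, , drop = FALSE]
    recs[[t]] <- do.call(rbind, lapply(seq_len(nrow(top)), function(h) {
      a <- top$anchor[h]
      minus <- anchors$strand[a] == "-"
      pos <- if (minus) anchors$cut_pos[a] - top$ref_width[h] + 1L
             else anchors$cut_pos[a]
      opt <- sprintf("NM:i:%d\tAS:i:%d", top$nm[h], top$score[h])
      if (!is.na(xs)) opt <- paste0(opt, sprintf("\tXS:i:%d", xs))
      cig <- top$cigar[h]
      if (minus) cig <- reverse_cigar(cig)
      data.frame(
        qname = qname[t], flag = (if (minus) 16L else 0L) +
          (if (h > 1L) 256L else 0L),
        rname = anchors$chrom[a], pos = pos,
        mapq = if (unique_best) 40L else 0L, cigar = cig,
        seq = if (minus) rev_comp(tag) else tag, opt = opt)
    }))
  }
  sam <- do.call(rbind, recs)
  write_sam(sam, setNames(nchar(ref), names(ref)), sam_path)
  invisible(tibble::tibble(tag = master$tag, status = status))
}

## cigar of a gapped tag-vs-reference alignment (tag = a, ref = b); trailing
## reference overhang (free end gaps) is clipped, not part of the alignment
alignment_cigar <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ## drop columns where the tag has trailing gaps (reference overhang)
  last <- max(which(av != "-"))
  av <- av[seq_len(last)]
  bv <- bv[seq_len(last)]
  op <- ifelse(av == "-", "D", ifelse(bv == "-", "I", "M"))
  r <- rle(op)
  list(cigar = paste0(r$lengths, r$values, collapse = ""),
       nm = sum(av != bv & op == "M") + sum(op != "M"),
       ref_width = sum(op %in% c("M", "D")))
}

reverse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  paste(rev(ops), collapse = "")
}

#' Write a minimal SAM file
#' @param records Data frame with columns qname, flag, rname, pos, mapq,
#'   cigar, seq, opt (tab-joined optional fields or "").
#' @param contig_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @keywords internal
write_sam <- function(records, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq,
                  ifelse(records$opt == "", "", paste0("\t", records$opt)))
  writeLines(c(hdr, body), path)
  invisible(path)
}
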
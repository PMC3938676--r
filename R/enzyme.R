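#' Restriction enzyme models
#'
#' A GBS read begins with a sample barcode immediately followed by the
#' remnant of the restriction enzyme cut site, so the enzyme model carries
#' two pieces of information: the cut-site remnant(s) expected right after
#' the barcode, and the internal recognition pattern(s) whose occurrence
#' inside a read marks a chimeric fragment (the read is trimmed there).
#' Remnants are plain A/C/G/T strings; internal patterns may use IUPAC
#' degenerate codes (e.g. `GCWGC` for ApeKI, where `W` = A or T).
#'
#' Shipped enzymes are data, not code: `gbs_enzymes()` lists the built-in
#' table and [read_enzyme_config()] extends it from a user file.
#'
#' @param name Enzyme name (case-insensitive match against the table).
#' @param table Optional enzyme table as returned by `gbs_enzymes()` or
#'   [read_enzyme_config()].
#' @return `gbs_enzyme()` returns a list with elements `name`, `remnants`
#'   (character), `internal_patterns` (character, IUPAC allowed).
#'   `gbs_enzymes()` returns the table as a tibble with list-columns.
#' @examples
#' gbs_enzyme("ApeKI")$remnants
#' @export
gbs_enzyme <- function(name, table = gbs_enzymes()) {
  hit <- which(tolower(table$name) == tolower(name))
  if (length(hit) != 1L) {
    stop("unknown enzyme '", name, "'; see gbs_enzymes() or supply a config")
  }
  list(
    name = table$name[hit],
    remnants = table$remnants[[hit]],
    internal_patterns = table$internal_patterns[[hit]]
  )
}

#' @rdname gbs_enzyme
#' @export
gbs_enzymes <- function() {
  tibble::tibble(
    name = c("ApeKI", "PstI-MspI", "EcoT22I"),
    remnants = list(c("CAGC", "CTGC"), "TGCAG", "TGCAT"),
    internal_patterns = list("GCWGC", c("CTGCAG", "CCGG"), "ATGCAT")
  )
}

#' Read an enzyme configuration file
#'
#' Tab-delimited with a header row and columns `Name`, `Remnants`,
#' `InternalPatterns`; the last two are comma-separated lists. Remnants must
#' be plain A/C/G/T; internal patterns may include IUPAC degenerate codes.
#'
#' @param path Path to the config file.
#' @return Enzyme table (same shape as [gbs_enzymes()]).
#' @export
read_enzyme_config <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Name", "Remnants", "InternalPatterns")
  if (!all(need %in% names(df))) {
    stop("enzyme config must have columns: ", paste(need, collapse = ", "))
  }
  split_list <- function(x) {
    lapply(strsplit(x, ","), function(v) toupper(trimws(v)))
  }
  tab <- tibble::tibble(
    name = df$Name,
    remnants = split_list(df$Remnants),
    internal_patterns = split_list(df$InternalPatterns)
  )
  for (i in seq_len(nrow(tab))) {
    if (any(!nzchar(tab$remnants[[i]])) ||
        any(grepl("[^ACGT]", tab$remnants[[i]]))) {
      stop("remnants must be non-empty A/C/G/T strings (enzyme ",
           tab$name[i], ")")
    }
    if (any(grepl("[^ACGTRYSWKMBDHVN]", tab$internal_patterns[[i]]))) {
      stop("internal patterns must be valid IUPAC strings (enzyme ",
           tab$name[i], ")")
    }
  }
  tab
}

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Translate an IUPAC pattern into a regular expression
#' @param pattern IUPAC nucleotide pattern.
#' @return Regular expression string.
#' @keywords internal
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ""))
  paste0(IUPAC_MAP[chars], collapse = "")
}

enzyme_internal_regex <- function(enzyme) {
  paste(vapply(enzyme$internal_patterns, iupac_regex, character(1)),
        collapse = "|")
}
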
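#' @keywords internal
"_PACKAGE"

## Canonical amino-acid alphabet, PAML/IQ-TREE column order.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")

## Residues encoded predominantly by GC-rich vs AT-rich codons.
GARP_SET   <- c("G", "A", "R", "P")
FIMNKY_SET <- c("F", "I", "M", "N", "K", "Y")

## Symbols treated as missing data in all frequency computations.
MISSING_SET <- c("-", "?", "X")

#' Construct an alignment object
#'
#' An `aa_alignment` is the package's central container: a character matrix
#' with one row per taxon and one column per site, together with its declared
#' alphabet.  Characters outside `alphabet` and the missing set
#' (`-`, `?`, `X`) are rejected.
#'
#' @param matrix character matrix, rownames are taxon labels.
#' @param alphabet declared character set; defaults to the 20 amino acids.
#'   Recoded alignments carry their bin symbols here.
#' @return an object of class `aa_alignment` with elements `taxa`, `matrix`,
#'   `n_sites`, `alphabet`.
#' @export
aa_alignment <- function(matrix, alphabet = AA_ALPHABET) {
  if (!is.matrix(matrix) || !is.character(matrix))
    stop("`matrix` must be a character matrix", call. = FALSE)
  taxa <- rownames(matrix)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("all rows must carry a taxon label", call. = FALSE)
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  matrix[] <- toupper(matrix)
  bad <- which(!(matrix %in% c(alphabet, MISSING_SET)))
  if (length(bad)) {
    i <- bad[1L]
    rc <- arrayInd(i, dim(matrix))
    stop(sprintf("invalid character '%s' for taxon '%s' at site %d",
                 matrix[i], taxa[rc[1L]], rc[2L]), call. = FALSE)
  }
  structure(
    list(taxa = taxa, matrix = matrix, n_sites = ncol(matrix),
         alphabet = alphabet),
    class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d taxa x %d sites (alphabet of %d states)\n",
              length(x$taxa), x$n_sites, length(x$alphabet)))
  cat(sprintf("missing data: %.2f%%\n", 100 * missing_fraction(x)))
  invisible(x)
}

#' @export
dim.aa_alignment <- function(x) dim(x$matrix)

is_missing_char <- function(ch) ch %in% MISSING_SET

#' Fraction of missing cells in an alignment
#'
#' Counts cells whose character is in the missing set `-`, `?`, `X` and
#' divides by the total cell count.
#'
#' @param a an `aa_alignment`.
#' @param count_x should `X` count as missing? Both conventions appear in
#'   published missing-data figures; the default counts it.
#' @return proportion in \[0, 1\].
#' @export
missing_fraction <- function(a, count_x = TRUE) {
  stopifnot(inherits(a, "aa_alignment"))
  if (a$n_sites < 1L || length(a$taxa) < 1L)
    stop("empty alignment", call. = FALSE)
  miss <- if (count_x) MISSING_SET else setdiff(MISSING_SET, "X")
  sum(a$matrix %in% miss) / length(a$matrix)
}

#' Drop taxa from an alignment
#'
#' Rows are removed; columns are untouched (no re-masking), so the remaining
#' taxa's per-taxon compositions are unchanged.
#'
#' @param a an `aa_alignment`.
#' @param taxa character vector of taxon labels to remove.
#' @return an `aa_alignment` without the named taxa.
#' @export
taxon_remove <- function(a, taxa) {
  stopifnot(inherits(a, "aa_alignment"))
  unknown <- setdiff(taxa, a$taxa)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- setdiff(a$taxa, taxa)
  if (!length(keep)) stop("removal would leave no taxa", call. = FALSE)
  aa_alignment(a$matrix[keep, , drop = FALSE], alphabet = a$alphabet)
}

#' Extract columns of an alignment
#'
#' @param a an `aa_alignment`.
#' @param sites integer vector of 1-based site indices to keep, in the order
#'   given.
#' @return an `aa_alignment` restricted to `sites`.
#' @export
site_subset <- function(a, sites) {
  stopifnot(inherits(a, "aa_alignment"))
  if (any(sites < 1L) || any(sites > a$n_sites))
    stop("site index out of range", call. = FALSE)
  aa_alignment(a$matrix[, sites, drop = FALSE], alphabet = a$alphabet)
}
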
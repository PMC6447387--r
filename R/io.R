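#' Read a protein alignment
#'
#' Reads FASTA (via \pkg{seqinr}) or relaxed PHYLIP (header `ntaxa nsites`,
#' whitespace-delimited names of arbitrary length, sequential records).
#' Characters are upper-cased; the declared alphabet is the 20 amino acids.
#' `-`, `?` and `X` pass through as missing data; any other character
#' (including `*`) is a format error naming the offender and its position.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip-relaxed"`; `"auto"` sniffs the first
#'   non-blank character (`>` means FASTA).
#' @return an [aa_alignment].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(trimws(first), ">"))
      "fasta" else "phylip-relaxed"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                               forceDNAtolower = FALSE, set.attributes = FALSE)
    if (!length(recs)) stop("no sequences in ", path, call. = FALSE)
    names(recs) <- sub("\\s.*$", "", names(recs))
    lens <- lengths(recs)
    if (length(unique(lens)) != 1L)
      stop(sprintf("ragged alignment in %s: sequence lengths %s", path,
                   paste(unique(lens), collapse = ", ")), call. = FALSE)
    if (anyDuplicated(names(recs)))
      stop("duplicate taxon labels in ", path, ": ",
           paste(unique(names(recs)[duplicated(names(recs))]), collapse = ", "),
           call. = FALSE)
    m <- do.call(rbind, recs)
    rownames(m) <- names(recs)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("not a PHYLIP file: ", path, call. = FALSE)
    hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
    if (length(hdr) != 2L || anyNA(hdr))
      stop("malformed PHYLIP header in ", path, call. = FALSE)
    n_taxa <- hdr[1L]; n_sites <- hdr[2L]
    if (length(lines) - 1L != n_taxa)
      stop(sprintf("PHYLIP header promises %d taxa, found %d records",
                   n_taxa, length(lines) - 1L), call. = FALSE)
    parts <- strsplit(trimws(lines[-1L]), "\\s+")
    labels <- vapply(parts, `[`, "", 1L)
    seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), "")
    if (anyDuplicated(labels))
      stop("duplicate taxon labels in ", path, ": ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "),
           call. = FALSE)
    lens <- nchar(seqs)
    if (any(lens != n_sites))
      stop(sprintf("ragged alignment in %s: expected %d sites, found %s",
                   path, n_sites, paste(unique(lens), collapse = ", ")),
           call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- labels
  }
  aa_alignment(m)
}

#' Write a protein alignment
#'
#' @param a an [aa_alignment].
#' @param path output file path.
#' @param format `"fasta"` (wrapped at 80 columns) or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, format = c("fasta", "phylip-relaxed")) {
  stopifnot(inherits(a, "aa_alignment"))
  format <- match.arg(format)
  seqs <- apply(a$matrix, 1L, paste, collapse = "")
  if (format == "fasta") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", a$taxa[i]), con)
      n <- nchar(seqs[i])
      starts <- seq(1L, n, by = 80L)
      writeLines(substring(seqs[i], starts, pmin(starts + 79L, n)), con)
    }
  } else {
    writeLines(c(sprintf("%d %d", length(a$taxa), a$n_sites),
                 sprintf("%s  %s", a$taxa, seqs)), path)
  }
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa absent from a gene receive an all-`?` block over that gene's columns.
#' The returned partition map records each gene's 1-based inclusive column
#' range in input order.
#'
#' @param genes named list of [aa_alignment] objects (names are gene names).
#' @param taxa optional master taxon list (superset of all gene taxa); by
#'   default the union of gene taxa in order of first appearance.
#' @return list with elements `alignment` (the supermatrix) and `partition`
#'   (data frame `gene`, `start`, `end`).
#' @export
concatenate <- function(genes, taxa = NULL) {
  if (!length(genes)) stop("no gene alignments supplied", call. = FALSE)
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("`genes` must be a named list", call. = FALSE)
  for (g in genes) stopifnot(inherits(g, "aa_alignment"))
  all_taxa <- unique(unlist(lapply(genes, `[[`, "taxa")))
  if (is.null(taxa)) {
    taxa <- all_taxa
  } else if (length(setdiff(all_taxa, taxa))) {
    stop("master taxon list is missing: ",
         paste(setdiff(all_taxa, taxa), collapse = ", "), call. = FALSE)
  }
  widths <- vapply(genes, `[[`, 0L, "n_sites")
  blocks <- lapply(genes, function(g) {
    m <- matrix("?", length(taxa), g$n_sites, dimnames = list(taxa, NULL))
    m[g$taxa, ] <- g$matrix
    m
  })
  ends <- cumsum(widths)
  part <- data.frame(gene = names(genes),
                     start = ends - widths + 1L, end = ends,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(alignment = aa_alignment(do.call(cbind, blocks),
                                alphabet = genes[[1L]]$alphabet),
       partition = part)
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `WAG, gene1 = 1-3`; the model token before the comma is
#' ignored.  Ranges must be contiguous, non-overlapping and start at 1.
#'
#' @param path file path.
#' @return data frame `gene`, `start`, `end`.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^\\s*\\S+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("unparseable partition line: ", lines[which(bad)[1L]], call. = FALSE)
  out <- data.frame(gene = vapply(m, `[`, "", 2L),
                    start = as.integer(vapply(m, `[`, "", 3L)),
                    end = as.integer(vapply(m, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (out$start[1L] != 1L || any(out$end < out$start) ||
      (nrow(out) > 1L && any(out$start[-1L] != out$end[-nrow(out)] + 1L)))
    stop("partition ranges must be contiguous from 1", call. = FALSE)
  out
}

#' Read a per-site rate file
#'
#' Plain text, one non-negative real per line; lines starting with `#` are
#' headers.  Such files are produced by ML tree software when asked for
#' conditional mean site rates (e.g. IQ-TREE's `-wsr` output reformatted to
#' one rate per line).
#'
#' @param path file path.
#' @param n_sites optional expected length; mismatch is an error.
#' @return numeric vector of rates.
#' @export
read_site_rates <- function(path, n_sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rates <- suppressWarnings(as.numeric(lines))
  if (anyNA(rates)) stop("non-numeric rate line in ", path, call. = FALSE)
  if (any(rates < 0)) stop("negative rate in ", path, call. = FALSE)
  if (!is.null(n_sites) && length(rates) != n_sites)
    stop(sprintf("rate file has %d entries but alignment has %d sites",
                 length(rates), n_sites), call. = FALSE)
  rates
}
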
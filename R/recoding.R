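#' Construct a reduced-alphabet recoding scheme
#'
#' A scheme is an ordered list of disjoint, non-empty amino-acid bins whose
#' union covers the 20-letter alphabet, plus one output symbol per bin.
#' Default symbols are `A C G T` for four bins (so recoded matrices can be
#' fed to DNA-capable inference software) and digits `0..k-1` otherwise.
#'
#' @param bins list of character vectors of residues, or a single string of
#'   space-separated residue groups such as `"ARNDQEILKSTV GHY CMFP W"`.
#' @param symbols optional output symbols, one per bin.
#' @return object of class `recoding_scheme`: `bins`, `symbols`, `n_bins`.
#' @export
recoding_scheme <- function(bins, symbols = NULL) {
  if (is.character(bins) && length(bins) == 1L)
    bins <- strsplit(strsplit(trimws(bins), "\\s+")[[1L]], "")
  bins <- lapply(bins, function(b) toupper(unlist(strsplit(b, ""))))
  if (any(lengths(bins) == 0L)) stop("empty bin", call. = FALSE)
  all_res <- unlist(bins)
  if (anyDuplicated(all_res))
    stop("residue in more than one bin: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "),
         call. = FALSE)
  if (!setequal(all_res, AA_ALPHABET))
    stop("bins must cover the 20 amino acids exactly; missing: ",
         paste(setdiff(AA_ALPHABET, all_res), collapse = ", "),
         if (length(setdiff(all_res, AA_ALPHABET)))
           paste0("; unknown: ",
                  paste(setdiff(all_res, AA_ALPHABET), collapse = ", ")),
         call. = FALSE)
  k <- length(bins)
  if (is.null(symbols)) symbols <- default_bin_symbols(k)
  if (length(symbols) != k || anyDuplicated(symbols))
    stop("need ", k, " unique output symbols", call. = FALSE)
  ## residues within each bin in canonical alphabet order (as schemes are
  ## conventionally printed)
  bins <- lapply(bins, function(b) b[order(match(b, AA_ALPHABET))])
  structure(list(bins = bins, symbols = as.character(symbols), n_bins = k),
            class = "recoding_scheme")
}

default_bin_symbols <- function(k) {
  if (k == 4L) c("A", "C", "G", "T")
  else if (k <= 10L) as.character(seq_len(k) - 1L)
  else AA_ALPHABET[seq_len(k)]
}

#' @export
print.recoding_scheme <- function(x, ...) {
  cat(sprintf("recoding_scheme (%d bins): %s\n", x$n_bins, format(x)))
  invisible(x)
}

#' @export
format.recoding_scheme <- function(x, ...)
  paste(vapply(x$bins, paste, "", collapse = ""), collapse = " ")

#' Read / write scheme files
#'
#' One line, bins space-separated, residues concatenated, e.g.
#' `ARNDQEILKSTV GHY CMFP W`.
#'
#' @param path file path.
#' @return [recoding_scheme] (reader); `path` invisibly (writer).
#' @export
read_scheme <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 1L)
    stop("scheme file must contain exactly one scheme line", call. = FALSE)
  recoding_scheme(lines)
}

#' @rdname read_scheme
#' @param scheme a [recoding_scheme].
#' @export
write_scheme <- function(scheme, path) {
  writeLines(format(scheme), path)
  invisible(path)
}

#' Recode an alignment to a reduced alphabet
#'
#' Each residue is replaced by its bin's output symbol; missing symbols
#' (`-`, `?`, `X`) pass through unchanged.  The result's declared alphabet
#' is the scheme's symbol set.
#'
#' @param a an [aa_alignment] over the 20 amino acids.
#' @param scheme a [recoding_scheme].
#' @return recoded [aa_alignment].
#' @export
apply_scheme <- function(a, scheme) {
  stopifnot(inherits(a, "aa_alignment"), inherits(scheme, "recoding_scheme"))
  map <- stats::setNames(rep(scheme$symbols, lengths(scheme$bins)),
                         unlist(scheme$bins))
  m <- a$matrix
  is_miss <- m %in% MISSING_SET
  out <- map[m]
  bad <- which(is.na(out) & !is_miss)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("residue '%s' (taxon '%s', site %d) not in any bin",
                 m[bad[1L]], a$taxa[rc[1L]], rc[2L]), call. = FALSE)
  }
  out[is_miss] <- m[is_miss]
  res <- matrix(out, nrow(m), ncol(m), dimnames = dimnames(m))
  aa_alignment(res, alphabet = scheme$symbols)
}

## max_t for a bin assignment, from a precomputed taxa x residues count
## matrix.  `assign` maps residue column -> bin index.
max_t_for_assignment <- function(counts, assign, n_bins) {
  binned <- matrix(0, nrow(counts), n_bins)
  for (b in seq_len(n_bins)) {
    cols <- which(assign == b)
    if (length(cols))
      binned[, b] <- rowSums(counts[, cols, drop = FALSE])
  }
  tot <- rowSums(binned)
  pooled <- colSums(binned) / sum(binned)
  keep <- pooled > 0
  dev <- sweep(binned[, keep, drop = FALSE] / tot, 2L, pooled[keep])
  max(as.vector((dev^2) %*% (1 / pooled[keep])))
}

#' Search for a dataset-specific minmax chi-square recoding scheme
#'
#' Hill-climbing over bin assignments: starting from random partitions of
#' the residues into `n_bins` bins, every single-residue move to another
#' bin is evaluated (moves that would empty a bin are rejected), the move
#' with the largest decrease in the maximum per-taxon chi-square statistic
#' `max_t` (see [chisquare_report()]) is taken (ties broken by smallest
#' residue letter, then smallest destination bin), and the climb stops at a
#' local minimum.  The best scheme over `n_restarts` restarts is returned.
#' Residues absent from the alignment carry zero counts, cannot change
#' `max_t`, and are excluded from the move set; they are appended to the
#' first bin of the returned scheme so that it covers the full alphabet.
#'
#' @param a an [aa_alignment] over the 20 amino acids.
#' @param n_bins number of bins, 2..19.
#' @param n_restarts random restarts.
#' @param seed integer seed; the search is deterministic given it.
#' @return list of class `scheme_search`: `scheme` ([recoding_scheme]),
#'   `max_t`, `trace` (best value per restart), `seed`, `n_restarts`.
#' @export
search_scheme <- function(a, n_bins, n_restarts = 20L, seed = 1L) {
  stopifnot(inherits(a, "aa_alignment"))
  if (n_bins < 2L || n_bins > 19L)
    stop("n_bins must be in 2..19", call. = FALSE)
  counts <- taxon_state_counts(a)
  present <- colnames(counts)[colSums(counts) > 0]
  if (length(present) < n_bins)
    stop(sprintf("only %d distinct residues present but %d bins requested",
                 length(present), n_bins), call. = FALSE)
  cts <- counts[, present, drop = FALSE]
  ## deterministic move order: residues alphabetically, bins ascending
  res_order <- order(present)
  set.seed(seed)
  best_assign <- NULL
  best_val <- Inf
  trace <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    repeat {
      assign <- sample.int(n_bins, length(present), replace = TRUE)
      if (length(unique(assign)) == n_bins) break
    }
    val <- max_t_for_assignment(cts, assign, n_bins)
    repeat {
      move_best <- NULL
      move_val <- val
      for (ri in res_order) {
        from <- assign[ri]
        if (sum(assign == from) == 1L) next   # would empty the bin
        for (to in seq_len(n_bins)) {
          if (to == from) next
          cand <- assign
          cand[ri] <- to
          v <- max_t_for_assignment(cts, cand, n_bins)
          if (v < move_val - 1e-15) {         # strict improvement only
            move_val <- v
            move_best <- cand
          }
        }
      }
      if (is.null(move_best)) break
      assign <- move_best
      val <- move_val
    }
    trace[r] <- val
    if (val < best_val - 1e-15) {
      best_val <- val
      best_assign <- assign
    }
  }
  bins <- lapply(seq_len(n_bins), function(b) present[best_assign == b])
  absent <- setdiff(AA_ALPHABET, present)
  if (length(absent)) bins[[1L]] <- c(bins[[1L]], absent)
  ## canonical bin order: by alphabet rank of each bin's first residue
  bins <- lapply(bins, function(b) b[order(match(b, AA_ALPHABET))])
  bins <- bins[order(vapply(bins, function(b) match(b[1L], AA_ALPHABET), 0L))]
  scheme <- recoding_scheme(bins)
  structure(list(scheme = scheme, max_t = best_val, trace = trace,
                 seed = seed, n_restarts = n_restarts),
            class = "scheme_search")
}

#' @export
print.scheme_search <- function(x, ...) {
  cat(sprintf("scheme_search: max_t = %.6g over %d restarts (seed %d)\n  %s\n",
              x$max_t, x$n_restarts, x$seed, format(x$scheme)))
  invisible(x)
}

#' Enumerate all 2-bin schemes over a small residue set
#'
#' Exhaustive minmax chi-square over every two-bin set partition of the
#' residues present in the alignment; used as an oracle against
#' [search_scheme()] on reduced-alphabet data.
#'
#' @param a an [aa_alignment] with at most 15 distinct residues present.
#' @return list: `max_t` (optimum), `assign` (optimal bin assignment over
#'   present residues), `all_values` (one value per partition).
#' @export
enumerate_two_bin <- function(a) {
  counts <- taxon_state_counts(a)
  present <- colnames(counts)[colSums(counts) > 0]
  p <- length(present)
  if (p < 2L || p > 15L)
    stop("exhaustive enumeration supports 2..15 present residues",
         call. = FALSE)
  cts <- counts[, present, drop = FALSE]
  ## fix residue 1 in bin 1 to enumerate set partitions once each
  n_part <- 2L^(p - 1L) - 1L
  vals <- numeric(n_part)
  best <- Inf; best_assign <- NULL
  for (code in seq_len(n_part)) {
    assign <- c(1L, 1L + as.integer(intToBits(code)[seq_len(p - 1L)] == 1))
    vals[code] <- max_t_for_assignment(cts, assign, 2L)
    if (vals[code] < best) { best <- vals[code]; best_assign <- assign }
  }
  list(max_t = best, assign = stats::setNames(best_assign, present),
       all_values = vals)
}

#' Collapse a profile mixture to a recoded alphabet
#'
#' Each class profile's bin value is the sum of its member amino-acid
#' frequencies (the construction that turns a 20-state empirical mixture
#' into its four- or six-state counterpart); class weights are unchanged.
#'
#' @param m a [profile_mixture] over 20 states.
#' @param scheme a [recoding_scheme].
#' @return a [profile_mixture] over the scheme's bins.
#' @export
collapse_profiles <- function(m, scheme) {
  stopifnot(inherits(m, "profile_mixture"), inherits(scheme, "recoding_scheme"))
  if (!setequal(colnames(m$profiles), AA_ALPHABET))
    stop("mixture must be over the 20 amino acids", call. = FALSE)
  collapsed <- vapply(scheme$bins, function(b)
    rowSums(m$profiles[, b, drop = FALSE]), numeric(m$K))
  if (m$K == 1L) collapsed <- matrix(collapsed, nrow = 1L)
  colnames(collapsed) <- scheme$symbols
  rownames(collapsed) <- rownames(m$profiles)
  profile_mixture(weights = m$weights, profiles = collapsed,
                  loglik = m$loglik, seed = m$seed)
}
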
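## Per-taxon counts over the alignment's alphabet (missing cells excluded).
taxon_state_counts <- function(a) {
  stopifnot(inherits(a, "aa_alignment"))
  k <- length(a$alphabet)
  idx <- matrix(match(a$matrix, a$alphabet), nrow = length(a$taxa))
  # NA marks missing symbols; tabulate() skips them
  counts <- matrix(0, length(a$taxa), k,
                   dimnames = list(a$taxa, a$alphabet))
  for (s in seq_along(a$taxa))
    counts[s, ] <- tabulate(idx[s, ], nbins = k)
  counts
}

#' Per-taxon amino-acid compositions and GARP:FIMNKY ratios
#'
#' Frequencies are computed over non-missing cells only.  The GARP:FIMNKY
#' ratio (pi_G + pi_A + pi_R + pi_P) / (pi_F + pi_I + pi_M + pi_N + pi_K +
#' pi_Y) proxies genomic GC content at the proteome level: AT-rich genomes
#' are enriched in F, I, M, N, K, Y.  A zero FIMNKY sum yields `Inf` with a
#' warning.
#'
#' @param a an [aa_alignment] over the 20 amino acids.
#' @return data frame, one row per taxon, sorted ascending by ratio:
#'   `taxon`, `garp_fimnky`, and one frequency column per amino acid.
#' @export
taxon_compositions <- function(a) {
  counts <- taxon_state_counts(a)
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("taxa with no non-missing cells: ",
         paste(rownames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  freqs <- counts / tot
  garp <- rowSums(freqs[, GARP_SET, drop = FALSE])
  fimnky <- rowSums(freqs[, FIMNKY_SET, drop = FALSE])
  ratio <- ifelse(fimnky == 0, Inf, garp / fimnky)
  if (any(!is.finite(ratio)))
    warning("FIMNKY frequency sum is zero for: ",
            paste(rownames(counts)[!is.finite(ratio)], collapse = ", "),
            "; ratio set to Inf", call. = FALSE)
  out <- data.frame(taxon = rownames(counts), garp_fimnky = ratio,
                    freqs, row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[order(out$garp_fimnky, out$taxon), , drop = FALSE]
}

#' Split taxa into AT-rich and GC-rich groups by ratio cutoff
#'
#' Taxa whose GARP:FIMNKY ratio is strictly below `cutoff` are classed
#' AT-rich; the rest GC-rich.  The default 1.06 targets a gap in the ratio
#' distribution separating compositionally biased intracellular lineages
#' from the rest; a cutoff should always sit in such a gap, so the strict
#' inequality never bites in practice and keeps behaviour deterministic.
#'
#' @param comps output of [taxon_compositions()].
#' @param cutoff positive ratio threshold.
#' @return object of class `taxon_partition`: list with `cutoff`, `at_rich`,
#'   `gc_rich`, `flagged` (TRUE when one side is empty).
#' @export
partition_taxa <- function(comps, cutoff = 1.06) {
  stopifnot(is.data.frame(comps), cutoff > 0)
  at <- comps$taxon[comps$garp_fimnky < cutoff]
  gc <- comps$taxon[comps$garp_fimnky >= cutoff]
  flagged <- length(at) == 0L || length(gc) == 0L
  if (flagged)
    warning("one-sided partition at cutoff ", cutoff,
            ": per-site bias scores will be undefined", call. = FALSE)
  structure(list(cutoff = cutoff, at_rich = at, gc_rich = gc,
                 flagged = flagged),
            class = "taxon_partition")
}

#' @export
print.taxon_partition <- function(x, ...) {
  cat(sprintf("taxon_partition (cutoff %g): %d AT-rich, %d GC-rich%s\n",
              x$cutoff, length(x$at_rich), length(x$gc_rich),
              if (x$flagged) " [flagged: one-sided]" else ""))
  invisible(x)
}

#' Per-taxon chi-square deviations from pooled frequencies
#'
#' For each taxon s, t_s = sum_i (pi_is - pi_i)^2 / pi_i, where pi_i is the
#' pooled frequency of state (or recoding bin) i over all non-missing cells
#' of all taxa, count-weighted as in the classical homogeneity X-squared.
#' Bins with pooled frequency zero are dropped from the sum (the limit of
#' the statistic as the expected frequency goes to zero with zero observed).
#' `max_t` over taxa is the criterion minimized by [search_scheme()].
#'
#' @param a an [aa_alignment].
#' @param scheme optional [recoding_scheme]; frequencies are then over bins.
#' @return list of class `chisq_report`: `bin_labels`, `pooled_freqs`,
#'   `taxon_freqs` (taxa x bins matrix), `t_s` (named vector), `max_t`.
#' @export
chisquare_report <- function(a, scheme = NULL) {
  counts <- taxon_state_counts(a)
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "recoding_scheme"))
    missing_res <- setdiff(colnames(counts)[colSums(counts) > 0],
                           unlist(scheme$bins))
    if (length(missing_res))
      stop("scheme does not cover residues: ",
           paste(missing_res, collapse = ", "), call. = FALSE)
    binned <- vapply(scheme$bins, function(b)
      rowSums(counts[, intersect(b, colnames(counts)), drop = FALSE]),
      numeric(nrow(counts)))
    if (is.null(dim(binned))) binned <- matrix(binned, nrow = 1L,
                                               dimnames = list(rownames(counts)))
    colnames(binned) <- scheme$symbols
    counts <- binned
  }
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("taxa with no non-missing cells: ",
         paste(rownames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  pooled <- colSums(counts) / sum(counts)
  taxon_freqs <- counts / tot
  keep <- pooled > 0
  dev <- sweep(taxon_freqs[, keep, drop = FALSE], 2L, pooled[keep])
  t_s <- as.vector((dev^2) %*% (1 / pooled[keep]))
  names(t_s) <- rownames(counts)
  structure(list(bin_labels = colnames(counts), pooled_freqs = pooled,
                 taxon_freqs = taxon_freqs, t_s = t_s, max_t = max(t_s)),
            class = "chisq_report")
}

#' @export
print.chisq_report <- function(x, ...) {
  cat(sprintf("chisq_report over %d bins, %d taxa: max_t = %.6g (taxon %s)\n",
              length(x$bin_labels), length(x$t_s), x$max_t,
              names(x$t_s)[which.max(x$t_s)]))
  invisible(x)
}

#' UPGMA clustering of taxon amino-acid compositions
#'
#' Average-linkage agglomeration on the Euclidean distance matrix between
#' 20-dimensional frequency vectors, the standard diagnostic for spotting
#' unrelated lineages with convergently similar compositions.  Ties in the
#' minimum pairwise distance are broken lexicographically by the smallest
#' member label, so the result is deterministic.
#'
#' @param comps output of [taxon_compositions()] (>= 2 taxa).
#' @return ultrametric `phylo` tree (branch lengths encode merge heights).
#' @export
upgma_compositions <- function(comps) {
  stopifnot(is.data.frame(comps))
  if (nrow(comps) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (anyDuplicated(comps$taxon))
    stop("duplicate taxon labels", call. = FALSE)
  f <- as.matrix(comps[, AA_ALPHABET, drop = FALSE])
  rownames(f) <- comps$taxon
  upgma_from_dist(as.matrix(stats::dist(f)))
}

## Deterministic average-linkage UPGMA from a symmetric distance matrix.
## Implemented directly (rather than via hclust) to pin the tie-break:
## among equal minimum distances, merge the pair whose smallest member
## label sorts first.  Returns an ultrametric ape::phylo.
upgma_from_dist <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n >= 2L, identical(rownames(d), colnames(d)))
  active <- seq_len(n)
  sizes <- rep(1L, n)
  height <- rep(0, n)
  minlab <- labels                      # smallest member label per cluster
  newick <- labels
  D <- d
  repeat {
    k <- length(active)
    if (k == 1L) break
    sub <- D[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best_d <- min(sub)
    cand <- which(sub <= best_d + 1e-15, arr.ind = TRUE)
    keys <- apply(cand, 1L, function(rc) {
      lab <- sort(c(minlab[active[rc[1L]]], minlab[active[rc[2L]]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    a <- active[pick[1L]]; b <- active[pick[2L]]
    h <- D[a, b] / 2
    new <- length(sizes) + 1L
    ## average-linkage update against every other active cluster
    others <- setdiff(active, c(a, b))
    Dnew <- rbind(cbind(D, 0), 0)
    for (o in others)
      Dnew[new, o] <- Dnew[o, new] <-
        (sizes[a] * D[a, o] + sizes[b] * D[b, o]) / (sizes[a] + sizes[b])
    D <- Dnew
    sizes <- c(sizes, sizes[a] + sizes[b])
    height <- c(height, h)
    minlab <- c(minlab, min(minlab[a], minlab[b]))
    newick <- c(newick, sprintf("(%s:%.10g,%s:%.10g)",
                                newick[a], h - height[a],
                                newick[b], h - height[b]))
    active <- c(others, new)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}
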
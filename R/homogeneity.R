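#' Construct a 20-state substitution model
#'
#' A reversible amino-acid model assembled from symmetric exchangeabilities
#' and equilibrium frequencies, with discrete-gamma rate variation (equal
#' probability categories, category means).  The rate matrix is normalized
#' to one expected substitution per unit branch length.  The default flat
#' model (all exchangeabilities equal, flat frequencies) is the 20-state
#' analogue of Jukes-Cantor and ships as the testing fallback; empirical
#' matrices can be supplied through `exchangeabilities` / `freqs`.
#'
#' @param exchangeabilities symmetric 20 x 20 non-negative matrix (diagonal
#'   ignored); default all ones.
#' @param freqs equilibrium frequencies (length 20, positive); default flat.
#' @param gamma_shape gamma shape for among-site rate variation; `Inf`
#'   disables it.
#' @param n_rate_categories number of discrete categories (default 4).
#' @return object of class `substitution_model` with the assembled rate
#'   matrix `Q`, its eigendecomposition, and category rates.
#' @export
substitution_model <- function(exchangeabilities = NULL, freqs = NULL,
                               gamma_shape = Inf, n_rate_categories = 4L) {
  k <- 20L
  if (is.null(exchangeabilities))
    exchangeabilities <- matrix(1, k, k)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  stopifnot(nrow(exchangeabilities) == k, ncol(exchangeabilities) == k,
            length(freqs) == k, all(freqs > 0))
  if (max(abs(exchangeabilities - t(exchangeabilities))) > 1e-9)
    stop("exchangeabilities must be symmetric", call. = FALSE)
  freqs <- freqs / sum(freqs)
  Q <- exchangeabilities * rep(freqs, each = k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale                         # mean rate 1
  ## reversible: symmetrize with sqrt(pi) for a stable eigendecomposition
  s <- sqrt(freqs)
  B <- (s %o% (1 / s)) * Q
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  rates <- if (is.finite(gamma_shape))
    phangorn::discrete.gamma(gamma_shape, n_rate_categories)
  else rep(1, n_rate_categories)
  structure(list(Q = Q, freqs = freqs, gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories),
                 category_rates = rates,
                 eig_values = eig$values,
                 eig_left = (1 / s) * eig$vectors,      # D^{-1/2} V
                 eig_right = t(s * eig$vectors)),       # V' D^{1/2}
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf(paste0("substitution_model: 20 states, gamma shape %s, ",
                     "%d rate categories\n"),
              format(x$gamma_shape), x$n_rate_categories))
  invisible(x)
}

## Transition kernel P(t) = D^{-1/2} V exp(L t) V' D^{1/2}.
transition_matrix <- function(model, t) {
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Precompute, for one tree and model, everything needed to draw replicate
## alignments fast: edge traversal order and cumulative transition kernels
## per (edge, rate category).  Shared across parametric-bootstrap draws.
simulation_kernel <- function(tree, model) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  edges <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE] # preorder
  lens <- rev(tree$edge.length)
  ncat <- model$n_rate_categories
  k <- 20L
  ## cumP[(edge-1)*ncat + cat] -> 20 x 20 row-cumulative kernel
  cum <- vector("list", nrow(edges) * ncat)
  for (e in seq_len(nrow(edges)))
    for (cc in seq_len(ncat)) {
      P <- transition_matrix(model, lens[e] * model$category_rates[cc])
      cum[[(e - 1L) * ncat + cc]] <- t(apply(P, 1L, cumsum))
    }
  list(tree = tree, edges = edges, ncat = ncat,
       n_nodes = max(tree$edge), root = edges[1L, 1L],
       tip_labels = tree$tip.label, cum = cum,
       cum_freqs = cumsum(model$freqs))
}

## One replicate from a precomputed kernel: taxa x sites integer matrix of
## state indices.  Site rate categories are drawn equiprobably and shared
## across the whole tree for that site.
draw_from_kernel <- function(kern, n_sites) {
  cats <- sample.int(kern$ncat, n_sites, replace = TRUE)
  states <- matrix(0L, kern$n_nodes, n_sites)
  states[kern$root, ] <- findInterval(stats::runif(n_sites),
                                      kern$cum_freqs) + 1L
  for (e in seq_len(nrow(kern$edges))) {
    parent <- kern$edges[e, 1L]; child <- kern$edges[e, 2L]
    ps <- states[parent, ]
    u <- stats::runif(n_sites)
    child_states <- integer(n_sites)
    base <- (e - 1L) * kern$ncat
    for (cc in seq_len(kern$ncat)) {
      sel <- which(cats == cc)
      if (!length(sel)) next
      cumP <- kern$cum[[base + cc]]
      ## rowSums of (cum < u) counts how many category boundaries lie
      ## below u -> sampled state index
      rows <- cumP[ps[sel], , drop = FALSE]
      child_states[sel] <- rowSums(rows < u[sel]) + 1L
    }
    states[child, ] <- child_states
  }
  m <- states[seq_along(kern$tip_labels), , drop = FALSE]
  rownames(m) <- kern$tip_labels
  m
}

#' Simulate an alignment on a tree
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved along each branch by the transition kernel of the assembled
#' rate matrix at branch length times the site's gamma-category rate
#' multiplier (one category per site, shared across the tree).
#'
#' @param tree an `ape::phylo` with branch lengths, or a newick string /
#'   file path.
#' @param model a [substitution_model].
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return an [aa_alignment] over the 20 amino acids, gap-free.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  tree <- as_phylo(tree)
  stopifnot(inherits(model, "substitution_model"), n_sites >= 1L)
  set.seed(seed)
  kern <- simulation_kernel(tree, model)
  idx <- draw_from_kernel(kern, n_sites)
  m <- matrix(AA_ALPHABET[idx], nrow(idx), ncol(idx),
              dimnames = dimnames(idx))
  aa_alignment(m)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    tr <- tryCatch(suppressWarnings(
      if (file.exists(tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree)),
      error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stop("malformed newick tree", call. = FALSE)
    return(tr)
  }
  stop("tree must be a phylo object, newick string, or file", call. = FALSE)
}

## Count-based homogeneity X^2: sum over taxa and states of
## (c_si - E_si)^2 / E_si with expectations from pooled frequencies scaled
## to each taxon's non-missing total.  Cells with zero expectation drop out.
composition_x2 <- function(counts) {
  tot <- rowSums(counts)
  pooled <- colSums(counts) / sum(counts)
  E <- tot %o% pooled
  keep <- E > 0
  sum((counts[keep] - E[keep])^2 / E[keep])
}

#' Parametric-bootstrap test of compositional homogeneity
#'
#' Compares the observed across-taxa X^2 statistic (pooled-expectation
#' count form) with its null distribution obtained by simulating `N`
#' replicate alignments of matching size on `tree` under `model` — the
#' simulation-based construction that, unlike the naive X^2 test, accounts
#' for phylogenetic correlation among sequences.  Replicates inherit the
#' observed alignment's missing-data mask so that per-taxon totals match.
#' The p-value uses the add-one rule `(1 + #\{null >= obs\}) / (N + 1)` and
#' is therefore never zero.
#'
#' @param a an [aa_alignment] (one gene).
#' @param tree tree with branch lengths covering exactly the alignment taxa.
#' @param model a [substitution_model].
#' @param N number of bootstrap replicates (>= 19).
#' @param seed integer seed.
#' @param gene gene name carried into the result.
#' @return object of class `homogeneity_result`: `gene`, `observed_stat`,
#'   `null_stats`, `p_value`, `N`, `seed`.
#' @export
test_gene <- function(a, tree, model, N = 99L, seed = 1L, gene = "gene") {
  stopifnot(inherits(a, "aa_alignment"), N >= 19L)
  tree <- as_phylo(tree)
  if (!setequal(tree$tip.label, a$taxa)) {
    only_tree <- setdiff(tree$tip.label, a$taxa)
    only_aln <- setdiff(a$taxa, tree$tip.label)
    stop("tree/alignment taxon mismatch",
         if (length(only_tree)) paste0("; only in tree: ",
                                       paste(only_tree, collapse = ", ")),
         if (length(only_aln)) paste0("; only in alignment: ",
                                      paste(only_aln, collapse = ", ")),
         call. = FALSE)
  }
  observed <- composition_x2(taxon_state_counts(a))
  set.seed(seed)
  kern <- simulation_kernel(tree, model)
  miss <- a$matrix %in% MISSING_SET
  null_stats <- vapply(seq_len(N), function(i) {
    idx <- draw_from_kernel(kern, a$n_sites)
    idx <- idx[a$taxa, , drop = FALSE]
    idx[miss] <- NA_integer_
    cts <- matrix(0, length(a$taxa), 20L)
    for (s in seq_along(a$taxa))
      cts[s, ] <- tabulate(idx[s, ], nbins = 20L)
    composition_x2(cts)
  }, 0)
  p <- (1 + sum(null_stats >= observed)) / (N + 1)
  structure(list(gene = gene, observed_stat = observed,
                 null_stats = null_stats, p_value = p, N = N, seed = seed),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("homogeneity_result '%s': X2 = %.4f, p = %.4f (N = %d)\n",
              x$gene, x$observed_stat, x$p_value, x$N))
  invisible(x)
}

#' Select the most compositionally homogeneous genes
#'
#' Ranks genes by descending bootstrap p-value (ties by smaller observed
#' statistic, then by name) and returns the top `n` — the route to a
#' reduced gene set that minimizes compositional heterogeneity.
#'
#' @param results list of [test_gene()] results.
#' @param n number of genes to keep.
#' @return character vector of gene names.
#' @export
select_homogeneous <- function(results, n) {
  stopifnot(n <= length(results))
  p <- vapply(results, `[[`, 0, "p_value")
  s <- vapply(results, `[[`, 0, "observed_stat")
  g <- vapply(results, `[[`, "", "gene")
  g[order(-p, s, g)][seq_len(n)]
}
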
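## Baseline amino-acid frequencies (LG empirical equilibrium), used as the
## backbone composition that regime profiles are bent away from.
LG_FREQS <- c(A = 0.079066, R = 0.055941, N = 0.041977, D = 0.053052,
              C = 0.012937, Q = 0.040767, E = 0.071586, G = 0.057337,
              H = 0.022355, I = 0.062157, L = 0.099081, K = 0.064600,
              M = 0.022951, F = 0.042302, P = 0.044040, S = 0.061197,
              T = 0.053287, W = 0.012066, V = 0.069147, Y = 0.034155)

garp_fimnky_ratio <- function(freqs)
  sum(freqs[GARP_SET]) / sum(freqs[FIMNKY_SET])

## Bend a composition to a target GARP:FIMNKY ratio by transferring mass
## between the GARP and FIMNKY sets, proportionally to each member's
## baseline frequency; other residues untouched.  A floor keeps every
## frequency at or above `floor`.
bend_composition <- function(base, target_ratio, floor = 0.001) {
  g <- sum(base[GARP_SET]); f <- sum(base[FIMNKY_SET])
  c_tot <- g + f
  g_new <- target_ratio * c_tot / (1 + target_ratio)
  f_new <- c_tot / (1 + target_ratio)
  out <- base
  out[GARP_SET] <- base[GARP_SET] * g_new / g
  out[FIMNKY_SET] <- base[FIMNKY_SET] * f_new / f
  if (any(out < floor))
    stop(sprintf("target ratio %.3f unreachable with frequency floor %g",
                 target_ratio, floor), call. = FALSE)
  out / sum(out)
}

## Solve for the disparity-site profile whose blend
## f * p_dis + (1 - f) * p_shared realizes `target_ratio` for a taxon.
solve_disparity_profile <- function(shared, f, target_ratio, floor = 0.001) {
  obj <- function(r) {
    p <- tryCatch(bend_composition(shared, r, floor), error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    blend <- f * p + (1 - f) * shared
    garp_fimnky_ratio(blend) - target_ratio
  }
  ## bracket over the ratios the frequency floor admits
  grid <- exp(seq(log(0.005), log(100), length.out = 400L))
  vals <- vapply(grid, obj, 0)
  ok <- which(is.finite(vals))
  pos <- which(diff(sign(vals[ok])) != 0)
  if (!length(pos))
    stop(sprintf(paste0("configured margin unreachable: no disparity-site ",
                        "profile realizes taxon ratio %.3f at disparity ",
                        "fraction %.2f"), target_ratio, f), call. = FALSE)
  i <- ok[pos[1L]]; j <- ok[pos[1L] + 1L]
  r <- stats::uniroot(obj, c(grid[i], grid[j]), tol = 1e-10)$root
  bend_composition(shared, r, floor)
}

#' Configuration for the two-regime synthetic generator
#'
#' Defaults describe the data structure the diagnostics are built for: a
#' supermatrix-scale alignment of ~100 taxa in which a minority of taxa,
#' scattered across at least two unrelated clades, has convergently shifted
#' toward AT-rich (FIMNKY-enriched) compositions at a fraction of sites.
#'
#' @param n_taxa_total total taxa.
#' @param n_taxa_biased taxa in the AT-rich (biased) regime.
#' @param n_sites alignment length.
#' @param fraction_disparity_sites fraction of sites carrying the
#'   compositional disparity.
#' @param margin target separation of realized GARP:FIMNKY ratios between
#'   regimes, centred on the 1.06 cutoff (biased below, background above).
#' @param missingness fraction of cells replaced by `?`.
#' @param gamma_shape shape of the gamma site-rate distribution.
#' @param seed integer seed.
#' @return list of class `regime_config`.
#' @export
regime_config <- function(n_taxa_total = 100L, n_taxa_biased = 25L,
                          n_sites = 5000L, fraction_disparity_sites = 0.3,
                          margin = 0.8, missingness = 0.1,
                          gamma_shape = 0.8, seed = 1L) {
  stopifnot(n_taxa_biased >= 1L, n_taxa_biased < n_taxa_total,
            n_sites >= 1L,
            fraction_disparity_sites >= 0, fraction_disparity_sites <= 1,
            margin >= 0, missingness >= 0, missingness < 1,
            gamma_shape > 0)
  structure(as.list(environment()), class = "regime_config")
}

#' Generate a two-regime alignment with recorded truth
#'
#' Emulates convergent compositional bias: a random birth-death-shaped tree
#' is drawn, the biased taxa are taken from two disjoint clades (so that
#' convergence, not common ancestry, explains their similarity), and
#' residues are drawn i.i.d. per cell — from a shared background profile at
#' ordinary sites, and from regime-specific profiles (FIMNKY-enriched for
#' biased taxa, GARP-enriched for the background) at disparity sites.
#' Profile targets are solved so that realized per-taxon ratios sit at
#' `1.06 - margin/2` (biased) and `1.06 + margin/2` (background).  Gamma
#' site rates are drawn and recorded; missing cells (`?`) are inserted
#' uniformly at the configured rate.
#'
#' @param cfg a [regime_config()].
#' @return list: `alignment` ([aa_alignment]), `truth` (list with
#'   `taxon_regime` data frame, `site_truth` data frame of per-site
#'   disparity flags and rates, and the regime profiles), `tree`
#'   (`ape::phylo`).
#' @export
make_regime_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "regime_config"))
  set.seed(cfg$seed)
  cutoff <- 1.06
  f <- cfg$fraction_disparity_sites
  shared <- bend_composition(LG_FREQS, cutoff)
  if (f > 0 && cfg$margin > 0) {
    p_bias <- solve_disparity_profile(shared, f, cutoff - cfg$margin / 2)
    p_back <- solve_disparity_profile(shared, f, cutoff + cfg$margin / 2)
  } else {
    p_bias <- p_back <- shared
  }

  tree <- ape::rphylo(cfg$n_taxa_total, birth = 1, death = 0.4)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("t%03d", seq_len(cfg$n_taxa_total))
  biased <- pick_biased_tips(tree, cfg$n_taxa_biased)
  taxa <- tree$tip.label
  regime <- ifelse(taxa %in% biased, "biased", "background")

  disparity <- stats::runif(cfg$n_sites) < f
  rates <- stats::rgamma(cfg$n_sites, shape = cfg$gamma_shape,
                         rate = cfg$gamma_shape)

  m <- matrix("", cfg$n_taxa_total, cfg$n_sites, dimnames = list(taxa, NULL))
  n_disp <- sum(disparity)
  n_ord <- cfg$n_sites - n_disp
  for (s in seq_along(taxa)) {
    row <- character(cfg$n_sites)
    if (n_ord)
      row[!disparity] <- sample(AA_ALPHABET, n_ord, TRUE, prob = shared)
    if (n_disp) {
      p <- if (regime[s] == "biased") p_bias else p_back
      row[disparity] <- sample(AA_ALPHABET, n_disp, TRUE, prob = p)
    }
    m[s, ] <- row
  }
  if (cfg$missingness > 0) {
    miss <- stats::runif(length(m)) < cfg$missingness
    m[miss] <- "?"
  }
  list(alignment = aa_alignment(m),
       truth = list(
         taxon_regime = data.frame(taxon = taxa, regime = regime,
                                   stringsAsFactors = FALSE),
         site_truth = data.frame(site = seq_len(cfg$n_sites),
                                 disparity = disparity, rate = rates),
         profiles = list(shared = shared, biased = p_bias,
                         background = p_back)),
       tree = tree)
}

## Choose biased tips from two disjoint clades of the tree (neither nested
## in the other), so the biased regime is not monophyletic.
pick_biased_tips <- function(tree, n_biased) {
  tips <- tree$tip.label
  if (n_biased == 1L) return(sample(tips, 1L))
  k1 <- ceiling(n_biased / 2); k2 <- n_biased - k1
  ntip <- length(tips)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  clades <- lapply(internal, function(nd)
    ape::extract.clade(tree, nd)$tip.label)
  sizes <- lengths(clades)
  ## candidate first clades, smallest adequate first (keeps them local)
  ord <- order(sizes)
  for (i in ord) {
    if (sizes[i] < k1 || sizes[i] >= ntip) next
    rest <- setdiff(seq_along(clades), i)
    for (j in rest[order(sizes[rest])]) {
      if (sizes[j] < k2) next
      if (length(intersect(clades[[i]], clades[[j]]))) next
      return(c(sample(clades[[i]], k1), sample(clades[[j]], k2)))
    }
  }
  stop("could not place biased taxa in two disjoint clades", call. = FALSE)
}

#' Generate alignment columns from known mixture profiles
#'
#' Each site is assigned a latent class and its residues are drawn i.i.d.
#' from that class's profile — the test bed for [fit_mixture()].
#'
#' @param K number of classes.
#' @param profiles optional K x 20 matrix (columns named by amino acid);
#'   by default K Dirichlet-ish random profiles with disjoint emphasis.
#' @param weights optional class weights (default uniform).
#' @param n_sites number of columns.
#' @param n_taxa rows per column.
#' @param seed integer seed.
#' @return list: `alignment`, `truth` (data frame `site`, `class`), and
#'   the `profiles` / `weights` used.
#' @export
make_mixture_columns <- function(K, profiles = NULL, weights = NULL,
                                 n_sites = 1000L, n_taxa = 20L, seed = 1L) {
  stopifnot(K >= 1L)
  set.seed(seed)
  if (is.null(profiles)) {
    profiles <- t(vapply(seq_len(K), function(k) {
      x <- stats::rgamma(20L, shape = 0.3)
      x / sum(x)
    }, numeric(20L)))
    colnames(profiles) <- AA_ALPHABET
  }
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 20L || nrow(profiles) != K)
    stop("profiles must be K x 20", call. = FALSE)
  if (is.null(colnames(profiles))) colnames(profiles) <- AA_ALPHABET
  profiles <- profiles[, AA_ALPHABET, drop = FALSE]
  if (is.null(weights)) weights <- rep(1 / K, K)
  weights <- weights / sum(weights)
  cls <- sample.int(K, n_sites, replace = TRUE, prob = weights)
  m <- matrix("", n_taxa, n_sites,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)), NULL))
  for (j in seq_len(n_sites))
    m[, j] <- sample(AA_ALPHABET, n_taxa, TRUE, prob = profiles[cls[j], ])
  list(alignment = aa_alignment(m),
       truth = data.frame(site = seq_len(n_sites), class = cls),
       profiles = profiles, weights = weights)
}
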
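#' Per-site compositional bias scores (zeta)
#'
#' For each site, zeta = (pi_FIMNKY^AT - pi_FIMNKY^GC) +
#' (pi_GARP^GC - pi_GARP^AT), where pi_FIMNKY and pi_GARP are the summed
#' frequencies of the AT-rich-codon and GC-rich-codon amino-acid sets over
#' the non-missing cells of each taxon group at that site.  zeta lies in
#' \[-2, 2\]; larger values mark sites where the AT-rich group is enriched
#' in FIMNKY residues and depleted in GARP residues relative to the rest —
#' the signature of convergent compositional bias.  A site where one group
#' is entirely missing gets zeta = 0 and is flagged.
#'
#' @param a an [aa_alignment] over the 20 amino acids.
#' @param part a [partition_taxa()] result with both groups non-empty.
#' @return data frame, one row per site: `site` (1-based),
#'   `fimnky_at`, `garp_at`, `fimnky_gc`, `garp_gc`, `zeta`, `flagged`.
#' @export
zeta_scores <- function(a, part) {
  stopifnot(inherits(a, "aa_alignment"), inherits(part, "taxon_partition"))
  if (!length(part$at_rich) || !length(part$gc_rich))
    stop("both partition groups must be non-empty; re-run partition_taxa ",
         "with a cutoff inside the observed ratio distribution", call. = FALSE)
  unknown <- setdiff(c(part$at_rich, part$gc_rich), a$taxa)
  if (length(unknown))
    stop("partition names taxa absent from alignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  group_site_freqs <- function(taxa) {
    m <- a$matrix[taxa, , drop = FALSE]
    n_obs <- colSums(!matrix(m %in% MISSING_SET, nrow(m)))
    fim <- colSums(matrix(m %in% FIMNKY_SET, nrow(m)))
    garp <- colSums(matrix(m %in% GARP_SET, nrow(m)))
    list(fim = ifelse(n_obs > 0, fim / n_obs, NA_real_),
         garp = ifelse(n_obs > 0, garp / n_obs, NA_real_),
         n_obs = n_obs)
  }
  at <- group_site_freqs(part$at_rich)
  gc <- group_site_freqs(part$gc_rich)
  flagged <- at$n_obs == 0L | gc$n_obs == 0L
  zeta <- (at$fim - gc$fim) + (gc$garp - at$garp)
  zeta[flagged] <- 0
  data.frame(site = seq_len(a$n_sites),
             fimnky_at = at$fim, garp_at = at$garp,
             fimnky_gc = gc$fim, garp_gc = gc$garp,
             zeta = zeta, flagged = flagged,
             row.names = NULL)
}

## Descending-score ranking with ties broken by ascending site index.
rank_sites <- function(scores) order(-scores, seq_along(scores))

#' Remove the highest-scoring fraction of sites
#'
#' Removes round-half-up(`fraction` * n_sites) sites with the largest
#' scores (ties broken by ascending site index); surviving columns keep
#' their original relative order.  With zeta scores this strips the most
#' compositionally biased sites; with evolutionary rates ([strip_by_rate()])
#' the fastest-evolving ones.  Nested across increasing fractions.
#'
#' @param a an [aa_alignment].
#' @param scores numeric vector, one score per site.
#' @param fraction proportion of sites to remove, in `[0, 1)`.
#' @return list: `alignment` (stripped), `removed` (1-based indices of the
#'   removed sites, ascending), `kept` (indices retained).
#' @export
strip_sites <- function(a, scores, fraction) {
  stopifnot(inherits(a, "aa_alignment"))
  if (length(scores) != a$n_sites)
    stop(sprintf("scores length %d != n_sites %d", length(scores), a$n_sites),
         call. = FALSE)
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  n_remove <- floor(fraction * a$n_sites + 0.5)
  removed <- sort(rank_sites(scores)[seq_len(n_remove)])
  kept <- setdiff(seq_len(a$n_sites), removed)
  list(alignment = site_subset(a, kept), removed = removed, kept = kept)
}

#' @rdname strip_sites
#' @param rates numeric vector of per-site evolutionary rates (e.g. from
#'   [read_site_rates()]).
#' @export
strip_by_rate <- function(a, rates, fraction) {
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  strip_sites(a, rates, fraction)
}

#' Progressive stripping schedule
#'
#' Applies [strip_sites()] at each fraction of a schedule (default 10% to
#' 90% in 10% increments).  The removed-site sets are nested by
#' construction.
#'
#' @param a an [aa_alignment].
#' @param scores per-site scores (zeta or rates).
#' @param fractions removal proportions, ascending.
#' @return named list (`"10"`, `"20"`, ...) of [strip_sites()] results.
#' @export
strip_schedule <- function(a, scores, fractions = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(all(diff(fractions) > 0), all(fractions >= 0 & fractions < 1))
  out <- lapply(fractions, function(f) strip_sites(a, scores, f))
  names(out) <- sprintf("%g", round(100 * fractions))
  out
}

#' Write a per-site zeta report as TSV
#'
#' @param tab a [zeta_scores()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zeta_table <- function(tab, path) {
  utils::write.table(format(tab, digits = 10), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
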
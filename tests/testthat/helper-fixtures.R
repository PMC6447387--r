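# Fixture builders shared across test files.  All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

AA20 <- compbias:::AA_ALPHABET

# Alignment from named sequence strings.
aln_from_strings <- function(seqs) {
  m <- do.call(rbind, strsplit(unlist(seqs), ""))
  rownames(m) <- names(seqs)
  aa_alignment(m)
}

# Random amino-acid alignment, optionally with uniform missingness.
random_alignment <- function(n_taxa, n_sites, seed = 1, missing = 0,
                             residues = AA20) {
  set.seed(seed)
  m <- matrix(sample(residues, n_taxa * n_sites, replace = TRUE),
              n_taxa, n_sites,
              dimnames = list(sprintf("tax%03d", seq_len(n_taxa)), NULL))
  if (missing > 0) {
    idx <- which(stats::runif(length(m)) < missing)
    m[idx] <- sample(c("-", "?", "X"), length(idx), replace = TRUE)
  }
  aa_alignment(m)
}

# S4-style reference scheme used throughout the recoding tests.
scheme_s4 <- function() recoding_scheme("ARNDQEILKSTV GHY CMFP W")

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Smallest mean total-variation distance between fitted and true profiles
# over all class matchings (K small).
matched_tv <- function(fitted, truth) {
  K <- nrow(truth)
  perms <- if (K == 1L) list(1L) else
    asplit(as.matrix(expand.grid(rep(list(seq_len(K)), K))), 1L)
  perms <- Filter(function(p) !anyDuplicated(p), perms)
  min(vapply(perms, function(p)
    mean(vapply(seq_len(K), function(k)
      total_variation(fitted[p[k], ], truth[k, ]), 0)), 0))
}
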
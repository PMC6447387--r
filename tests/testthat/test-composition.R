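test_that("GARP:FIMNKY ratios match hand tallies and degenerate cases", {
  # one residue of each amino acid -> uniform composition
  a <- aln_from_strings(c(t1 = paste(AA20, collapse = "")))
  comps <- taxon_compositions(a)
  expect_equal(comps$garp_fimnky, (4 * 0.05) / (6 * 0.05), tolerance = 1e-12)

  # hand tally on GARPFIMNKY: 4 GARP + 6 FIMNKY residues of 10
  b <- aln_from_strings(c(t1 = "GARPFIMNKY"))
  expect_equal(taxon_compositions(b)$garp_fimnky, 0.4 / 0.6)

  # all-G sequence: FIMNKY sum zero -> Inf with warning
  g <- aln_from_strings(c(t1 = "GGGG"))
  expect_warning(cg <- taxon_compositions(g), "FIMNKY")
  expect_equal(cg$garp_fimnky, Inf)
  expect_equal(cg[["G"]], 1)

  # all-missing taxon is an error naming it
  bad <- aln_from_strings(c(ok = "ACDE", gone = "??--"))
  expect_error(taxon_compositions(bad), "gone")

  # output sorted ascending by ratio; frequencies over non-missing cells
  r <- random_alignment(8, 300, seed = 2, missing = 0.1)
  comps <- taxon_compositions(r)
  expect_true(!is.unsorted(comps$garp_fimnky))
  expect_equal(rowSums(as.matrix(comps[, AA20])), rep(1, 8),
               tolerance = 1e-9, ignore_attr = TRUE)

  # scale invariance: duplicating every sequence leaves ratios unchanged
  dup <- aa_alignment(cbind(r$matrix, r$matrix))
  cd <- taxon_compositions(dup)
  expect_equal(cd$garp_fimnky[match(comps$taxon, cd$taxon)],
               comps$garp_fimnky, tolerance = 1e-12)
})

test_that("cutoff partition is strict-below for AT-rich and flags one-sided splits", {
  comps <- data.frame(taxon = c("low", "high"),
                      garp_fimnky = c(1.05, 1.07))
  p <- partition_taxa(comps, cutoff = 1.06)
  expect_equal(p$at_rich, "low")
  expect_equal(p$gc_rich, "high")
  expect_false(p$flagged)

  # exactly on the cutoff goes GC-rich
  comps2 <- data.frame(taxon = c("edge", "low"), garp_fimnky = c(1.06, 0.9))
  p2 <- partition_taxa(comps2, cutoff = 1.06)
  expect_equal(p2$gc_rich, "edge")

  # all on one side -> warning and flag
  comps3 <- data.frame(taxon = paste0("t", 1:3),
                       garp_fimnky = rep(2 / 3, 3))
  expect_warning(p3 <- partition_taxa(comps3, 1.06), "one-sided")
  expect_true(p3$flagged)
  expect_equal(sort(p3$at_rich), sort(comps3$taxon))
})

test_that("per-taxon chi-square statistics match hand computation", {
  # two gap-free taxa with 2-bin frequencies (0.6,0.4) vs (0.4,0.6) over a
  # scheme that isolates {A} vs the rest: use A/R only
  a <- aln_from_strings(c(t1 = strrep("A", 6) |> paste0(strrep("R", 4)),
                          t2 = strrep("A", 4) |> paste0(strrep("R", 6))))
  two_bin <- recoding_scheme(list(c("A", setdiff(AA20, c("A", "R"))), "R"))
  rep2 <- chisquare_report(a, two_bin)
  expect_equal(unname(rep2$t_s), rep(0.1^2 / 0.5 + 0.1^2 / 0.5, 2))
  expect_equal(rep2$max_t, 0.04)

  # identical compositions -> all t_s zero
  same <- aln_from_strings(c(t1 = "ACDKL", t2 = "ACDKL"))
  expect_equal(chisquare_report(same)$max_t, 0)

  # invariance under permutation of taxon order
  r <- random_alignment(6, 200, seed = 3)
  perm <- aa_alignment(r$matrix[rev(r$taxa), ])
  expect_equal(sort(chisquare_report(r)$t_s), sort(chisquare_report(perm)$t_s))

  # zero-frequency bins are dropped, not divided by
  narrow <- random_alignment(4, 100, seed = 5, residues = c("A", "C", "D"))
  expect_true(is.finite(chisquare_report(narrow)$max_t))
})

test_that("max_t is zero iff per-taxon frequency vectors coincide", {
  same <- aln_from_strings(c(t1 = "AACD", t2 = "ACAD", t3 = "CDAA"))
  expect_equal(chisquare_report(same)$max_t, 0, tolerance = 1e-12)
  diff <- aln_from_strings(c(t1 = "AACD", t2 = "ACDD"))
  expect_gt(chisquare_report(diff)$max_t, 1e-12)
})

test_that("UPGMA of compositions is ultrametric and matches oracles", {
  # base case: 2 taxa merge at half their distance
  comps2 <- data.frame(taxon = c("a", "b"),
                       garp_fimnky = c(1, 1),
                       matrix(c(rep(c(0.5, 0.5), 1), rep(0, 18),
                                rep(c(0.4, 0.6), 1), rep(0, 18)),
                              2, 20, byrow = TRUE))
  names(comps2)[3:22] <- AA20
  tr2 <- upgma_compositions(comps2)
  d <- sqrt(sum((as.numeric(comps2[1, AA20]) -
                   as.numeric(comps2[2, AA20]))^2))
  expect_equal(unname(ape::cophenetic.phylo(tr2)["a", "b"]), d,
               tolerance = 1e-9)

  # 4-taxon hand-constructed matrix vs brute-force average-linkage:
  # d(a,b)=2, d(c,d)=3, cross distances 8,8,8,9 -> merges at 1, 1.5,
  # then ((8+8+8+9)/4)/2 = 4.125
  dm <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 9,
                 8, 8, 0, 3,
                 8, 9, 3, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr4 <- compbias:::upgma_from_dist(dm)
  cp <- ape::cophenetic.phylo(tr4)
  expect_equal(unname(cp["a", "b"]), 2)
  expect_equal(unname(cp["c", "d"]), 3)
  expect_equal(unname(cp["a", "c"]), 8.25)

  # agreement with hclust average linkage on random (tie-free) matrices
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(7 * 3), 7, dimnames = list(paste0("s", 1:7), NULL))
    dmat <- as.matrix(dist(x))
    ours <- compbias:::upgma_from_dist(dmat)
    hc <- hclust(dist(x), method = "average")
    expect_equal(ape::cophenetic.phylo(ours)[paste0("s", 1:7), paste0("s", 1:7)],
                 as.matrix(cophenetic(hc))[paste0("s", 1:7), paste0("s", 1:7)],
                 tolerance = 1e-9)
  }

  # ultrametricity on real compositions
  comps <- taxon_compositions(random_alignment(10, 200, seed = 8))
  tr <- upgma_compositions(comps)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})

test_that("biased taxa cluster together in the composition dendrogram", {
  sim <- make_regime_alignment(regime_config(
    n_taxa_total = 24, n_taxa_biased = 8, n_sites = 2000,
    fraction_disparity_sites = 0.3, margin = 0.9, missingness = 0,
    seed = 21))
  comps <- taxon_compositions(sim$alignment)
  tr <- upgma_compositions(comps)
  biased <- sim$truth$taxon_regime$taxon[
    sim$truth$taxon_regime$regime == "biased"]
  expect_true(ape::is.monophyletic(tr, biased))
})
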
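flat_model <- function(...) substitution_model(...)

test_that("the assembled rate matrix has the reversible-model invariants", {
  set.seed(1)
  ex <- matrix(rgamma(400, 1), 20, 20); ex <- (ex + t(ex)) / 2
  fr <- rgamma(20, 2); fr <- fr / sum(fr)
  m <- substitution_model(ex, fr, gamma_shape = 0.7)
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
  # transition kernels are stochastic and satisfy detailed balance
  P <- compbias:::transition_matrix(m, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12)
  expect_equal(m$freqs * P, t(m$freqs * P), tolerance = 1e-9)
  # gamma category rates average to 1
  expect_equal(mean(m$category_rates), 1, tolerance = 1e-6)
})

test_that("simulation honors the degenerate, stationary and closed-form limits", {
  model <- flat_model(gamma_shape = 1)
  # zero-length star tree: every taxon equals the root draw at every site
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  s0 <- simulate_alignment(star, model, 100, seed = 1)
  expect_true(all(apply(s0$matrix, 2, function(col)
    length(unique(col)) == 1L)))

  # very long branch: child composition reaches equilibrium
  tr <- ape::read.tree(text = "(a:0,b:10000);")
  s1 <- simulate_alignment(tr, flat_model(), 10000, seed = 2)
  fb <- tabulate(match(s1$matrix["b", ], AA20), 20) / 10000
  expect_lt(0.5 * sum(abs(fb - 0.05)), 0.02)

  # flat model, one branch: 20-state Jukes-Cantor change probability
  m_nogamma <- flat_model(gamma_shape = Inf)
  tr2 <- ape::read.tree(text = "(a:0,b:0.5);")
  s2 <- simulate_alignment(tr2, m_nogamma, 20000, seed = 3)
  p_hat <- mean(s2$matrix["a", ] != s2$matrix["b", ])
  p_theory <- 19 / 20 * (1 - exp(-20 * 0.5 / 19))
  expect_lt(abs(p_hat - p_theory), 3 * sqrt(p_theory * (1 - p_theory) / 20000))

  expect_error(simulate_alignment("((a:1,b:-1):1);", model, 10), "negative")
  expect_error(simulate_alignment("not a newick ((", model, 10), "malformed")
})

test_that("the observed X2 statistic matches the printed toy table", {
  # 2 taxa, 2 effective states with counts (6,4) and (4,6):
  # pooled expectation (5,5) per taxon, four cells of (1)^2/5 -> 0.8
  counts <- rbind(t1 = c(6, 4), t2 = c(4, 6))
  expect_equal(compbias:::composition_x2(counts), 0.8)
})

test_that("the parametric bootstrap is reproducible and bounded away from zero", {
  set.seed(20)
  tree <- ape::rphylo(8, 1, 0.3)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  model <- flat_model(gamma_shape = 1)
  g <- simulate_alignment(tree, model, 150, seed = 4)
  r1 <- test_gene(g, tree, model, N = 29, seed = 7)
  r2 <- test_gene(g, tree, model, N = 29, seed = 7)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_gte(r1$p_value, 1 / 30)
  expect_lte(r1$p_value, 1)
  expect_length(r1$null_stats, 29L)

  # leaf/taxon mismatch is a descriptive error
  g2 <- taxon_remove(g, g$taxa[1])
  expect_error(test_gene(g2, tree, model, N = 19), "only in tree")
})

test_that("a strongly two-regime gene is rejected at the add-one floor", {
  sim <- make_regime_alignment(regime_config(
    n_taxa_total = 20, n_taxa_biased = 6, n_sites = 300,
    fraction_disparity_sites = 0.3, margin = 0.8, missingness = 0,
    seed = 13))
  model <- flat_model(gamma_shape = 1)
  res <- test_gene(sim$alignment, sim$tree, model, N = 199, seed = 5)
  expect_equal(res$p_value, 1 / 200)
})

test_that("gene selection ranks by p-value with stat and name tie-breaks", {
  mk <- function(gene, p, s) structure(
    list(gene = gene, observed_stat = s, null_stats = numeric(0),
         p_value = p, N = 99, seed = 1), class = "homogeneity_result")
  res <- list(mk("g1", 0.9, 5), mk("g2", 0.1, 2), mk("g3", 0.5, 1))
  expect_equal(select_homogeneous(res, 2), c("g1", "g3"))
  expect_setequal(select_homogeneous(res, 3), c("g1", "g2", "g3"))
  # ties: smaller statistic first, then name
  res2 <- list(mk("b", 0.5, 2), mk("a", 0.5, 2), mk("c", 0.5, 1))
  expect_equal(select_homogeneous(res2, 2), c("c", "a"))
  expect_error(select_homogeneous(res, 4))
})

test_that("homogeneous-gene selection lowers pooled heterogeneity on mixed genes", {
  # 12 genes: 8 simulated under a homogeneous model, 4 two-regime
  set.seed(31)
  tree <- ape::rphylo(12, 1, 0.3)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("t%03d", 1:12)
  model <- flat_model(gamma_shape = 1)
  genes <- list()
  for (i in 1:8)
    genes[[sprintf("hom%02d", i)]] <- simulate_alignment(tree, model, 300,
                                                         seed = 100 + i)
  # one two-regime alignment carved into 4 genes so the biased taxa are the
  # same in every heterogeneous gene
  sim <- make_regime_alignment(regime_config(
    n_taxa_total = 12, n_taxa_biased = 4, n_sites = 1200,
    fraction_disparity_sites = 0.4, margin = 0.8, missingness = 0,
    seed = 207))
  for (i in 1:4) {
    g <- site_subset(sim$alignment, ((i - 1) * 300 + 1):(i * 300))
    rownames(g$matrix) <- tree$tip.label   # align taxon sets across genes
    genes[[sprintf("het%02d", i)]] <- aa_alignment(g$matrix)
  }
  results <- lapply(names(genes), function(nm)
    test_gene(genes[[nm]], tree, model, N = 49,
              seed = match(nm, names(genes)), gene = nm))
  picked <- select_homogeneous(results, 8)
  expect_true(all(startsWith(picked, "hom")))
  sup_all <- concatenate(genes)$alignment
  sup_sel <- concatenate(genes[picked])$alignment
  expect_lt(chisquare_report(sup_sel)$max_t, chisquare_report(sup_all)$max_t)
})
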
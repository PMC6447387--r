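test_that("scheme construction validates bins and round-trips its file format", {
  s4 <- scheme_s4()
  expect_equal(s4$n_bins, 4L)
  expect_equal(s4$symbols, c("A", "C", "G", "T"))
  expect_equal(format(s4), "ARNDQEILKSTV GHY CMFP W")

  path <- tempfile()
  write_scheme(s4, path)
  expect_identical(readLines(path), "ARNDQEILKSTV GHY CMFP W")
  s4b <- read_scheme(path)
  expect_identical(s4b$bins, s4$bins)

  expect_error(recoding_scheme("ARNDQEILKSTV GHY CMFP"), "cover")
  expect_error(recoding_scheme("ARNDQEILKSTVW GHY CMFP W"), "more than one")
  # six bins default to digit symbols
  s6 <- recoding_scheme(list(c("A","R","N","D"), c("C","Q","E"), c("G","H"),
                             c("I","L","K","M"), c("F","P","S","T"),
                             c("W","V","Y")))
  expect_equal(s6$symbols, as.character(0:5))
})

test_that("applying a scheme maps residues to bin symbols and passes missing through", {
  s4 <- scheme_s4()
  a <- aln_from_strings(c(x = "GW-D"))
  expect_equal(paste(apply_scheme(a, s4)$matrix["x", ], collapse = ""),
               "CT-A")

  # identity 20-bin scheme is a pure renaming
  id <- recoding_scheme(as.list(AA20), symbols = AA20)
  r <- random_alignment(5, 80, seed = 7, missing = 0.1)
  expect_identical(apply_scheme(r, id)$matrix, r$matrix)

  # recoded pooled bin frequencies equal summed member frequencies
  rep20 <- chisquare_report(r)
  rep4 <- chisquare_report(apply_scheme(r, s4))
  expected <- vapply(s4$bins, function(b) sum(rep20$pooled_freqs[b]), 0)
  expect_equal(unname(rep4$pooled_freqs), expected, tolerance = 1e-12)

  # on-the-fly binning and recode-then-report agree
  rep_fly <- chisquare_report(r, s4)
  expect_equal(rep_fly$t_s, rep4$t_s, tolerance = 1e-12)
  expect_equal(rep_fly$max_t, rep4$max_t, tolerance = 1e-12)
})

test_that("hill-climbing search finds constructible-zero and enumeration optima", {
  # taxa differing only by an L<->V frequency swap: binning L with V zeros max_t
  set.seed(10)
  base <- c(rep("L", 30), rep("V", 20), rep("A", 25), rep("K", 25))
  swap <- c(rep("L", 20), rep("V", 30), rep("A", 25), rep("K", 25))
  a <- aln_from_strings(c(t1 = paste(sample(base), collapse = ""),
                          t2 = paste(sample(swap), collapse = "")))
  sr <- search_scheme(a, 2, n_restarts = 10, seed = 1)
  expect_equal(sr$max_t, 0, tolerance = 1e-12)
  lv_bin <- vapply(sr$scheme$bins, function(b) all(c("L", "V") %in% b), TRUE)
  expect_true(any(lv_bin))

  # 5-residue instances: hill climb vs exhaustive two-bin enumeration
  for (seed in 1:6) {
    inst <- random_alignment(8, 150, seed = seed,
                             residues = c("A", "R", "N", "D", "C"))
    sr <- search_scheme(inst, 2, n_restarts = 20, seed = seed)
    en <- enumerate_two_bin(inst)
    expect_equal(sr$max_t, en$max_t, tolerance = 1e-12,
                 label = sprintf("instance %d", seed))
  }

  # restart stability: different seeds reach the same optimum
  inst <- random_alignment(8, 150, seed = 42,
                           residues = c("A", "R", "N", "D", "C"))
  r1 <- search_scheme(inst, 2, n_restarts = 20, seed = 1)
  r2 <- search_scheme(inst, 2, n_restarts = 20, seed = 2)
  expect_equal(r1$max_t, r2$max_t, tolerance = 1e-12)

  # returned value never exceeds anything on the trace
  expect_true(all(r1$max_t <= r1$trace + 1e-12))

  expect_error(search_scheme(inst, 1), "n_bins")
  expect_error(search_scheme(inst, 6), "distinct residues")
})

test_that("search is deterministic given a seed and reproducible from scratch", {
  a <- random_alignment(10, 300, seed = 77)
  r1 <- search_scheme(a, 4, n_restarts = 5, seed = 9)
  r2 <- search_scheme(a, 4, n_restarts = 5, seed = 9)
  expect_identical(format(r1$scheme), format(r2$scheme))
  expect_identical(r1$trace, r2$trace)
  # stored criterion equals a from-scratch recomputation
  expect_equal(chisquare_report(a, r1$scheme)$max_t, r1$max_t,
               tolerance = 1e-12)
})

test_that("profile collapse sums member frequencies and is linear", {
  s4 <- scheme_s4()
  uniform <- profile_mixture(1, matrix(0.05, 1, 20,
                                       dimnames = list(NULL, AA20)))
  expect_equal(unname(collapse_profiles(uniform, s4)$profiles[1, ]),
               c(0.60, 0.15, 0.20, 0.05))

  point <- matrix(0, 1, 20, dimnames = list(NULL, AA20))
  point[1, "W"] <- 1
  expect_equal(unname(collapse_profiles(profile_mixture(1, point),
                                        s4)$profiles[1, ]),
               c(0, 0, 0, 1))

  # every collapsed profile renormalizes to 1 for a random 60-class mixture
  set.seed(4)
  profs <- matrix(rgamma(60 * 20, 0.5), 60, 20,
                  dimnames = list(NULL, AA20))
  m <- profile_mixture(rgamma(60, 1), profs)
  cm <- collapse_profiles(m, s4)
  expect_equal(rowSums(cm$profiles), rep(1, 60), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cm$weights, m$weights)

  # linearity: collapse(alpha p + (1-alpha) q) = alpha collapse(p) + ...
  p <- profs[1, ] / sum(profs[1, ]); q <- profs[2, ] / sum(profs[2, ])
  alpha <- 0.3
  mix <- profile_mixture(1, matrix(alpha * p + (1 - alpha) * q, 1,
                                   dimnames = list(NULL, AA20)))
  lhs <- collapse_profiles(mix, s4)$profiles[1, ]
  rhs <- alpha * collapse_profiles(profile_mixture(1, matrix(p, 1,
           dimnames = list(NULL, AA20))), s4)$profiles[1, ] +
    (1 - alpha) * collapse_profiles(profile_mixture(1, matrix(q, 1,
           dimnames = list(NULL, AA20))), s4)$profiles[1, ]
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
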
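test_that("hypergeometric upper tail is exact", {
  # hand enumeration: (C(4,2)C(6,1) + C(4,3)C(6,0)) / C(10,3) = 40/120
  expect_equal(hypergeom_upper_tail(2, 4, 3, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 10), 1)  # K = N: every draw hits

  # against direct choose()-ratio enumeration on a modest grid
  for (N in c(1, 2, 5, 9, 12)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   oracle_hyper_upper(k, K, n, N), tolerance = 1e-12)
    }
  }

  # against the library upper tail on larger random parameters
  set.seed(17)
  for (rep in 1:50) {
    N <- sample(50:5000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # monotone non-increasing in k
  p_seq <- vapply(0:10, hypergeom_upper_tail, numeric(1), K = 20, n = 10, N = 100)
  expect_true(all(diff(p_seq) <= 1e-15))

  expect_error(hypergeom_upper_tail(5, 4, 10, 20), "inconsistent")
  expect_error(hypergeom_upper_tail(1, 25, 10, 20), "inconsistent")
})

test_that("Benjamini-Hochberg step-up matches hand examples and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order restored: shuffle the same example
  expect_equal(bh_fdr(c(0.04, 0.01, 0.03, 0.02)), rep(0.04, 4))

  set.seed(19)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
  }

  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(1.2), "0, 1")
})

test_that("enrich counts against the universe and ranks terms", {
  universe <- sprintf("g%03d", 1:100)
  terms <- list(T1 = universe[1:10], T2 = universe[11:40],
                T3 = c("not_in_universe"), T4 = universe[1:100])
  attr(terms, "descriptions") <- c(T1 = "small", T2 = "medium",
                                   T3 = "ghost", T4 = "all")

  # selected = universe forces k = K for every term -> all p = 1
  res_all <- enrich(universe, terms, universe)
  expect_true(all(res_all$p == 1))

  # T3 has no member in the universe and is skipped
  sel <- universe[1:10]
  res <- enrich(sel, terms, universe)
  expect_false("T3" %in% res$term_id)
  expect_equal(res$term_id[1], "T1")  # perfect overlap ranks first
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$k, 10); expect_equal(r1$K, 10)
  expect_equal(r1$n, 10); expect_equal(r1$N, 100)
  expect_equal(r1$p, hypergeom_upper_tail(10, 10, 10, 100))
  expect_true(r1$significant)
  # zero-overlap terms are still tested with p = 1
  r2 <- res[res$term_id == "T2", ]
  expect_equal(r2$k, 0); expect_equal(r2$p, 1)
  expect_true(all(res$q >= res$p - 1e-15))

  # selected genes outside the universe are dropped with a warning
  expect_warning(res_w <- enrich(c(sel, "alien"), terms, universe), "outside")
  expect_equal(res_w[res_w$term_id == "T1", "k"], 10)

  # empty inputs
  expect_equal(nrow(enrich(sel, list(), universe)), 0L)
  expect_warning(res0 <- enrich(character(0), terms, universe), "no selected")
  expect_true(all(res0$p == 1))
  expect_error(enrich(sel, terms, character(0)), "empty universe")
})

test_that("the planted category tops the ranking on a simulated cohort", {
  ev <- list(cnv_event(1, 1, 1, 30000, +1), cnv_event(2, 1, 170001, 200000, -1))
  co <- simulate_cohort(tiny_config(seed = 2, cnv_events = ev, noise_sd = 0.15,
                                    reference_bias_sd = 0.3, n_terms = 10L,
                                    genes_per_term = 6L))
  norm <- renormalize(co$matrix)
  sel <- select_divergent(norm, k = 2)
  universe <- rownames(norm)
  res <- enrich(sel$selected, co$terms, universe)
  expect_equal(res$term_id[1], "TERM_001")
  expect_true(res$significant[1])
})
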
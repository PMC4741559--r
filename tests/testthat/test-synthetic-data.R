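test_that("degenerate no-signal configuration yields an (almost) all-zero matrix", {
  co <- simulate_cohort(tiny_config(noise_sd = 1e-12))
  expect_equal(dim(co$matrix), c(40L, 4L))
  expect_lt(max(abs(co$matrix)), 1e-9)
  expect_length(co$truth_divergent_genes, 0)
})

test_that("a planted event appears exactly where and for whom it was planted", {
  # chromosome 1: 20 genes over 200 kb -> genes 1..10 have midpoints <= 100 kb
  ev <- cnv_event(1, 1, 1, 100000, +1.0, "block")
  co <- simulate_cohort(tiny_config(cnv_events = list(ev)))
  in_block <- sprintf("g01_%04d", 1:10)
  g1 <- names(co$truth_partition)[co$truth_partition == 1]
  g2 <- names(co$truth_partition)[co$truth_partition == 2]
  expect_equal(unname(co$matrix[in_block, g1]),
               matrix(1, 10, 2), tolerance = 1e-6)
  expect_lt(max(abs(co$matrix[in_block, g2])), 1e-6)
  expect_lt(max(abs(co$matrix[setdiff(rownames(co$matrix), in_block), ])), 1e-6)
  expect_setequal(co$truth_divergent_genes, in_block)
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(seed = 42, genes_per_chromosome = 30L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$terms, b$terms)
  expect_identical(a$bands, b$bands)
  expect_identical(a$truth_divergent_genes, b$truth_divergent_genes)
  # different seed changes the noise
  c <- simulate_cohort(simulation_config(seed = 43, genes_per_chromosome = 30L))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("overlapping same-group events sum their deltas with a warning", {
  evs <- list(cnv_event(1, 1, 1, 100000, +1.0),
              cnv_event(1, 1, 50000, 150000, +0.5))
  expect_warning(co <- simulate_cohort(tiny_config(cnv_events = evs)),
                 "overlapping")
  g1 <- names(co$truth_partition)[co$truth_partition == 1][1]
  # genes 6..10 (midpoints 55..95 kb) carry both events
  expect_equal(unname(co$matrix["g01_0007", g1]), 1.5, tolerance = 1e-6)
  expect_equal(unname(co$matrix["g01_0002", g1]), 1.0, tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(group_sizes = integer(0)), "group sizes")
  expect_error(simulation_config(group_sizes = c(3, 0)), "group sizes")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(reference_bias_sd = -1), "reference_bias_sd")
  expect_error(tiny_config(subtelomere_length_bp = 150000L), "subtelomere")
  expect_error(tiny_config(cnv_events = list(cnv_event(1, 1, 1, 999999, 1))),
               "outside")
  expect_error(tiny_config(cnv_events = list(cnv_event(5, 1, 1, 1000, 1))),
               "group index")
  expect_error(cnv_event(1, 1, 1, 100, 0), "non-zero")
})

test_that("truth never names a gene outside every event region", {
  for (seed in 1:3) {
    ev <- list(cnv_event(1, 1, 1, 60000, +1), cnv_event(2, 2, 250000, 300000, -1))
    co <- simulate_cohort(tiny_config(seed = seed, cnv_events = ev,
                                      noise_sd = 0.2,
                                      reference_bias_sd = 0.3))
    mid <- (co$annotation$start + co$annotation$end) / 2
    covered <- co$annotation$gene_id[
      (co$annotation$chromosome == 1 & mid <= 60000) |
        (co$annotation$chromosome == 2 & mid >= 250000)]
    expect_true(all(co$truth_divergent_genes %in% covered))
  }
})

test_that("the annotation flags subtelomeric genes by midpoint", {
  co <- simulate_cohort(tiny_config())
  ann <- co$annotation
  mid <- (ann$start + ann$end) / 2
  L <- ifelse(ann$chromosome == 1, 200000, 300000)
  expect_identical(ann$subtelomeric, mid <= 30000 | mid >= L - 30000 + 1)
  expect_true(any(ann$subtelomeric) && !all(ann$subtelomeric))
})

test_that("band simulation is deterministic and plants markers per group", {
  cfg <- tiny_config(band_jitter_sd = 0,
                     marker_bands = list(1300, numeric(0)))
  bands <- simulate_bands(cfg)
  expect_identical(bands, simulate_bands(cfg))
  has_marker <- vapply(bands, function(b) any(abs(b - 1300) < 1e-9), logical(1))
  expect_identical(unname(has_marker), c(TRUE, TRUE, FALSE, FALSE))
  # jitter 0, no markers anywhere -> identical lists
  cfg0 <- tiny_config(band_jitter_sd = 0,
                      marker_bands = list(numeric(0), numeric(0)))
  bands0 <- simulate_bands(cfg0)
  expect_true(all(vapply(bands0, identical, logical(1), bands0[[1]])))
})
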
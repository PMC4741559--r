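mk <- function(values, n_strains, genes = NULL) {
  m <- matrix(values, ncol = n_strains)
  rownames(m) <- if (is.null(genes)) sprintf("g%03d", seq_len(nrow(m))) else genes
  colnames(m) <- sprintf("s%02d", seq_len(n_strains))
  m
}

test_that("renormalize centers every gene and cancels per-gene bias exactly", {
  expect_equal(unname(renormalize(mk(c(0.5, 0.1, 0.0), 3))[1, ]),
               c(0.3, -0.1, -0.2))

  set.seed(3)
  m <- mk(rnorm(50 * 6), 6)
  r <- renormalize(m)
  expect_lt(max(abs(rowMeans(r))), 1e-12)
  # additive per-gene bias cancels to machine precision
  bias <- rnorm(50, 0, 5)
  expect_equal(renormalize(m + bias), r, tolerance = 1e-12)
  # idempotence
  expect_equal(renormalize(r), r, tolerance = 1e-12)

  # missing values are excluded from the mean; all-missing rows drop
  m[1, ] <- NA
  m[2, 1] <- NA
  expect_warning(r2 <- renormalize(m), "dropped")
  expect_false("g001" %in% rownames(r2))
  expect_equal(unname(r2["g002", -1]),
               unname(m["g002", -1] - mean(m["g002", -1])))
  expect_error(renormalize(mk(1:5, 1)), "2 strains")
})

test_that("divergence profile computes population SDs and smooths per chromosome", {
  # two strains at (x, -x) have population SD exactly |x|
  sds <- c(0, 0, 3, 0, 0)
  ann <- genome_annotation(sprintf("g%03d", 1:5), 1, (0:4) * 100 + 1,
                           (0:4) * 100 + 100, FALSE)
  m <- mk(c(sds, -sds), 2)
  prof <- divergence_profile(m, ann, window = 3L)
  expect_equal(prof$sd, sds)
  expect_equal(prof$smoothed_sd, c(0, 1, 1, 1, 0))  # edge windows shrink

  # window 1 is the identity
  expect_equal(divergence_profile(m, ann, window = 1L)$smoothed_sd, sds)

  # windows never cross chromosome boundaries; constants are preserved
  ann2 <- genome_annotation(sprintf("g%03d", 1:10), rep(1:2, each = 5),
                            rep((0:4) * 100 + 1, 2), rep((0:4) * 100 + 100, 2),
                            FALSE)
  m2 <- mk(c(rep(1, 5), rep(4, 5), rep(-1, 5), rep(-4, 5)), 2)
  prof2 <- divergence_profile(m2, ann2, window = 5L)
  expect_equal(prof2$smoothed_sd, c(rep(1, 5), rep(4, 5)))

  # permutation of strain columns changes nothing
  set.seed(9)
  m3 <- mk(rnorm(10 * 6), 6)
  p1 <- divergence_profile(m3, ann2, window = 3L)
  p2 <- divergence_profile(m3[, sample(6)], ann2, window = 3L)
  expect_equal(p1, p2)

  # a gene observed in fewer than 2 strains gets NA sd
  m3[1, -1] <- NA
  expect_true(is.na(divergence_profile(m3, ann2, window = 1L)$sd[1]))

  expect_error(divergence_profile(m, ann, window = 2L), "odd")
  expect_error(divergence_profile(m, ann, window = 0L), "odd")
})

test_that("segmentation solves the penalized least-squares problem exactly", {
  # constant vector -> one segment with that mean
  s <- segment_profile(rep(2.5, 8), penalty = 0.1)
  expect_equal(nrow(s), 1L)
  expect_equal(s$mean, 2.5)

  # a clean step: 2-segment cost beats 1-segment when penalty < SSE saved (2.5)
  x <- c(rep(0, 5), rep(1, 5))
  s2 <- segment_profile(x, penalty = 1)
  expect_equal(s2$start_index, c(1L, 6L))
  expect_equal(s2$mean, c(0, 1))
  # and loses when the penalty exceeds it
  s1 <- segment_profile(x, penalty = 3)
  expect_equal(nrow(s1), 1L)

  # exact cost ties resolve toward fewer segments: both splits cost 1.0 here
  tie <- segment_profile(c(0, 1), penalty = 0.5)
  expect_equal(nrow(tie), 1L)

  # equals exhaustive enumeration on random vectors
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    v <- round(rnorm(n), 2)
    pen <- runif(1, 0.05, 2)
    seg <- segment_profile(v, penalty = pen)
    expect_equal(segmentation_cost(seg, v, pen),
                 oracle_segment_cost(v, pen), tolerance = 1e-9)
    expect_equal(seg$start_index[1], 1L)
    expect_equal(seg$end_index[nrow(seg)], n)
    expect_equal(seg$start_index[-1], head(seg$end_index, -1) + 1L)
  }

  # automatic penalty recovers a clear step under noise
  set.seed(4)
  v <- c(rep(0, 30), rep(1, 30)) + rnorm(60, 0, 0.1)
  s_auto <- segment_profile(v)
  expect_equal(nrow(s_auto), 2L)
  expect_equal(s_auto$start_index[2], 31L)

  expect_error(segment_profile(numeric(0)), "empty")
  expect_error(segment_profile(1:5, penalty = -1), "penalty")
})

test_that("region calls label gains and losses with an inclusive boundary", {
  ann <- genome_annotation(sprintf("g%03d", 1:10), 1, (0:9) * 100 + 1,
                           (0:9) * 100 + 100, FALSE)
  regions <- data.frame(name = c("left", "right", "empty"),
                        chromosome = c(1, 1, 2),
                        start = c(1, 501, 1), end = c(500, 1000, 500))
  z <- mk(rep(0, 20), 2, genes = sprintf("g%03d", 1:10))
  calls <- call_region_events(z, ann, regions, threshold = 0.2)
  expect_true(all(calls$call[calls$region != "empty"] == "neutral"))
  expect_true(all(calls$call[calls$region == "empty"] == "missing"))

  # boundary inclusive: mean exactly +threshold is a gain
  m <- z; m[1:5, 1] <- 0.2
  calls2 <- call_region_events(m, ann, regions, threshold = 0.2)
  expect_equal(calls2$call[calls2$region == "left" & calls2$strain == "s01"],
               "gain")

  # a planted noise-free event is called for exactly its group's strains
  ev <- cnv_event(1, 1, 1, 100000, +1.0)
  co <- simulate_cohort(tiny_config(cnv_events = list(ev)))
  norm <- renormalize(co$matrix)
  reg <- data.frame(name = "block", chromosome = 1, start = 1, end = 100000)
  calls3 <- call_region_events(norm, co$annotation, reg, threshold = 0.2)
  grp <- co$truth_partition[calls3$strain]
  expect_true(all(calls3$call[grp == 1] == "gain"))
  expect_true(all(calls3$call[grp == 2] == "loss"))  # re-normalization pushes others down

  expect_error(call_region_events(z, ann, regions, threshold = 0), "threshold")
})

test_that("smoothed divergence peaks fall inside the planted event regions", {
  hits <- 0L; total <- 0L
  for (seed in 1:2) {
    cfg <- simulation_config(seed = seed)
    co <- simulate_cohort(cfg)
    prof <- divergence_profile(renormalize(co$matrix), co$annotation,
                               window = 21L)
    mid <- (co$annotation$start + co$annotation$end) / 2
    names(mid) <- co$annotation$gene_id
    ev_chroms <- unique(vapply(cfg$cnv_events, `[[`, integer(1), "chromosome"))
    for (chr in ev_chroms) {
      total <- total + 1L
      sub <- prof[prof$chromosome == chr, ]
      top_gene <- sub$gene_id[which.max(sub$smoothed_sd)]
      inside <- any(vapply(cfg$cnv_events, function(ev) {
        ev$chromosome == chr && mid[top_gene] >= ev$start &&
          mid[top_gene] <= ev$end
      }, logical(1)))
      hits <- hits + inside
    }
  }
  expect_gte(total, 20L)
  expect_gte(hits / total, 0.95)
})
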
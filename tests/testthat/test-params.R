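test_that("GEV matches its defining formula on hand cases", {
  # 2 points: GFPs {1,2}, |r| {1, 0.5} -> (1 + 1) / (1 + 4) = 0.4
  seg <- toy_segmentation(matrix(c(1, 2), 2, 1),
                          best_corr = matrix(c(1, 0.5), 2, 1),
                          gfp = matrix(c(1, 2), 2, 1))
  g <- gev(seg)
  expect_equal(g$total, 0.4)
  expect_equal(as.numeric(g$per_class), c(0.2, 0.2, 0, 0))
  expect_equal(sum(g$per_class), g$total)
  zero <- toy_segmentation(matrix(1, 3, 1), gfp = matrix(0, 3, 1))
  expect_error(gev(zero), "GFP")
})

test_that("noise-free backfit explains all variance; worse labels explain less", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = Inf,
                            n_epochs = 5, seed = 13)
  ep <- average_reference(sim$epochs)
  seg <- backfit(ep, fix_templates)
  expect_gte(gev(seg)$total, 1 - 1e-6)
  set.seed(2)
  rand <- matrix(sample(1:4, length(seg$labels), replace = TRUE),
                 nrow(seg$labels))
  seg_rand <- make_segmentation(ep, fix_templates, rand)
  expect_lt(gev(seg_rand)$total, gev(seg)$total)
})

test_that("durations respect the truncation convention", {
  seg <- toy_segmentation(matrix(c(1, 1, 2, 2, 2, 1), 6, 1))
  d <- mean_duration(seg)
  expect_equal(d[["B"]], 24)            # 3 samples at 125 Hz
  expect_true(is.na(d[["A"]]))          # both A runs touch the boundary
  d_all <- mean_duration(seg, include_truncated = TRUE)
  expect_equal(d_all[["A"]], 12)        # mean(2, 1) * 8 ms
  mono <- toy_segmentation(matrix(1, 10, 1))
  expect_true(is.na(mean_duration(mono)[["A"]]))
})

test_that("frequency counts run onsets per analyzed second", {
  lab <- rep(1L, 250)
  lab[60:70] <- 2L
  lab[150:165] <- 2L
  seg <- toy_segmentation(matrix(lab, 250, 1))
  expect_equal(ms_frequency(seg)[["B"]], 1.0)   # 2 onsets / 2 s
  expect_equal(ms_frequency(seg)[["C"]], 0)
})

test_that("frequency approximates the renewal rate on long simulations", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = Inf,
                            n_epochs = 100, seed = 19)
  seg <- toy_segmentation(sim$truth$labels)
  f <- ms_frequency(seg, include_truncated = TRUE)
  expect_equal(as.numeric(f), rep(0.25 / 0.080, 4), tolerance = 0.1)
})

test_that("coverage is an exact time share", {
  seg <- toy_segmentation(matrix(c(1, 1, 2, 2), 4, 1))
  expect_equal(as.numeric(ms_coverage(seg)), c(0.5, 0.5, 0, 0))
  expect_equal(sum(ms_coverage(seg)), 1)
  one <- toy_segmentation(matrix(3, 8, 1))
  expect_equal(ms_coverage(one)[["C"]], 1)
})

test_that("per-state GFP is the conditional mean of the GFP curve", {
  seg <- toy_segmentation(matrix(c(1, 1, 2), 3, 1),
                          gfp = matrix(c(1, 2, 3), 3, 1))
  expect_equal(gfp_per_state(seg)[["A"]], 1.5)
  expect_equal(gfp_per_state(seg)[["B"]], 3)
  expect_true(is.na(gfp_per_state(seg)[["D"]]))
  const <- toy_segmentation(matrix(c(1, 2, 1), 3, 1),
                            gfp = matrix(5, 3, 1))
  expect_true(all(gfp_per_state(const)[1:2] == 5))
})

test_that("transition matrix counts within-epoch changes only", {
  seg <- toy_segmentation(matrix(c(1, 2, 1, 2), 4, 1))
  P <- ms_transitions(seg)
  expect_equal(P[1, 2], 1)
  expect_equal(P[2, 1], 1)
  expect_equal(as.numeric(diag(P)), rep(0, 4))
  # epoch boundary A|B is not a transition
  two <- toy_segmentation(cbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(sum(attr(ms_transitions(two), "counts")), 0)
})

test_that("transition probabilities recover a uniform generator", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = Inf,
                            n_epochs = 60, seed = 29)
  seg <- toy_segmentation(sim$truth$labels)
  P <- ms_transitions(seg)
  expect_gt(sum(attr(P, "counts")), 500)
  off <- P[row(P) != col(P)]
  expect_true(all(abs(off - 1 / 3) < 0.05))
})

test_that("coverage = frequency x duration in include-truncated mode", {
  sim <- simulate_recording(fix_templates, c(60, 75, 90, 100), snr = Inf,
                            n_epochs = 20, seed = 31)
  seg <- toy_segmentation(sim$truth$labels)
  f <- ms_frequency(seg, include_truncated = TRUE)
  d <- mean_duration(seg, include_truncated = TRUE)
  expect_equal(as.numeric(f * d / 1000), as.numeric(ms_coverage(seg)),
               tolerance = 1e-9)
})

test_that("the parameter bundle is internally consistent", {
  sim <- simulate_recording(fix_templates, c(60, 75, 90, 100), snr = 4,
                            n_epochs = 6, seed = 37)
  seg <- backfit(average_reference(sim$epochs), fix_templates)
  p <- microstate_parameters(seg)
  expect_equal(sum(p$table$coverage), 1, tolerance = 1e-9)
  expect_equal(sum(p$table$gev), p$total_gev, tolerance = 1e-12)
  expect_equal(p$analyzed_s, 12)
  rows <- parameter_rows(seg, "P1", "TD", "EC")
  expect_equal(nrow(rows), 20)          # 4 classes x 5 parameters
  expect_equal(attr(rows, "total_gev"), p$total_gev)
})

test_that("parameter recovery is accurate when states are identifiable", {
  # estimator validation at high SNR: ranks and values match the programme
  sim <- simulate_recording(fix_templates, c(60, 75, 90, 100), snr = 8,
                            n_epochs = 30, seed = 43)
  seg <- backfit(average_reference(sim$epochs), fix_templates)
  d <- mean_duration(seg)
  expect_true(all(abs(d / c(60, 75, 90, 100) - 1) < 0.15))
  expect_false(is.unsorted(d))
  cov <- ms_coverage(seg)
  expect_true(all(abs(cov - stationary_coverage(c(60, 75, 90, 100))) < 0.03))
})
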
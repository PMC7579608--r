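test_that("GFP is the population SD across channels", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(5, 5, 5)), 0)
  expect_equal(gfp(c(2, 0, -2, 0)), sqrt(2))
  # reference and scale behaviour
  v <- rnorm(32)
  expect_equal(gfp(v + 7), gfp(v))
  expect_equal(gfp(3 * v), 3 * gfp(v))
  expect_error(gfp(3), "channels")
})

test_that("GFP peaks are strict interior maxima with a first-sample plateau rule", {
  expect_equal(find_gfp_peaks(c(1, 3, 1, 2, 5, 2)), c(2, 5))
  expect_length(find_gfp_peaks(c(1, 2, 3, 4, 5)), 0)
  expect_equal(find_gfp_peaks(c(1, 2, 2, 1)), 2)
  expect_length(find_gfp_peaks(c(2, 1)), 0)
  # min_sep keeps the larger of two close peaks
  expect_equal(find_gfp_peaks(c(0, 3, 0, 5, 0, 1, 0), min_sep = 3), 4)
})

test_that("spatial correlation matches hand values and rejects bad input", {
  u <- c(1, 0, -1)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), -1)
  expect_equal(spatial_correlation(c(1, 0, -1), c(0, 1, -1)), 0.5)
  expect_error(spatial_correlation(u, c(1, 1, 1)), "constant")
  expect_error(spatial_correlation(u, c(1, 2)), "length")
})

test_that("T-AAHC recovers well-separated generators from noiseless maps", {
  gen <- orthogonal_generators(32)
  set.seed(12)
  truth <- rep(1:4, each = 10)
  amps <- runif(40, 5, 15)
  maps <- gen[, truth] * rep(amps, each = 32)
  tpl <- taahc(maps, gfp(maps), K = 4)
  part <- attr(tpl, "partition")
  # induced partition equals ground truth (up to cluster numbering)
  expect_equal(length(unique(paste(truth, part))), 4)
  R <- abs(cor(tpl$maps, gen))
  expect_true(all(apply(R, 1, max) >= 0.999))
  expect_true(all(apply(R, 1, function(r) sum(r >= 0.999)) == 1))
})

test_that("T-AAHC degenerate and polarity cases", {
  gen <- orthogonal_generators(32)
  maps <- gen[, c(1, 2, 3, 4)] * 3
  # K = number of maps: each map its own cluster, centroid = normalized map
  tpl <- taahc(maps, rep(1, 4), K = 4)
  expect_equal(sort(attr(tpl, "partition")), 1:4)
  for (k in 1:4) {
    best <- max(abs(cor(tpl$maps[, k], maps)))
    expect_equal(best, 1, tolerance = 1e-9)
  }
  expect_error(taahc(maps, rep(1, 4), K = 5), "fewer maps")
  # sign flips of the inputs change nothing (polarity invariance)
  set.seed(30)
  truth <- rep(1:4, each = 8)
  m2 <- gen[, truth] * rep(runif(32, 5, 15), each = 32)
  flips <- sample(c(-1, 1), 32, replace = TRUE)
  a <- taahc(m2, gfp(m2), K = 4)
  b <- taahc(sweep(m2, 2, flips, "*"), gfp(m2), K = 4)
  expect_equal(attr(a, "partition"), attr(b, "partition"))
  expect_equal(unname(abs(diag(cor(a$maps, b$maps)))), rep(1, 4),
               tolerance = 1e-9)
})

test_that("total GEV is non-decreasing in K on the same peak maps", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = 2, n_epochs = 4,
                            seed = 61)
  ep <- average_reference(sim$epochs)
  pk <- gfp_peak_maps(ep)
  gevs <- sapply(2:6, function(K) {
    tpl <- taahc(pk$maps, pk$gfp, K = K, montage = fix_montage)
    seg <- backfit(ep, tpl)
    gev(seg)$total
  })
  expect_true(all(diff(gevs) >= -1e-9))
})

test_that("group templates pool individual maps polarity-invariantly", {
  tpls <- replicate(3, fix_templates, simplify = FALSE)
  g <- group_templates(tpls, K = 4)
  expect_true(all(apply(abs(cor(g$maps, fix_templates$maps)), 1, max) > 0.999))
  flipped <- fix_templates
  flipped$maps <- -flipped$maps
  g2 <- group_templates(list(fix_templates, flipped), K = 4)
  expect_true(all(apply(abs(cor(g2$maps, fix_templates$maps)), 1, max) > 0.999))
  expect_error(group_templates(list(), 4), "empty")
})

test_that("template sorting equals the exhaustive assignment oracle", {
  set.seed(17)
  for (rep_i in 1:5) {
    maps <- matrix(rnorm(32 * 4), 32)
    maps <- sweep(maps, 2, colMeans(maps))
    tpl <- microstatr:::new_templates(paste0("M", 1:4), maps, fix_montage)
    srt <- sort_to_normative(tpl, fix_templates)
    oracle <- sort_oracle_score(tpl$maps, fix_templates$maps)
    expect_equal(oracle$n_perms, 24)
    expect_equal(sum(attr(srt, "similarity")), oracle$score, tolerance = 1e-12)
    expect_equal(unname(attr(srt, "order")), oracle$perm)
  }
})

test_that("sorting recovers a shuffled, sign-flipped normative set", {
  perm <- c(3, 1, 4, 2)
  shuf <- microstatr:::new_templates(
    paste0("M", 1:4), fix_templates$maps[, perm] %*% diag(c(-1, 1, -1, 1)),
    fix_montage)
  srt <- sort_to_normative(shuf, fix_templates)
  expect_equal(srt$labels, c("A", "B", "C", "D"))
  expect_equal(sum(attr(srt, "similarity")), 4, tolerance = 1e-9)
  expect_equal(srt$maps, fix_templates$maps, ignore_attr = TRUE,
               tolerance = 1e-12)
  small <- make_canonical_templates(make_montage(16))
  expect_error(sort_to_normative(small, fix_templates), "mismatch")
})

test_that("backfit labels noise-free data at ground truth, polarity-invariantly", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = Inf,
                            n_epochs = 10, seed = 41)
  ep <- average_reference(sim$epochs)
  seg <- backfit(ep, fix_templates)
  expect_equal(dim(seg$labels), c(250, 10))   # 2500 points = 20 s at 125 Hz
  expect_gte(mean(seg$labels == sim$truth$labels), 0.99)
  neg <- ep
  neg$data <- -neg$data
  expect_identical(backfit(neg, fix_templates)$labels, seg$labels)
})

test_that("backfit handles constant frames by carrying the previous label", {
  sim <- simulate_recording(fix_templates, rep(80, 4), snr = Inf,
                            n_epochs = 1, seed = 9)
  ep <- sim$epochs
  ep$data[, 5, 1] <- 0
  seg <- backfit(ep, fix_templates)
  expect_equal(seg$degenerate_frames, 1L)
  expect_equal(seg$labels[5, 1], seg$labels[4, 1])
  expect_equal(seg$best_corr[5, 1], 0)
})

test_that("backfit on the clustering's own peak maps reproduces the partition", {
  gen <- orthogonal_generators(32)
  set.seed(23)
  truth <- sample(1:4, 60, replace = TRUE)
  maps <- gen[, truth] * rep(runif(60, 5, 15), each = 32)
  tpl <- taahc(maps, gfp(maps), K = 4)
  # centroids are well separated here (oracle generators are orthogonal)
  ctr_r <- abs(cor(tpl$maps))
  diag(ctr_r) <- 0
  expect_lt(max(ctr_r), 0.5)
  ep <- microstatr:::new_epochs(array(maps, c(32, 60, 1)), 125, 60 / 125,
                                fix_montage)
  seg <- backfit(ep, tpl)
  expect_equal(as.integer(seg$labels), attr(tpl, "partition"))
})
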
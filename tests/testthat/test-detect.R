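# Centroid distances, GEV threshold modelling, run extraction, widening
# geometry and channel-group fusion.

test_that("centroid distances match a brute-force computation", {
  feats <- structure(list(vectors = matrix(c(1, 2, -1, -2), 2, byrow = TRUE),
                          starts = c(0, 32), Lw = 155L, d = 32L),
                     class = "uar_features")
  prof <- centroid_distances(feats)
  expect_equal(prof$centroid, c(0, 0))
  expect_equal(prof$distances, rep(sqrt(5), 2))  # rows v and -v
  v <- withr::with_seed(3, matrix(rnorm(40), 5, 8))
  prof2 <- centroid_distances(structure(
    list(vectors = v, starts = 0:4 * 32, Lw = 155L, d = 32L),
    class = "uar_features"))
  ctr <- colMeans(v)
  naive <- sapply(1:5, function(i) sqrt(sum((v[i, ] - ctr)^2)))
  expect_equal(prof2$distances, naive)
  same <- structure(list(vectors = v[c(1, 1), ], starts = c(0, 32),
                         Lw = 155L, d = 32L), class = "uar_features")
  expect_equal(centroid_distances(same)$distances, c(0, 0))
  one <- structure(list(vectors = v[1, , drop = FALSE], starts = 0,
                        Lw = 155L, d = 32L), class = "uar_features")
  expect_error(centroid_distances(one), "at least 2")
})

test_that("GEV fit recovers known parameters and respects equivariance", {
  x <- withr::with_seed(21, rgev(100000, 0.1, 1.0, 0.3))
  g <- fit_gev(x)
  expect_lt(abs(g$shape - 0.1), 0.05)
  expect_lt(abs(g$location - 1.0), 0.05)
  expect_lt(abs(g$scale - 0.3), 0.05)
  g2 <- fit_gev(x + 5)
  expect_lt(abs(g2$location - g$location - 5), 0.02)
  expect_lt(abs(g2$shape - g$shape), 0.02)
  expect_lt(abs(g2$scale - g$scale), 0.02)
  expect_error(fit_gev(rep(1, 100)), "degenerate")
  expect_error(fit_gev(1:10), "at least 50")
  # fitted CDF monotone on the data range
  grid <- seq(min(x), max(x), length.out = 200)
  expect_true(all(diff(pgev(grid, g$shape, g$location, g$scale)) >= 0))
})

test_that("threshold T1 echoes the fixed value or reads a GEV quantile", {
  d <- withr::with_seed(22, rgev(5000, 0.05, 1.0, 0.25))
  expect_equal(threshold_T1(d, "fixed", 1.33), 1.33)
  g <- fit_gev(d)
  expect_equal(threshold_T1(d, "gev_quantile", 0.5),
               qgev(0.5, g$shape, g$location, g$scale), tolerance = 1e-6)
  # closed-form check of the quantile function itself
  expect_equal(pgev(qgev(0.9, 0.1, 1, 0.3), 0.1, 1, 0.3), 0.9)
  expect_error(threshold_T1(d, "gev_quantile", 1.0), "probability")
})

test_that("threshold T2 balances the tail beyond and within [T1, T2)", {
  expect_equal(threshold_T2(c(0.1, 0.4, 2, 3, 4, 5), 2), 3.5)
  expect_equal(threshold_T2(c(2, 3, 4), 2), 3)
  expect_error(threshold_T2(c(0.5, 2), 3), "fewer than 2")
  withr::with_seed(23, for (k in 1:50) {
    d <- rgev(500, 0.1, 1, 0.3)
    T1 <- quantile(d, 0.9)
    T2 <- threshold_T2(d, T1)
    beyond <- sum(d >= T2)
    within <- sum(d >= T1 & d < T2)
    expect_lte(abs(beyond - within), 1)
  })
})

test_that("detect_runs maps runs to window unions and matches a naive scan", {
  prof <- structure(list(distances = c(0.5, 2, 2, 0.5), starts = 0:3 * 32,
                         Lw = 155L, d = 32L), class = "uar_distance_profile")
  sp <- detect_runs(prof, T = 1, min_run = 1)
  expect_equal(spans_df(sp), data.frame(start = 32, end = 219))
  expect_length(detect_runs(prof, T = 3), 0)
  withr::with_seed(24, for (k in 1:25) {
    n <- sample(10:60, 1)
    d <- runif(n)
    min_run <- sample(1:3, 1)
    prof <- structure(list(distances = d, starts = (0:(n - 1)) * 32,
                           Lw = 155L, d = 32L),
                      class = "uar_distance_profile")
    got <- detect_runs(prof, T = 0.5, min_run = min_run)
    want <- naive_runs(d >= 0.5, min_run)
    expect_length(got, length(want))
    for (i in seq_along(want)) {
      expect_equal(got[[i]]$start, (want[[i]][1] - 1) * 32)
      expect_equal(got[[i]]$end, (want[[i]][2] - 1) * 32 + 155)
    }
  })
})

test_that("higher thresholds only shrink detections (monotonicity)", {
  d <- withr::with_seed(25, rgev(200, 0.1, 1, 0.4))
  prof <- structure(list(distances = d, starts = (0:199) * 32,
                         Lw = 155L, d = 32L), class = "uar_distance_profile")
  lo <- detect_runs(prof, T = 1.2)
  hi <- detect_runs(prof, T = 1.8)
  for (h in hi) {
    contained <- any(vapply(lo, function(l)
      h$start >= l$start && h$end <= l$end, logical(1)))
    expect_true(contained)
  }
})

test_that("widening builds the ART/ICA_P/REF geometry with truncation", {
  cfg <- uar_config()
  p <- widen_and_layout(list(span(5000, 6000)), cfg, 256, 20000)
  expect_equal(p[[1]]$art$start, 4744)   # 5000 - 256
  expect_equal(p[[1]]$art$end, 6256)     # 6000 + 256
  expect_equal(p[[1]]$icap$end, 6256)
  expect_equal(p[[1]]$icap$start, 0)     # 26 s window clipped at origin
  expect_equal(p[[1]]$ref$start, 4744 - 1512)
  expect_false(p[[1]]$truncated_at2)

  # a new artefact starting inside AT2 truncates ART and anchors the next AT1
  p2 <- widen_and_layout(list(span(5000, 6000), span(6100, 6500)),
                         cfg, 256, 20000)
  expect_equal(p2[[1]]$art$end, 6100)
  expect_true(p2[[1]]$truncated_at2)
  expect_equal(p2[[2]]$art$start, 6100)  # zero-length AT1
  expect_equal(p2[[2]]$art$end, 6756)

  # AT at the recording start clips AT1
  p3 <- widen_and_layout(list(span(0, 500)), cfg, 256, 20000)
  expect_equal(p3[[1]]$art$start, 0)
  expect_null(p3[[1]]$ref)

  expect_error(widen_and_layout(list(span(100, 300), span(200, 400)),
                                cfg, 256, 20000), "non-overlapping")
})

test_that("widened portions cover their ATs and never overlap", {
  cfg <- uar_config()
  withr::with_seed(26, for (k in 1:20) {
    pos <- sample(0:2000, 1)
    ats <- list()
    for (j in 1:5) {
      len <- sample(100:900, 1)
      ats[[j]] <- span(pos, pos + len)
      pos <- pos + len + sample(10:2000, 1)
    }
    ps <- widen_and_layout(ats, cfg, 256, 60000)
    for (i in seq_along(ps)) {
      expect_true(ps[[i]]$at$start >= ps[[i]]$art$start)
      expect_true(ps[[i]]$at$end <= ps[[i]]$art$end ||
                    ps[[i]]$truncated_at2)
      expect_true(ps[[i]]$art$start >= ps[[i]]$icap$start)
      expect_equal(ps[[i]]$art$end, ps[[i]]$icap$end)
      if (i > 1) expect_gte(ps[[i]]$art$start, ps[[i - 1]]$art$end)
    }
  })
})

test_that("group-wise detection fuses spans and finds focal artefacts", {
  # one group covering all channels behaves like plain detection
  seeg <- build_seeg(small_scenario(seed = 2))
  cfg <- uar_config(icap_seconds = 10)
  det <- uar_detect(seeg$contaminated, cfg)
  fused <- detect_grouped(seeg$contaminated, list(1:16), cfg)
  expect_equal(spans_df(fused), spans_df(merge_spans(det$at_spans)))

  # an artefact confined to channels 13:16 is invisible to the first group
  # but detected by its own group and present in the fused result
  rec <- make_test_recording(16, 256 * 20, seed = 31)
  burst <- gen_emg(1.5, 256, 60, seed = 32)
  sp <- span(2560, 2560 + length(burst))
  for (ch in 13:16) rec$data[ch, span_idx(sp)] <-
    rec$data[ch, span_idx(sp)] + burst
  cfg2 <- uar_config(T = 1.33)
  fused2 <- detect_grouped(rec, list(1:4, 5:8, 9:12, 13:16), cfg2)
  hit <- any(vapply(fused2, function(s) s$start < sp$end && sp$start < s$end,
                    logical(1)))
  expect_true(hit)

  # plain union semantics on overlapping spans
  expect_equal(spans_df(merge_spans(list(span(0, 100), span(50, 150)))),
               data.frame(start = 0, end = 150))
  expect_error(detect_grouped(rec, list(), cfg2), "non-empty")
})
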
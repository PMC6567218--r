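# Variance-equality stopping test, reference selection, the per-electrode
# filtering loop and the whole-recording pipeline.

test_that("variance test matches the F-distribution oracle", {
  x <- withr::with_seed(51, rnorm(101))
  r <- variance_test(x, x)
  expect_equal(r$F, 1)
  expect_equal(r$p, 1)
  expect_false(r$reject)

  # exact sample variances 4 and 1 at n1 = n2 = 101
  scale_to_var <- function(z, v) {
    z <- z - mean(z); z * sqrt(v / var(z))
  }
  withr::with_seed(52, {
    x1 <- scale_to_var(rnorm(101), 4)
    x2 <- scale_to_var(rnorm(101), 1)
  })
  r2 <- variance_test(x1, x2, alpha = 0.01)
  expect_equal(r2$F, 4, tolerance = 1e-12)
  p_oracle <- 2 * min(pf(4, 100, 100), pf(4, 100, 100, lower.tail = FALSE))
  expect_equal(r2$p, p_oracle, tolerance = 1e-12)
  expect_true(r2$reject)

  # two-sided symmetry: swapping the samples cannot change the decision
  r3 <- variance_test(x2, x1, alpha = 0.01)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)
  expect_equal(r3$reject, r2$reject)

  # degenerate conventions
  z <- rep(2, 10)
  expect_true(variance_test(x1, z)$reject)
  expect_equal(variance_test(x1, z)$F, Inf)
  expect_true(variance_test(z, x1)$reject)
  expect_false(variance_test(z, z)$reject)
  expect_error(variance_test(1, x1), "at least 2")
})

test_that("reference selection walks back through clean history", {
  portion <- structure(list(art = span(4744, 6256)), class = "uar_portion")
  mask <- rep(TRUE, 8000)
  r <- select_reference(portion, mask, min_len = 155)
  expect_equal(r$ref$start, 3232)  # 4744 - 1512
  expect_equal(r$ref$end, 4744)
  expect_false(r$short)

  # a previously filtered span counts as clean: same reference
  mask2 <- mask  # spans [3000, 4744) were filtered, already flagged clean
  expect_equal(select_reference(portion, mask2, 155)$ref$start, 3232)

  # dirty patch inside the natural window pushes the reference further back
  mask3 <- mask
  mask3[4001:4100] <- FALSE              # samples 4000..4099 dirty
  r3 <- select_reference(portion, mask3, 155)
  expect_equal(r3$ref$end, 4000)
  expect_equal(r3$ref$start, 4000 - 1512)
  expect_false(r3$short)

  # not enough full-length history: longest clean run ending at ART start
  early <- structure(list(art = span(300, 1812)), class = "uar_portion")
  r4 <- select_reference(early, mask, 155)
  expect_true(r4$short)
  expect_equal(r4$ref$start, 0)
  expect_equal(r4$ref$end, 300)

  # fully contaminated history is a typed condition
  tight <- structure(list(art = span(100, 400)), class = "uar_portion")
  expect_error(select_reference(tight, mask, 155),
               class = "uar_reference_unavailable")
})

test_that("one dominant component stops the loop after one subtraction", {
  fx <- build_filter_fixture("one_component")
  out <- filter_electrode(fx$signal, 1, fx$art, fx$ref, fx$dec, fx$ord,
                          alpha = 0.01)
  expect_equal(out$trace$n_components_subtracted, 1)
  expect_equal(out$trace$stop_reason, "significant_drop")
  expect_equal(out$filtered,
               fx$signal[span_idx(fx$art)] -
                 project_component(fx$dec, 1, 1, fx$art))
})

test_that("a later significant drop rolls back to the R0 plateau", {
  fx <- build_filter_fixture("rollback")
  out <- filter_electrode(fx$signal, 1, fx$art, fx$ref, fx$dec, fx$ord,
                          alpha = 0.01)
  expect_equal(out$trace$stop_reason, "rollback_to_plateau")
  expect_equal(out$trace$n_components_subtracted, 2)
  rejects <- vapply(out$trace$iterations, `[[`, logical(1), "reject")
  expect_false(rejects[2])               # the plateau itself
  expect_true(rejects[3])                # the overshoot that triggered it
  want <- fx$signal[span_idx(fx$art)] -
    project_component(fx$dec, 1, 1, fx$art) -
    project_component(fx$dec, 1, 2, fx$art)
  expect_equal(out$filtered, want)
})

test_that("zero-influence components leave a clean portion unchanged", {
  fx <- build_filter_fixture("noop")
  out <- filter_electrode(fx$signal, 1, fx$art, fx$ref, fx$dec, fx$ord,
                          alpha = 0.01)
  # all-zero projections keep N_ART == ART == REF-like background: every
  # iteration is R0, so the plateau equals the original portion
  expect_equal(out$filtered, fx$signal[span_idx(fx$art)])
  expect_true(out$trace$stop_reason %in%
                c("rollback_to_plateau", "exhausted_unchanged"))
})

test_that("filter_electrode agrees with a literal pseudocode step-through", {
  for (kind in c("one_component", "rollback", "noop")) {
    for (seed in 61:63) {
      fx <- build_filter_fixture(kind, seed)
      got <- filter_electrode(fx$signal, 1, fx$art, fx$ref, fx$dec, fx$ord,
                              alpha = 0.01)
      want <- pseudocode_filter(fx$signal, 1, fx$art, fx$ref, fx$dec, fx$ord,
                                alpha = 0.01)
      expect_equal(got$filtered, want, info = paste(kind, seed))
    }
  }
})

test_that("uar_filter recovers artefacts and preserves everything else", {
  seeg <- build_seeg(small_scenario(seed = 7))
  cfg <- uar_config(icap_seconds = 10, seed = 7)
  res <- uar_filter(seeg$contaminated, cfg)
  filtered <- Filter(function(p) !p$skipped, res$report$portions)
  expect_gt(length(filtered), 0)

  # bit-exact preservation outside every ART span
  mask <- rep(TRUE, n_samples(seeg$contaminated))
  for (p in res$report$portions) mask[span_idx(p$portion$art)] <- FALSE
  expect_identical(res$recording$data[, mask],
                   seeg$contaminated$data[, mask])

  # filtered artefact spans move closer to the clean signal
  for (p in filtered) {
    idx <- span_idx(p$portion$art)
    m_f <- mean(sapply(seq_len(16), function(e)
      mse(res$recording$data[e, idx], seeg$clean$data[e, idx])))
    m_c <- mean(sapply(seq_len(16), function(e)
      mse(seeg$contaminated$data[e, idx], seeg$clean$data[e, idx])))
    expect_lt(m_f, m_c)
  }

  # a second pass either finds nothing or touches only its own new spans
  res2 <- uar_filter(res$recording, cfg)
  mask2 <- rep(TRUE, n_samples(res$recording))
  for (p in res2$report$portions) mask2[span_idx(p$portion$art)] <- FALSE
  expect_identical(res2$recording$data[, mask2], res$recording$data[, mask2])
})

test_that("a quiet recording passes through untouched with an empty report", {
  rec <- gen_background(8, 256, 8, seed = 55)
  cfg <- uar_config(T = 50, icap_seconds = 5)
  res <- uar_filter(rec, cfg)
  expect_identical(res$recording$data, rec$data)
  expect_length(res$report$portions, 0)
})

test_that("artefacts without clean history are skipped with a warning", {
  # EMG burst right at the start: no reference history exists
  rec <- make_test_recording(8, 256 * 10, seed = 56)
  burst <- gen_emg(1, 256, 80, seed = 57)
  idx <- 40 + seq_along(burst)
  for (ch in 1:8) rec$data[ch, idx] <- rec$data[ch, idx] + burst
  cfg <- uar_config(icap_seconds = 5, T = 1.0)
  expect_warning(res <- uar_filter(rec, cfg), "skipping artefact")
  skipped <- Filter(function(p) p$skipped, res$report$portions)
  expect_gt(length(skipped), 0)
  expect_identical(res$recording$data[, idx], rec$data[, idx])
})
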
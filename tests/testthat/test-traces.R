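test_that("baseline normalisation divides by the pre-stimulus mean", {
  # constant raw trace
  tr <- make_trace(rep(7, 30))
  ntr <- normalize_trace(tr)
  expect_equal(ntr$I_basal, 7)
  expect_equal(ntr$intensity, rep(1, 30))
  # flat baseline then a peak of 3x baseline
  tr2 <- make_trace(c(rep(1, 10), 3, rep(1.5, 19)))
  f2 <- trace_features(normalize_trace(tr2))
  expect_equal(f2$amplitude, 3)
  # random baseline: I_basal equals an independently computed mean
  set.seed(3)
  vals <- c(rnorm(10, 50, 4), rnorm(30, 120, 10))
  tr3 <- make_trace(vals)
  expect_equal(normalize_trace(tr3)$I_basal, sum(vals[1:10]) / 10)
})

test_that("normalisation is idempotent and cancels raw-intensity scaling", {
  set.seed(4)
  vals <- c(rnorm(10, 80, 3), 200 * exp(-(0:29) / 10) + 80)
  tr <- make_trace(vals)
  n1 <- normalize_trace(tr)
  n2 <- normalize_trace(n1)
  expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
  # amplitude of a scaled raw trace is unchanged
  tr_scaled <- make_trace(5.5 * vals)
  expect_equal(trace_features(normalize_trace(tr_scaled))$amplitude,
               trace_features(n1)$amplitude, tolerance = 1e-12)
})

test_that("non-positive baselines are flagged as data errors", {
  tr <- make_trace(c(rep(0, 10), rep(5, 20)))
  expect_error(normalize_trace(tr), "non-positive baseline")
  expect_error(trace_features(make_trace(c(rep(2, 10), rep(5, 20)))),
               "not normalized")
})

test_that("50% decay time follows the mid-level geometry", {
  # triangle: rise to 3 at t = 10, fall linearly back to 1 at t = 110;
  # the mid-level 2 is crossed halfway down, 50 s after the peak
  tt <- seq(0, 130, by = 1)
  y <- ifelse(tt < 10, 1 + tt * 0.2, pmax(1, 3 - (tt - 10) * 0.02))
  y[tt < 5] <- 1  # baseline frames
  tr <- intensity_trace("tri", seq_along(tt) - 1, tt, y, stim_frame = 5)
  tr$normalized <- TRUE
  f <- trace_features(tr)
  expect_equal(f$amplitude, 3)
  expect_equal(f$decay50, 50, tolerance = 1e-9)
  # the half-max convention references amplitude/2 instead
  f2 <- trace_features(tr, decay_reference = "half_max")
  expect_equal(f2$decay50, 75, tolerance = 1e-9)  # crossing 1.5, not 2
})

test_that("a trace that never decays has an undefined decay time", {
  y <- c(rep(1, 10), seq(1, 4, length.out = 20))
  f <- trace_features(make_trace(y))
  expect_true(is.na(f$decay50))
  expect_false(f$decay50_defined)
})

test_that("sampled decay time matches a dense-grid oracle on an exponential", {
  A <- 2; tau <- 30
  dt <- 1.23
  tt <- (0:130) * dt
  t0 <- 10 * dt
  y <- ifelse(tt < t0, 1, A * exp(-(tt - t0) / tau) + 1)
  tr <- make_trace(y)
  f <- trace_features(tr)
  oracle <- oracle_decay50_dense(function(s) A * exp(-s / tau) + 1)
  expect_equal(oracle, tau * log(2), tolerance = 1e-3)
  expect_lt(abs(f$decay50 - oracle), dt)
})

test_that("decay time is invariant under appending post-crossing frames", {
  dt <- 1.23
  y <- c(rep(1, 10), 3 * exp(-(0:60) / 20) + 1)
  f1 <- trace_features(make_trace(y))
  f2 <- trace_features(make_trace(c(y, rep(y[length(y)], 40))))
  expect_equal(f1$decay50, f2$decay50, tolerance = 1e-12)
})

test_that("maxima during the baseline window are ignored", {
  y <- c(rep(1, 9), 5, 2, rep(1.2, 20))   # spike on the last baseline frame
  tr <- make_trace(y)
  tr$normalized <- TRUE
  f <- trace_features(tr)
  expect_equal(f$amplitude, 2)
})

test_that("quantile bins split by amplitude rank with deterministic ties", {
  peaks <- c(1, 2, 3, 4)
  traces <- lapply(seq_along(peaks), function(i) {
    tr <- make_trace(c(rep(1, 10), 1 + peaks[i] * exp(-(0:40) / 15)),
                     cell_id = sprintf("c%02d", i))
    tr$normalized <- TRUE
    tr
  })
  avg <- group_average(traces, quantiles = 2, responders_only = FALSE)
  bins <- attr(avg, "bins")
  expect_equal(nrow(bins), 2)
  expect_equal(bins$n_cells, c(2, 2))
  expect_equal(bins$mean_amplitude,
               c(mean(1 + peaks[1:2]), mean(1 + peaks[3:4])))
  # identical traces: every bin average equals the common trace
  same <- lapply(1:4, function(i) {
    tr <- make_trace(c(rep(1, 10), 1 + 2 * exp(-(0:40) / 15)),
                     cell_id = paste0("s", i))
    tr$normalized <- TRUE
    tr
  })
  avg_same <- group_average(same, quantiles = 2, responders_only = FALSE)
  for (b in split(avg_same, avg_same$bin)) {
    expect_equal(b$intensity, same[[1]]$intensity, tolerance = 1e-12)
  }
})

test_that("bin averages equal an independent frame-wise recomputation", {
  set.seed(9)
  n <- 100
  traces <- lapply(seq_len(n), function(i) {
    A <- rlnorm(1, log(1.5), 0.4)
    y <- c(rep(1, 10), 1 + A * exp(-(0:40) / 12)) *
      (1 + rnorm(51, 0, 0.01))
    tr <- make_trace(y, cell_id = sprintf("c%03d", i), group = "target")
    normalize_trace(tr)
  })
  avg <- group_average(traces, quantiles = 4, responders_only = FALSE)
  # brute-force recomputation
  amps <- vapply(traces, function(x) max(x$intensity[11:51]), numeric(1))
  ids <- vapply(traces, function(x) x$cell_id, character(1))
  ord <- order(amps, ids)
  bin_of <- integer(n)
  bin_of[ord] <- ceiling(seq_len(n) * 4 / n)
  for (b in 1:4) {
    mat <- sapply(traces[bin_of == b], function(x) x$intensity)
    expect_equal(avg$intensity[avg$bin == b], rowMeans(mat),
                 tolerance = 1e-12)
  }
})

test_that("too few traces reduce the bin count with a warning", {
  traces <- lapply(1:2, function(i) {
    tr <- make_trace(c(rep(1, 10), 1 + i * exp(-(0:40) / 15)),
                     cell_id = paste0("c", i))
    tr$normalized <- TRUE
    tr
  })
  expect_warning(avg <- group_average(traces, quantiles = 4,
                                      responders_only = FALSE),
                 "reducing bin count")
  expect_equal(max(avg$bin), 2)
})

test_that("Pearson correlation matches its closed-form limits", {
  x <- seq(1, 20)
  r1 <- correlate_features(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- correlate_features(x, -x)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  set.seed(123)
  a <- rnorm(1000); b <- rnorm(1000)
  r3 <- correlate_features(a, b)
  expect_lt(abs(r3$r), 0.1)
  expect_gt(r3$p, 1e-4)
  r4 <- correlate_features(rep(1, 10), rnorm(10))
  expect_false(r4$defined)
  expect_error(correlate_features(1:2, 1:2), "at least 3")
})

test_that("classification labels targets, their contacts, and the rest", {
  # single cell covering the stimulation rectangle
  lay1 <- cell_layout(list(a = rect_polygon(0, 0, 20, 20)),
                      list(rect_polygon(5, 9, 10, 1)))
  expect_equal(unname(classify_cells(lay1)), "target")
  # chain A-B-C with the rectangle inside A only
  lay2 <- cell_layout(list(A = rect_polygon(0, 0, 10, 10),
                           B = rect_polygon(10.2, 0, 10, 10),
                           C = rect_polygon(20.6, 0, 10, 10)),
                      list(rect_polygon(2, 4, 5, 1)))
  expect_equal(classify_cells(lay2),
               c(A = "target", B = "neighbor", C = "other"))
  # empty stimulation region: everything is "other"
  lay3 <- cell_layout(list(a = rect_polygon(0, 0, 5, 5),
                           b = rect_polygon(6, 0, 5, 5)))
  expect_true(all(classify_cells(lay3) == "other"))
})

test_that("classification agrees with a brute-force geometric oracle", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    rects <- lapply(seq_len(n), function(i) {
      x0 <- runif(1, 0, 80); y0 <- runif(1, 0, 80)
      c(x0, y0, x0 + runif(1, 3, 15), y0 + runif(1, 3, 15))
    })
    names(rects) <- paste0("c", seq_len(n))
    sx <- runif(1, 0, 70); sy <- runif(1, 0, 80)
    stim <- c(sx, sy, sx + 30, sy + runif(1, 0.5, 3))
    lay <- cell_layout(lapply(rects, rect_to_poly),
                       list(rect_to_poly(stim)))
    got <- classify_cells(lay)
    want <- oracle_classify_rects(rects, stim)
    expect_equal(got, want)
    # partition: exactly one label per cell
    expect_true(all(got %in% c("target", "neighbor", "other")))
    expect_equal(length(got), n)
  }
})
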
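test_that("layouts are deterministic and match the geometric oracle", {
  cfg <- synth_config(n_cells = 100, seed = 5)
  lay1 <- generate_layout(cfg)
  lay2 <- generate_layout(cfg)
  expect_identical(lay1, lay2)
  # brute-force target count from rectangle interval arithmetic
  rects <- lapply(lay1$cells, function(p) {
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  })
  s <- lay1$stim_regions[[1]]
  stim <- c(min(s[, 1]), min(s[, 2]), max(s[, 1]), max(s[, 2]))
  want <- oracle_classify_rects(rects, stim, eps = lay1$adjacency_eps)
  expect_equal(classify_cells(lay1), want)
  expect_gt(sum(want == "target"), 0)
  expect_gt(sum(want == "neighbor"), 0)
})

test_that("a single cell over the rectangle is the sole target", {
  cfg <- synth_config(n_cells = 1, cell_size = 120, stim_rect = c(80, 1.4),
                      seed = 2)
  lay <- generate_layout(cfg)
  expect_equal(unname(classify_cells(lay)), "target")
})

test_that("noise-free responders round-trip through the trace pipeline", {
  cfg <- synth_config(n_cells = 1, cell_size = 120,
                      responder_prob = c(target = 1, neighbor = 1, other = 0),
                      jtheta_sdlog = 0, noise_mult = 0, noise_add = 0,
                      seed = 8)
  synth <- generate_traces(cfg)
  expect_equal(synth$truth$group, "target")
  f <- trace_features(normalize_trace(synth$traces[[1]]))
  expect_equal(f$amplitude, synth$truth$true_amplitude, tolerance = 1e-9)
  expect_equal(f$decay50, synth$truth$true_decay50, tolerance = 1e-9)
})

test_that("generated populations carry the assumed statistical structure", {
  cfg <- synth_config(n_cells = 200, seed = 31,
                      responder_prob = c(target = 1, neighbor = 1,
                                         other = 0.1))
  synth <- generate_traces(cfg)
  feats <- feature_table(synth$traces)
  resp <- feats[feats$responder & feats$decay50_defined, ]
  # pipeline-recovered amplitudes track the ground truth
  truth <- synth$truth[match(resp$cell_id, synth$truth$cell_id), ]
  expect_lt(mean(abs(resp$amplitude - truth$true_amplitude) /
                   truth$true_amplitude), 0.05)
  # target cells decay slower than neighbors on average (q_ncx > 0)
  dt_t <- resp$decay50[resp$group == "target"]
  dt_n <- resp$decay50[resp$group == "neighbor"]
  expect_gt(length(dt_t), 1)
  expect_gt(length(dt_n), 1)
  expect_gt(mean(dt_t), mean(dt_n))
  # non-responders hover around their baseline
  nonresp <- synth$truth$cell_id[!synth$truth$responder]
  for (id in nonresp[1:5]) {
    ntr <- normalize_trace(synth$traces[[id]])
    expect_lt(max(ntr$intensity),
              1 + 5 * (cfg$noise_mult + cfg$noise_add))
  }
})

test_that("trace generation is byte-identical under a fixed seed", {
  cfg <- synth_config(n_cells = 30, seed = 17)
  s1 <- generate_traces(cfg)
  s2 <- generate_traces(cfg)
  expect_identical(s1$table, s2$table)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace_table(s1$table, f1, seed = cfg$seed)
  write_trace_table(s2$table, f2, seed = cfg$seed)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("particle tracks reproduce the configured displacement statistics", {
  # zero jitter: every record gives the same shear speed
  tr0 <- generate_particle_tracks(n = 20, mean_displacement = 41, jitter = 0)
  expect_true(all(tr0$speed_nm_per_ms == 41 / 27.7))
  trz <- generate_particle_tracks(n = 20, mean_displacement = 0, jitter = 0)
  expect_true(all(trz$speed_nm_per_ms == 0))
  # sample mean within 3 standard errors of the configured mean
  tr <- generate_particle_tracks(n = 1000, mean_displacement = 41,
                                 jitter = 2, seed = 4)
  se <- 2 / sqrt(1000)
  expect_lt(abs(mean(tr$displacement_nm) - 41), 3 * se)
})
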
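fake_traces <- function(V, dt = 0.1, burn_in = 0) {
  # driver appended as the last row; config carries burn_in
  voltages <- rbind(V, -60)
  cfg <- sim_config(n_free = nrow(V), duration = ncol(V) * dt,
                    burn_in = burn_in, dt = dt)
  structure(list(voltages = voltages, dt = dt,
                 clamped_node = nrow(V), config = cfg),
            class = "critnet_traces")
}

test_that("rasterize applies level and onset rules as hand-evaluated", {
  tr <- fake_traces(matrix(c(-65, 5, 10, -65, 5), nrow = 1))
  expect_equal(as.vector(rasterize(tr, 0, "level")$firing),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(as.vector(rasterize(tr, 0, "onset")$firing),
               c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # constant suprathreshold: level all true, onset only the first step
  tc <- fake_traces(matrix(10, 1, 4))
  expect_true(all(rasterize(tc, 0, "level")$firing))
  expect_equal(as.vector(rasterize(tc, 0, "onset")$firing),
               c(TRUE, FALSE, FALSE, FALSE))
  # subthreshold trace: empty raster; driver excluded from rows
  tq <- fake_traces(matrix(-65, 3, 10))
  expect_equal(nrow(rasterize(tq, 0)$firing), 3)
  expect_false(any(rasterize(tq, 0)$firing))
  expect_warning(rasterize(tq, 50), "physiological")
  expect_error(rasterize(tq, 0, "banana"))
})

test_that("rasterize drops the burn-in interval", {
  tr <- fake_traces(matrix(c(10, 10, -65, 10), nrow = 1), dt = 1,
                    burn_in = 2)
  expect_equal(ncol(rasterize(tr, 0)$firing), 2)
  expect_equal(as.vector(rasterize(tr, 0)$firing), c(FALSE, TRUE))
})

test_that("firing histogram counts simultaneity and conserves steps", {
  firing <- matrix(FALSE, 3, 4)
  firing[1, 2] <- TRUE                  # column sums 0,1,3,1
  firing[, 3] <- TRUE
  firing[2, 4] <- TRUE
  h <- firing_histogram(firing)
  expect_equal(h$counts, c(`0` = 1L, `1` = 2L, `2` = 0L, `3` = 1L))
  expect_equal(sum(h$counts), h$n_steps)
  expect_equal(firing_histogram(matrix(FALSE, 5, 100))$counts[["0"]], 100)
  h_full <- firing_histogram(matrix(TRUE, 12, 50))
  expect_equal(h_full$counts[["12"]], 50)
  expect_error(firing_histogram(matrix(FALSE, 0, 0)), "empty")
})

test_that("exponential fit recovers the generating cutoff", {
  h <- law_hist(function(k) exp(-k / 2), kmax = 8)
  f <- fit_exponential(h)
  expect_equal(f$s0, 2, tolerance = 0.025)
  expect_true(length(f$flags) == 0)
  # flat counts: degenerate, s0 -> Inf
  flat <- make_hist(stats::setNames(rep(100, 5), 1:5), 12)
  f2 <- fit_exponential(flat)
  expect_true("degenerate" %in% f2$flags || is.infinite(f2$s0))
  two <- make_hist(stats::setNames(c(10, 5), 1:2), 12)
  expect_error(fit_exponential(two), "insufficient")
})

test_that("power-law fit recovers the generating exponent", {
  for (tau in c(1.5, 2.0)) {
    h <- law_hist(function(k) k^(-tau), kmax = 10)
    expect_equal(fit_power_law(h)$tau, tau, tolerance = 0.05 / tau)
  }
  # model selection sanity: exponential data fit better by the exponential
  h_exp <- law_hist(function(k) exp(-k / 2), kmax = 8)
  expect_gt(fit_power_law(h_exp)$goodness, fit_exponential(h_exp)$goodness)
})

test_that("truncated power-law fit recovers both parameters and flags degeneracies", {
  h <- law_hist(function(k) k^(-1.5) * exp(-k / 20), kmax = 15,
                scale = 1e5)
  f <- fit_truncated_power_law(h)
  expect_equal(f$tau, 1.5, tolerance = 0.1)
  expect_equal(f$s0, 20, tolerance = 0.25 * 20)
  # pure power law: cutoff unidentifiable
  f_pow <- fit_truncated_power_law(law_hist(function(k) k^(-1.5), 15,
                                            scale = 1e5))
  expect_true("cutoff_unidentifiable" %in% f_pow$flags)
  # pure exponential: tau degenerates to ~0
  f_exp <- fit_truncated_power_law(law_hist(function(k) exp(-k / 3), 15,
                                            scale = 1e5))
  expect_equal(f_exp$tau, 0, tolerance = 0.2)
})

test_that("estimated s0 tracks the generating cutoff ordering", {
  est <- sapply(c(5, 20, 80), function(s0)
    fit_truncated_power_law(law_hist(function(k) k^(-1.5) * exp(-k / s0),
                                     kmax = 30, scale = 1e6))$s0)
  expect_true(all(diff(est) > 0))
})

test_that("mean cluster size matches hand arithmetic and monotonicity", {
  expect_equal(mean_cluster_size(make_hist(c(`1` = 4, `2` = 1), 12)), 8 / 6)
  expect_equal(mean_cluster_size(make_hist(c(`1` = 7), 12)), 1)
  expect_equal(mean_cluster_size(make_hist(c(`2` = 5), 12)), 2)
  expect_warning(S <- mean_cluster_size(make_hist(c(`0` = 10), 12)))
  expect_true(is.na(S))
  # moving mass from small to large k increases S
  expect_gt(mean_cluster_size(make_hist(c(`1` = 5, `8` = 5), 12)),
            mean_cluster_size(make_hist(c(`1` = 6, `8` = 4), 12)))
})

test_that("phase classification follows the decision rule", {
  expect_equal(classify_phase(make_hist(c(`0` = 1e5), 12))$label, "silent")
  ict <- make_hist(c(`0` = 9000, `12` = 900, `1` = 100), 12)
  expect_equal(classify_phase(ict)$label, "ictal")
  pow <- law_hist(function(k) k^(-1.5), kmax = 12, scale = 1e4,
                  n_silent = 9e4)
  expect_equal(classify_phase(pow)$label, "power")
  expb <- law_hist(function(k) exp(-k / 2), kmax = 12, scale = 1e4,
                   n_silent = 9e4)
  expect_equal(classify_phase(expb)$label, "exponential")
})

test_that("classification is invariant to uniform count scaling", {
  h1 <- law_hist(function(k) k^(-1.5), kmax = 12, scale = 1e4,
                 n_silent = 9e4)
  h10 <- law_hist(function(k) k^(-1.5), kmax = 12, scale = 1e5,
                  n_silent = 9e5)
  expect_equal(classify_phase(h1)$label, classify_phase(h10)$label)
  expect_equal(classify_phase(h1)$activity_fraction,
               classify_phase(h10)$activity_fraction, tolerance = 1e-3)
})

test_that("synthesized rasters close the loop with the fitters", {
  # generator -> histogram -> fitter recovers the generating parameters
  r_pow <- synthesize_raster("power", list(tau = 1.5), 12, 2e5, seed = 11)
  h_pow <- firing_histogram(r_pow)
  expect_equal(fit_power_law(h_pow)$tau, 1.5, tolerance = 0.1)
  r_exp <- synthesize_raster("exponential", list(s0 = 2), 12, 2e5,
                             seed = 12)
  expect_equal(fit_exponential(firing_histogram(r_exp))$s0, 2,
               tolerance = 0.2)
  expect_false(any(synthesize_raster("silent", list(), 12, 100, 1)$firing))
  r_ict <- synthesize_raster("ictal", list(sync_prob = 0.9), 12, 5e4,
                             seed = 13)
  expect_equal(classify_phase(firing_histogram(r_ict))$label, "ictal")
  expect_equal(classify_phase(firing_histogram(r_pow))$label, "power")
  expect_equal(classify_phase(firing_histogram(r_exp))$label, "exponential")
  expect_error(synthesize_raster("power", list(), 12, 10, 1), "tau")
  expect_error(synthesize_raster("ictal", list(sync_prob = 2), 12, 10, 1),
               "sync_prob")
})

test_that("raster CSV roundtrips", {
  r <- synthesize_raster("power", list(tau = 1.5), 6, 500, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(r, path)
  back <- read_raster(path)
  expect_identical(back$firing, r$firing)
  expect_equal(back$mode, "power")
})
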
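test_that("an empty config file yields the documented defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  cfg <- load_config(path)
  expect_equal(cfg$dt, 0.1)
  expect_equal(cfg$V0, -64)
  expect_equal(cfg$hh$g_Na, 20)
  expect_equal(cfg$hh$g_K, 12)
  expect_equal(cfg$hh$g_leak, 0.05)
  expect_equal(cfg$hh$V_Na, 50)
  expect_equal(cfg$hh$V_K, -90)
  expect_equal(cfg$hh$V_leak, -60)
  expect_equal(cfg$n_free, 12)
})

test_that("config validation names the offending field", {
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("dt: -1", bad)
  expect_error(load_config(bad), "dt")
  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("frobnicate: 3", unk)
  expect_error(load_config(unk), "frobnicate")
  short <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("duration: 100", "burn_in: 200"), short)
  expect_error(load_config(short), "burn_in")
})

test_that("configs roundtrip through YAML", {
  cfg <- sim_config(g_max = 77, stickiness = 1.07, noise_seed = 42,
                    duration = 1234)
  cfg$profile <- "classic"
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- load_config(path)
  expect_equal(back, cfg)
})

test_that("the textbook profile selects canonical squid-axon constants", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("profile: textbook", path)
  cfg <- load_config(path)
  expect_equal(cfg$hh$g_Na, 120)
  expect_equal(cfg$hh$V_K, -77)
})

test_that("a decoupled quiet run is classified silent end to end", {
  cfg <- sim_config(g_max = 0, noise_sd = 0, duration = 1200,
                    burn_in = 200)
  rep <- run_experiment(cfg, scalogram = FALSE)
  expect_equal(rep$phase$label, "silent")
  expect_true(is.na(rep$mean_cluster_size))
})

test_that("experiment reports are reproducible from config seeds", {
  cfg <- quick_config(g_max = 120, duration = 2500)
  r1 <- run_experiment(cfg, scalogram = FALSE)
  r2 <- run_experiment(cfg, scalogram = FALSE)
  expect_identical(r1$phase$label, r2$phase$label)
  expect_identical(r1$psd_slope, r2$psd_slope)
  expect_identical(r1$histogram$counts, r2$histogram$counts)
})

test_that("an injected synthetic raster bypasses simulation", {
  r <- synthesize_raster("power", list(tau = 1.5), 12, 2e5, seed = 7)
  rep <- run_experiment(sim_config(), raster = r)
  expect_equal(rep$phase$label, "power")
  expect_true(is.na(rep$psd_slope))
})

test_that("run_experiment writes the full artifact set", {
  dir <- withr::local_tempdir()
  cfg <- quick_config(g_max = 120, duration = 2100)
  rep <- run_experiment(cfg, output_dir = dir)
  for (f in c("traces.csv", "eeg.csv", "eeg.edf", "raster.csv",
              "histogram.csv", "psd.csv", "scalogram.csv", "report.json"))
    expect_true(file.exists(file.path(dir, f)), label = f)
  doc <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(doc$phase$label, rep$phase$label)
  expect_equal(doc$config$g_max, 120)
  # histogram CSV conserves steps
  h <- read.csv(file.path(dir, "histogram.csv"))
  expect_equal(sum(h$steps), rep$histogram$n_steps)
})

test_that("CSV trace export roundtrips to printed precision", {
  cfg <- quick_config(n_free = 2, k = 2, g_max = 50, duration = 700)
  tr <- run_network(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  export_traces(tr, "csv", path)
  back <- read.csv(path)
  expect_equal(ncol(back), 4)  # time + 3 nodes
  expect_equal(back$node_0, tr$voltages[1, ], tolerance = 1e-8)
  expect_equal(back$time_ms[2] - back$time_ms[1], cfg$dt)
})

test_that("EDF export reports the correct rate, count and survives constants", {
  eeg <- structure(list(values = sin(seq_len(20000) / 50), dt = 0.1),
                   class = "critnet_eeg")
  path <- withr::local_tempfile(fileext = ".edf")
  export_traces(eeg, "edf", path)
  hdr <- read_edf_header(path)
  expect_equal(hdr$n_signals, 1)
  expect_equal(hdr$sampling_rate, 10000)
  expect_equal(hdr$n_samples, 20000)
  expect_equal(hdr$labels, "eeg")
  # constant signal: physical range widened, file still valid
  flat <- structure(list(values = rep(-64, 15000), dt = 0.1),
                    class = "critnet_eeg")
  export_traces(flat, "edf", path)
  hdr2 <- read_edf_header(path)
  expect_gt(hdr2$phys_max - hdr2$phys_min, 0)
  # expected size: header + records * samples * 2 bytes
  expect_equal(file.info(path)$size,
               256 * 2 + hdr2$n_records * hdr2$sampling_rate * 2)
})

test_that("sweeps summarize phases and locate the cluster-size argmax", {
  base <- quick_config(g_max = 120, duration = 2100)
  sw <- run_sweep(base, "stickiness", c(0.95, 1.05))
  expect_equal(nrow(sw$summary), 2)
  expect_true(sw$argmax_value %in% c(0.95, 1.05))
  expect_true(all(c("value", "label", "mean_cluster_size", "psd_slope")
                  %in% names(sw$summary)))
  # singleton sweep: argmax is that value
  one <- run_sweep(base, "stickiness", 1.0)
  expect_equal(one$argmax_value, 1.0)
  # all-silent sweep: argmax undefined
  silent_base <- sim_config(g_max = 0, noise_sd = 0, duration = 1200,
                            burn_in = 200)
  sw0 <- suppressWarnings(run_sweep(silent_base, "g_max", c(0, 0)))
  expect_true(all(sw0$summary$label == "silent"))
  expect_true(is.na(sw0$argmax_value))
})

test_that("the command-line entry point drives fixture and analyze paths", {
  script <- file.path(system.file(package = "critnet"), "exec", "critnet.R")
  expect_true(file.exists(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  raster_path <- file.path(dir, "r.csv")
  out <- system2(rscript, c(script, "fixture", "--law", "power", "--tau",
                            "1.5", "--neurons", "12", "--steps", "20000",
                            "--seed", "7", "--out", raster_path),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(raster_path))
  out2 <- system2(rscript, c(script, "analyze", "--raster", raster_path,
                             "--out", dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "report.json")))
  doc <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(doc$phase$label, "power")
})
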
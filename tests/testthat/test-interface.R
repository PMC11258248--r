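test_that("trajectory XYZ + sidecar round-trips", {
  m <- model_carotenoid()
  o <- propagate_trajectory(list(coords = c(0.08, 0.1),
                                 velocities = c(0.002, 0.001), state = 3),
                            m, sh_settings(total_time = 20, seed = 13,
                                           record_stride = 10))
  xyz <- tempfile(fileext = ".xyz")
  csv <- tempfile(fileext = ".csv")
  write_trajectory(o$record, xyz, csv)
  r <- read_trajectory(xyz, csv)
  expect_equal(r$time, o$record$time, tolerance = 1e-9)
  expect_equal(r$coords, o$record$coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(r$energies), unname(o$record$energies),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(Mod(r$coeffs), Mod(o$record$coeffs), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$active, o$record$active)
  expect_equal(r$metadata$model, o$record$metadata$model)
})

test_that("frame-count mismatch between XYZ and sidecar is a parse error", {
  m <- model_harmonic(k = 2)
  o <- propagate_trajectory(list(coords = 0.2, velocities = 0, state = 1),
                            m, sh_settings(total_time = 10, seed = 1,
                                           record_stride = 10))
  xyz <- tempfile(fileext = ".xyz")
  csv <- tempfile(fileext = ".csv")
  write_trajectory(o$record, xyz, csv)
  lines <- readLines(csv)
  writeLines(lines[-length(lines)], csv)  # drop one sidecar row
  expect_error(read_trajectory(xyz, csv), "mismatch")
})

test_that("a hand-written 3-frame fixture parses field by field", {
  xyz <- tempfile(fileext = ".xyz")
  csv <- tempfile(fileext = ".csv")
  writeLines(c("1", "t= 0.000000", "X 0.1 0 0",
               "1", "t= 1.000000", "X 0.2 0 0",
               "1", "t= 2.000000", "X 0.25 0 0"), xyz)
  writeLines(c("# carotdyn-sidecar/1 model=demo seed=7",
               "frame,time_fs,active,E0,E1,c0_mag,c0_phase,c1_mag,c1_phase,mu0,mu1,v1",
               "1,0,2,0.0,2.0,0,0,1,0,0.1,0,0.01",
               "2,1,2,0.1,1.9,0.1,0,0.99498743710662,0,0.1,0,0.011",
               "3,2,1,0.2,1.8,1,0,0,0,0.1,0,0.012"), csv)
  r <- read_trajectory(xyz, csv)
  expect_equal(r$time, c(0, 1, 2))
  expect_equal(drop(r$coords), c(0.1, 0.2, 0.25))
  expect_equal(r$active, c(2L, 2L, 1L))
  expect_equal(r$energies[2, ], c(E0 = 0.1, E1 = 1.9), ignore_attr = TRUE)
  expect_equal(Mod(r$coeffs[2, ]), c(0.1, 0.99498743710662))
  expect_equal(r$metadata$model, "demo")
  expect_equal(r$metadata$seed, 7L)
})

test_that("malformed XYZ reports the offending line", {
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t= 0", "X 0 0 0", "X 1 0"), bad)
  expect_error(read_xyz(bad), "line 4")
  bad2 <- tempfile(fileext = ".xyz")
  writeLines(c("not-a-count", "t= 0"), bad2)
  expect_error(read_xyz(bad2), "line 1")
})

test_that("cli: generate then report runs end to end deterministically", {
  dir1 <- file.path(tempdir(), "cli-gen1")
  dir2 <- file.path(tempdir(), "cli-gen2")
  expect_equal(run_cli(c("generate", "--out", dir1, "--seed", "4")), 0L)
  expect_equal(run_cli(c("generate", "--out", dir2, "--seed", "4")), 0L)
  t1 <- read.csv(file.path(dir1, "trajectories.csv"))
  t2 <- read.csv(file.path(dir2, "trajectories.csv"))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 782L)
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))
  out <- capture.output(status <- run_cli(c("report", "--input", dir1)))
  expect_equal(status, 0L)
  expect_true(any(grepl("tau1_avg", out)))
})

test_that("cli: fit-populations recovers the generator parameters", {
  dir <- file.path(tempdir(), "cli-fit-src")
  run_cli(c("generate", "--out", dir, "--seed", "10"))
  fitdir <- file.path(tempdir(), "cli-fit-out")
  expect_equal(run_cli(c("fit-populations", "--input",
                         file.path(dir, "trajectories.csv"),
                         "--out", fitdir, "--grid-fs", "25")), 0L)
  rep <- yaml::read_yaml(file.path(fitdir, "fit_report.yaml"))
  # set A generated at tau1_avg = 17.14 ps; finite-ensemble fit nearby
  expect_lt(abs(rep$A$tau1_avg_ps - 17.1) / 17.1, 0.4)
  expect_lt(abs(rep$B$tau1_avg_ps - 13.1) / 13.1, 0.4)
})

test_that("cli: simulate writes a regenerable trajectory", {
  model_path <- system.file("extdata", "carotenoid_model.yaml",
                            package = "carotdyn")
  d1 <- file.path(tempdir(), "cli-sim1")
  d2 <- file.path(tempdir(), "cli-sim2")
  expect_equal(run_cli(c("simulate", "--model", model_path, "--out", d1,
                         "--seed", "3", "--total-fs", "20")), 0L)
  expect_equal(run_cli(c("simulate", "--model", model_path, "--out", d2,
                         "--seed", "3", "--total-fs", "20")), 0L)
  expect_identical(readLines(file.path(d1, "trajectory.csv")),
                   readLines(file.path(d2, "trajectory.csv")))
})

test_that("cli: usage errors exit with status 2", {
  out1 <- capture.output(s <- run_cli(c("frobnicate")))
  expect_equal(s, 2L)
  out <- capture.output(s2 <- run_cli(c("generate", "--bogus", "1")))
  expect_equal(s2, 2L)
  out3 <- capture.output(s3 <- run_cli(character(0)))
  expect_equal(s3, 2L)
  expect_true(any(grepl("usage", out3)))
})
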
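test_that("generated test surfaces hit the requested minima count", {
  pes <- generate_test_pes(1, seed = 21, minima_range = c(2, 2))
  # independent 1-degree scan of the returned surface
  g <- seq(-180, 179, by = 1)
  E <- vapply(g, function(d) calc_energy(pes, d), numeric(1))
  n <- length(E)
  is_min <- E < E[c(n, 1:(n - 1))] & E < E[c(2:n, 1)]
  expect_equal(sum(is_min), 2)
  # determinism: the same seed reproduces the same coefficients
  pes2 <- generate_test_pes(1, seed = 21, minima_range = c(2, 2))
  expect_identical(pes$amplitudes, pes2$amplitudes)
  expect_identical(pes$phases, pes2$phases)
})

test_that("analytic surfaces are 360-degree periodic with exact gradients", {
  pes <- generate_test_pes(2, seed = 22, minima_range = c(2, 9))
  set.seed(23)
  for (i in 1:5) {
    t <- runif(2, -180, 180)
    shift <- t + 360 * c(1, -2)
    expect_equal(calc_energy(pes, t), calc_energy(pes, shift),
                 tolerance = 1e-12)
    g <- pes_gradient(pes, t)
    h <- 1e-4
    for (j in 1:2) {
      tp <- t; tp[j] <- tp[j] + h
      tm <- t; tm[j] <- tm[j] - h
      fd <- (calc_energy(pes, tp) - calc_energy(pes, tm)) / (2 * h)
      expect_equal(g[j], fd, tolerance = 1e-6)
    }
  }
})

test_that("an unachievable minima range fails after the draw budget", {
  expect_error(generate_test_pes(1, seed = 1, minima_range = c(50, 60),
                                 max_draws = 5), "could not generate")
})

test_that("the grid mapper evaluates exactly n^dims points", {
  pes1 <- cysteine_d1_profile()
  m1 <- grid_reference_map(pes1, n = 5, dihedrals = 1)
  expect_equal(m1$n_evaluations, 5L)
  expect_length(m1$energies, 5)
  # grid values equal direct calculator calls, shifted to the grid minimum
  direct <- vapply(m1$axes[[1]], function(d) calc_energy(pes1, d), numeric(1))
  expect_equal(m1$energies, direct - min(direct), tolerance = 1e-12)
  expect_true(all(m1$energies >= 0))
  # grid points follow the -180 + 360 i/n convention, endpoint not doubled
  expect_equal(m1$axes[[1]], -180 + 360 * (0:4) / 5)
})

test_that("map failures are recorded as missing without changing the count", {
  flaky <- structure(list(dim = 1), class = c("hole_calc", "torsion_calculator"))
  registerS3method("calc_energy", "hole_calc",
                   function(calc, x, ...) if (x > 0) NaN else cos(x * pi / 180),
                   envir = asNamespace("torsionbo"))
  m <- grid_reference_map(flaky, n = 10, dihedrals = 1)
  expect_equal(m$n_evaluations, 10L)
  expect_gt(m$n_failed, 0)
  expect_true(any(is.na(m$energies)))
})

test_that("the contrast transform applies only to valid relative energies", {
  expect_equal(map_contrast(c(0, 1, 16)), c(0, 1, 8))
  expect_error(map_contrast(-0.1), ">= 0")
})

test_that("PES fixtures survive a JSON round trip", {
  pes <- generate_test_pes(2, seed = 24, minima_range = c(2, 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_pes_json(pes, path)
  back <- read_pes_json(path)
  set.seed(25)
  for (i in 1:5) {
    t <- runif(2, -180, 180)
    expect_equal(calc_energy(back, t), calc_energy(pes, t), tolerance = 1e-12)
  }
})

test_that("the mm force field reduces to its torsion profile on rigid scans", {
  hooh <- mk_hooh()
  amp <- c(0.05, 0.10, 0.002)
  for (t in c(-150, -60, 0, 77, 160)) {
    g <- set_torsions(hooh$model, t)
    th <- t * pi / 180
    expect_equal(calc_energy(hooh$calc, g), sum(amp * cos((1:3) * th)),
                 tolerance = 1e-9)
  }
  # determinism on repeated evaluation of identical coordinates
  g <- set_torsions(hooh$model, 42)
  expect_identical(calc_energy(hooh$calc, g), calc_energy(hooh$calc, g))
})

test_that("the file-exchange bridge round-trips energies and forces", {
  wd <- withr::local_tempdir()
  calc <- file_exchange_calculator(wd, elements = c("O", "H"), timeout = 5)
  # scripted responder: answer the first two requests before they are made
  e_ref <- -1.23456789
  f_ref <- rbind(c(0.1, 0, -0.2), c(-0.1, 0, 0.2))
  jsonlite::write_json(list(energy = e_ref),
                       file.path(wd, "eval_000001_result.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(energy = e_ref, forces = f_ref),
                       file.path(wd, "eval_000002_result.json"),
                       auto_unbox = TRUE, digits = NA)
  co <- rbind(c(0, 0, 0), c(0.97, 0, 0))
  expect_equal(calc_energy(calc, co), e_ref, tolerance = 1e-10)
  expect_equal(calc_forces(calc, co), f_ref, tolerance = 1e-10)
  # the request files document the exchanged geometry
  expect_true(file.exists(file.path(wd, "eval_000001.xyz")))
  req <- jsonlite::read_json(file.path(wd, "eval_000002_request.json"))
  expect_equal(req$want, "energy+forces")
})

test_that("missing force blocks and timeouts are contract violations", {
  wd <- withr::local_tempdir()
  calc <- file_exchange_calculator(wd, elements = "H", timeout = 0.2,
                                   poll = 0.01)
  jsonlite::write_json(list(energy = 1.0),
                       file.path(wd, "eval_000001_result.json"),
                       auto_unbox = TRUE)
  expect_error(calc_forces(calc, rbind(c(0, 0, 0))), "forces")
  # no responder: times out
  expect_error(calc_energy(calc, rbind(c(0, 0, 0))), "timeout")
})
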
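test_that("relaxation honours the force threshold contract", {
  calc <- harmonic_well_calculator(rbind(c(1, 2, 3)), k = 2)
  # already converged input returns unchanged in zero steps
  r0 <- relax_structure(calc, rbind(c(1, 2, 3 + 1e-4)))
  expect_equal(r0$steps, 0L)
  expect_equal(r0$coords, rbind(c(1, 2, 3 + 1e-4)))
  # displaced start relaxes to the closed-form minimum
  r <- relax_structure(calc, rbind(c(1.6, 2.4, 2.1)), fmax = 1e-5)
  expect_lt(max(abs(r$coords - c(1, 2, 3))), 1e-4)
  expect_lt(r$energy, calc_energy(calc, rbind(c(1.6, 2.4, 2.1))) + 1e-8)
})

test_that("a non-finite calculator energy aborts the relaxation", {
  bad <- structure(list(), class = c("nan_calc", "cartesian_calculator"))
  registerS3method("calc_energy", "nan_calc", function(calc, x, ...) NaN,
                   envir = asNamespace("torsionbo"))
  expect_error(relax_structure(bad, rbind(c(0, 0, 0))), "non-finite")
})

test_that("the finite-difference Hessian of a quadratic well is exact", {
  k <- 3.7; m <- 12.011
  calc <- harmonic_well_calculator(rbind(c(0, 0, 0)), k = k)
  H <- hessian_finite_difference(calc, rbind(c(0, 0, 0)), m)
  expect_equal(H, t(H))
  # all three eigenvalues equal k/m (mass-weighted)
  expect_equal(eigen(H, symmetric = TRUE)$values, rep(k / m, 3),
               tolerance = 1e-6)
})

test_that("a harmonic diatomic gives the reduced-mass frequency", {
  k <- 25; m1 <- 1.008; m2 <- 18.998403
  calc <- spring_calculator(rbind(c(1, 2)), k, 1.0)
  co <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  H <- hessian_finite_difference(calc, co, c(m1, m2))
  nm <- normal_modes(H, co, c(m1, m2))
  expect_equal(length(nm$hbar_omega), 1L)  # 3*2 - 5 for a linear molecule
  expect_equal(nm$n_zero, 5L)
  expected <- tbo_constants$hbar_omega_factor * sqrt(k * (1 / m1 + 1 / m2))
  expect_equal(nm$hbar_omega, expected, tolerance = 1e-6)
  expect_equal(nm$n_imaginary, 0L)
})

test_that("halving the displacement barely moves a quadratic's frequencies", {
  k <- 25; m1 <- 1.008; m2 <- 18.998403
  calc <- spring_calculator(rbind(c(1, 2)), k, 1.0)
  co <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  w1 <- normal_modes(hessian_finite_difference(calc, co, c(m1, m2),
                                               delta = 0.0025),
                     co, c(m1, m2))$hbar_omega
  w2 <- normal_modes(hessian_finite_difference(calc, co, c(m1, m2),
                                               delta = 0.00125),
                     co, c(m1, m2))$hbar_omega
  expect_lt(abs(w1 - w2) / w1, 1e-5)
})

test_that("mode counting follows 3N-6 (3N-5 linear, 0 for an atom)", {
  # free atom: no internal modes
  calcA <- harmonic_well_calculator(rbind(c(0, 0, 0)), k = 0)
  HA <- hessian_finite_difference(calcA, rbind(c(0, 0, 0)), 12)
  expect_length(normal_modes(HA, rbind(c(0, 0, 0)), 12)$hbar_omega, 0)
  # bent triatomic held by three springs: 3*3 - 6 = 3 modes
  wat <- spring_calculator(rbind(c(1, 2), c(1, 3), c(2, 3)),
                           c(30, 30, 5), c(0.96, 0.96, 1.52))
  cw <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  rr <- relax_structure(wat, cw, fmax = 1e-5)
  m3 <- c(15.999, 1.008, 1.008)
  nm <- normal_modes(hessian_finite_difference(wat, rr$coords, m3),
                     rr$coords, m3)
  expect_length(nm$hbar_omega, 3)
  expect_false(nm$suspicious)
})

test_that("the harmonic free energy matches its closed form", {
  expect_equal(vibrational_free_energy(0.1, 0), 0.05)
  kT <- tbo_constants$kB * 300
  expect_equal(vibrational_free_energy(0.1, 300),
               0.05 + kT * log(1 - exp(-0.1 / kT)), tolerance = 1e-12)
  # additivity over modes
  expect_equal(vibrational_free_energy(c(0.1, 0.23), 350),
               vibrational_free_energy(0.1, 350) +
                 vibrational_free_energy(0.23, 350), tolerance = 1e-12)
  # strictly decreasing in temperature; F(0) = ZPE
  modes <- c(0.05, 0.11, 0.4)
  Ts <- c(0, 50, 150, 300, 600, 1200)
  Fv <- vapply(Ts, function(T) vibrational_free_energy(modes, T), numeric(1))
  expect_true(all(diff(Fv) < 0))
  expect_equal(Fv[1], zero_point_energy(modes))
  expect_gt(zero_point_energy(modes), 0)
  expect_error(vibrational_free_energy(c(0.1, -0.2), 300), "non-positive")
})

test_that("high-level deltas reorder only when they should", {
  rec <- data.frame(label = c("a", "b"), E_opt = c(0.00, 0.02),
                    zpe = c(0.1, 0.1), f_vib = c(0.09, 0.09))
  # identity deltas preserve the +VE(300 K) ordering
  hl0 <- data.frame(label = c("a", "b"), energy = rec$E_opt)
  h0 <- assemble_hierarchy(apply_singlepoint_delta(rec, hl0))
  expect_equal(h0$table$rank_cc, h0$table$rank_ve300)
  # a uniform delta leaves relative energies unchanged
  hlc <- data.frame(label = c("a", "b"), energy = rec$E_opt + 0.3)
  hc <- assemble_hierarchy(apply_singlepoint_delta(rec, hlc))
  expect_equal(hc$table$rel_cc, h0$table$rel_cc)
  # deltas of -0.05 and 0 applied across a 0.02 eV gap swap the order
  hls <- data.frame(label = c("a", "b"), energy = c(0.0, 0.02 - 0.05))
  hs <- assemble_hierarchy(apply_singlepoint_delta(rec, hls))
  expect_equal(hs$table$rank_cc[hs$table$label == "b"], 1L)
  # unmatched labels are reported
  expect_error(
    apply_singlepoint_delta(rec, data.frame(label = "zz", energy = 1)),
    "zz")
})

test_that("hierarchy assembly is shift-invariant and order-independent", {
  set.seed(15)
  rec <- data.frame(label = sprintf("c%02d", 1:6),
                    E_opt = c(-3.2, -3.15, -3.28, -3.05, -3.3, -3.21),
                    E_surrogate = c(-3.18, -3.12, -3.25, -3.0, -3.27, -3.2),
                    zpe = runif(6, 0.4, 0.5))
  rec$f_vib <- rec$zpe - runif(6, 0.001, 0.01)
  h <- assemble_hierarchy(rec)
  # exactly one zero per stage, all relative energies non-negative
  for (st in h$stages) {
    rel <- h$table[[paste0("rel_", st)]]
    expect_equal(sum(rel == 0), 1)
    expect_true(all(rel >= 0))
  }
  # a global shift of E_opt changes no relative energy
  rec2 <- rec; rec2$E_opt <- rec2$E_opt + 11.1
  h2 <- assemble_hierarchy(rec2)
  for (st in c("opt", "ve0", "ve300"))
    expect_equal(h2$table[[paste0("rel_", st)]],
                 h$table[[paste0("rel_", st)]], tolerance = 1e-12)
  # input row order does not matter
  h3 <- assemble_hierarchy(rec[sample(1:6), ])
  expect_equal(h3$table, h$table)
  # with zero corrections every stage ranks like E_opt
  rec4 <- rec; rec4$zpe <- 0.2; rec4$f_vib <- 0.2
  h4 <- assemble_hierarchy(rec4)
  expect_equal(h4$table$rank_ve0, h4$table$rank_opt)
  expect_equal(h4$table$rank_ve300, h4$table$rank_opt)
  # singleton record: zero at every stage
  h1 <- assemble_hierarchy(rec[1, ])
  for (st in h1$stages) expect_equal(h1$table[[paste0("rel_", st)]], 0)
})

test_that("torsion-space relaxation lands on the true PES minimum", {
  pes <- cysteine_d1_profile()
  gm <- grid_argmin_1d(function(d) calc_energy(pes, d), step = 0.1)
  r <- relax_torsions(pes, gm + 20)
  expect_lt(periodic_distance(r$torsions, gm), 0.2)
})
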
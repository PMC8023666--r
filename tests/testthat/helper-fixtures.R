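# Fixtures are built in code at test time.

# Four-atom chain whose a-b-c-d dihedral is phi_deg by construction: the
# far atom is rotated about the central-bond (x) axis from the cis
# reference by an explicit axis-angle rotation.
mk_chain <- function(phi_deg) {
  a <- c(-0.5, 1.0, 0)
  b <- c(0, 0, 0)
  cc <- c(1.5, 0, 0)
  th <- phi_deg * pi / 180
  d <- cc + c(0.5, cos(th), sin(th))
  rbind(a, b, cc, d)
}

# Pentane-like heavy-atom chain with two searchable dihedrals.
mk_pentane <- function() {
  co <- rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.05, 1.45, 0),
              c(3.59, 1.45, 0.1), c(4.1, 2.9, 0.2))
  molecule_model(rep("C", 5), co,
                 dihedrals = list(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

# Hydrogen peroxide bound to the package's molecular-mechanics backend;
# one searchable torsion with a two-well profile.
mk_hooh <- function(amplitudes = c(0.05, 0.10, 0.002)) {
  O1 <- c(0, 0, 0); O2 <- c(1.45, 0, 0)
  H1 <- O1 + c(-0.33, 0.91, 0)
  th <- 111 * pi / 180
  H2 <- O2 + c(0.33, 0.91 * cos(th), 0.91 * sin(th))
  model <- molecule_model(c("H", "O", "O", "H"), rbind(H1, O1, O2, H2),
                          dihedrals = list(c(1, 2, 3, 4)))
  calc <- mm_calculator(model, matrix(amplitudes, 1, 3), matrix(0, 1, 3))
  list(model = model, calc = calc)
}

# Fit a GP to f sampled on a regular 1D grid over the circle.
fit_1d_gp <- function(f, n = 13, noise_var = 1e-8, optimize = TRUE) {
  x <- seq(-180, 180, length.out = n + 1)[seq_len(n)]
  gp_fit(matrix(x, ncol = 1), vapply(x, f, numeric(1)),
         noise_var = noise_var, optimize = optimize)
}

# Brute-force argmin of a scalar function of one angle.
grid_argmin_1d <- function(f, step = 0.1) {
  g <- seq(-180, 180 - step, by = step)
  g[which.min(vapply(g, f, numeric(1)))]
}
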
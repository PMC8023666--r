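# Refinement of conformer candidates: full-coordinate relaxation,
# finite-difference harmonic vibrational analysis, free-energy
# corrections, optional high-level single-point deltas, and assembly of
# the staged energy hierarchy.

max_force_norm <- function(forces) max(sqrt(rowSums(forces^2)))

#' Relax a structure to a force threshold
#'
#' Quasi-Newton (L-BFGS) minimization of the calculator energy over all
#' Cartesian degrees of freedom; convergence when the maximum per-atom
#' force norm drops below `fmax`. An input already below the threshold is
#' returned unchanged in zero steps.
#'
#' @param calc Cartesian calculator providing energy and forces.
#' @param coords n x 3 starting coordinates (Angstrom).
#' @param fmax Convergence threshold on the residual force, eV/Angstrom
#'   (default 0.01).
#' @param maxsteps Step limit (default 500); exceeding it raises a
#'   condition of class `tbo_nonconvergence` carrying the last geometry.
#' @return List with `coords`, `energy` (eV), `fmax` (residual), `steps`.
#' @export
relax_structure <- function(calc, coords, fmax = 0.01, maxsteps = 500) {
  stopifnot(fmax > 0)
  x <- as.matrix(coords)
  n <- nrow(x)
  e0 <- calc_energy(calc, x)
  if (!is.finite(e0))
    stop("relax_structure: calculator returned a non-finite energy",
         call. = FALSE)
  f <- calc_forces(calc, x)
  if (max_force_norm(f) < fmax)
    return(list(coords = x, energy = e0, fmax = max_force_norm(f),
                steps = 0L))
  steps <- 0L
  chunk <- 50L
  while (steps < maxsteps) {
    res <- stats::optim(as.vector(x),
                        fn = function(v) calc_energy(calc, matrix(v, n, 3)),
                        gr = function(v)
                          -as.vector(calc_forces(calc, matrix(v, n, 3))),
                        method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 10))
    x <- matrix(res$par, n, 3)
    steps <- steps + chunk
    f <- calc_forces(calc, x)
    if (max_force_norm(f) < fmax)
      return(list(coords = x, energy = calc_energy(calc, x),
                  fmax = max_force_norm(f), steps = steps))
    if (res$convergence == 0 && max_force_norm(f) >= fmax) {
      # optimizer stalled above the force threshold; perturb-free retry
      # with tighter tolerance happens implicitly on the next chunk
      if (steps >= maxsteps) break
    }
  }
  stop(errorCondition(
    sprintf("relaxation did not reach fmax = %g eV/A in %d steps (residual %g)",
            fmax, maxsteps, max_force_norm(f)),
    class = "tbo_nonconvergence",
    geometry = x, energy = calc_energy(calc, x)))
}

#' Relax a torsion vector on a torsion-space calculator
#'
#' L-BFGS minimization of the true potential in torsion coordinates,
#' used to polish surrogate minima when the backend itself is a function
#' of the torsions.
#'
#' @param calc Torsion calculator.
#' @param torsions Starting torsion vector (degrees).
#' @return List with `torsions` (wrapped) and `energy` (eV).
#' @export
relax_torsions <- function(calc, torsions) {
  gr <- if (inherits(calc, "analytic_torsion_pes"))
    function(t) pes_gradient(calc, t) else NULL
  res <- stats::optim(as.numeric(torsions),
                      fn = function(t) calc_energy(calc, t), gr = gr,
                      method = "L-BFGS-B",
                      control = list(maxit = 300, factr = 1e4))
  list(torsions = wrap_angle(res$par), energy = res$value)
}

#' Mass-weighted Hessian by central finite differences of forces
#'
#' Each Cartesian coordinate is displaced by +/- `delta`; the force
#' difference gives one Hessian column. The matrix is symmetrized as
#' (H + t(H))/2 and mass-weighted by 1/sqrt(m_i m_j).
#'
#' @param calc Cartesian calculator with forces.
#' @param coords Relaxed n x 3 coordinates (Angstrom).
#' @param masses Atomic masses (amu), length n.
#' @param delta Finite-difference displacement, Angstrom (default 0.0025).
#' @return 3n x 3n mass-weighted Hessian, eV/(Angstrom^2 amu), with the
#'   displacement stored in `attr(, "delta")`.
#' @export
hessian_finite_difference <- function(calc, coords, masses,
                                      delta = 0.0025) {
  stopifnot(delta > 0)
  x <- as.matrix(coords)
  n <- nrow(x)
  stopifnot(length(masses) == n)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in 1:3) {
    col <- (i - 1) * 3 + j
    xp <- x; xp[i, j] <- xp[i, j] + delta
    xm <- x; xm[i, j] <- xm[i, j] - delta
    fp <- calc_forces(calc, xp)
    fm <- calc_forces(calc, xm)
    if (any(!is.finite(fp)) || any(!is.finite(fm)))
      stop(sprintf("calculator failed at displacement atom %d coord %d", i, j),
           call. = FALSE)
    H[, col] <- -as.vector(t(fp - fm)) / (2 * delta)
  }
  H <- (H + t(H)) / 2
  w <- rep(1 / sqrt(masses), each = 3)
  H <- H * outer(w, w)
  attr(H, "delta") <- delta
  H
}

# Orthonormal rigid-body (translation + rotation) vectors in
# mass-weighted coordinates; 5 for linear molecules, 6 otherwise,
# 3 for a single atom.
rigid_body_basis <- function(coords, masses) {
  n <- nrow(coords)
  sm <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  rel <- sweep(coords, 2, com)
  vecs <- list()
  for (a in 1:3) {
    v <- matrix(0, n, 3); v[, a] <- sm
    vecs[[length(vecs) + 1L]] <- as.vector(t(v))
  }
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- 1
    v <- t(vapply(seq_len(n), function(i) sm[i] * cross3(rel[i, ], e),
                  numeric(3)))
    vecs[[length(vecs) + 1L]] <- as.vector(t(v))
  }
  B <- do.call(cbind, vecs)
  s <- svd(B)
  keep <- s$d > max(s$d) * 1e-8
  s$u[, keep, drop = FALSE]
}

#' Harmonic normal modes from a mass-weighted Hessian
#'
#' Projects out rigid-body translations and rotations (Eckart-style,
#' rather than discarding the smallest modes), diagonalizes the projected
#' Hessian and converts positive eigenvalues to vibrational quanta
#' \eqn{\hbar\omega} (eV). Eigenvalues whose magnitude falls below the
#' 10 cm^-1 equivalent are treated as numerically zero; more negative
#' ones are imaginary modes, which are reported, flagged and excluded
#' from the retained set.
#'
#' @param H Mass-weighted Hessian from [hessian_finite_difference()].
#' @param coords n x 3 coordinates (Angstrom) of the analyzed geometry.
#' @param masses Atomic masses (amu).
#' @return List with `hbar_omega` (retained mode quanta, eV, ascending),
#'   `n_imaginary`, `imaginary_hbar_omega` (eV magnitudes), `n_zero`
#'   (projected-out rigid-body space), and `suspicious` (`TRUE` when more
#'   near-zero/negative modes remain than rigid-body motions explain).
#' @export
normal_modes <- function(H, coords, masses) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(nrow(H) == 3 * n)
  fac <- tbo_constants$hbar_omega_factor
  lam_thresh <- (10 * tbo_constants$cm1_to_eV / fac)^2
  if (n == 1)
    return(list(hbar_omega = numeric(0), n_imaginary = 0L,
                imaginary_hbar_omega = numeric(0), n_zero = 3L,
                suspicious = FALSE))
  Q <- rigid_body_basis(coords, masses)
  P <- diag(3 * n) - tcrossprod(Q)
  Hp <- P %*% H %*% P
  lam <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  # the projected-out space contributes ncol(Q) exact zeros
  lam <- sort(lam)
  pos <- lam > lam_thresh
  neg <- lam < -lam_thresh
  near0 <- sum(!pos & !neg)
  list(hbar_omega = fac * sqrt(lam[pos]),
       n_imaginary = sum(neg),
       imaginary_hbar_omega = fac * sqrt(-lam[neg]),
       n_zero = near0,
       suspicious = near0 > ncol(Q) || any(neg))
}

#' Harmonic vibrational free energy
#'
#' \deqn{F_{vib}(T) = \sum_i \left[ \frac{\hbar\omega_i}{2}
#'   + k_B T \ln(1 - e^{-\hbar\omega_i / k_B T}) \right]}
#' summed over the molecule's normal modes (its phonon density of states
#' is a sum of delta functions). At T = 0 the thermal term vanishes and
#' F_vib equals the zero-point energy.
#'
#' @param hbar_omega Vector of mode quanta \eqn{\hbar\omega_i} (eV,
#'   positive).
#' @param temperature Temperature in K (>= 0).
#' @return F_vib in eV (0 for an empty mode set).
#' @export
vibrational_free_energy <- function(hbar_omega, temperature) {
  stopifnot(temperature >= 0)
  if (any(hbar_omega <= 0))
    stop("vibrational_free_energy: non-positive frequency", call. = FALSE)
  if (!length(hbar_omega)) return(0)
  zpe <- sum(hbar_omega) / 2
  if (temperature == 0) return(zpe)
  kT <- tbo_constants$kB * temperature
  zpe + kT * sum(log(1 - exp(-hbar_omega / kT)))
}

#' Zero-point energy of a mode set
#' @inheritParams vibrational_free_energy
#' @return Sum of \eqn{\hbar\omega_i/2}, eV.
#' @export
zero_point_energy <- function(hbar_omega) {
  if (!length(hbar_omega)) return(0)
  sum(hbar_omega) / 2
}

#' Full harmonic vibrational analysis of a geometry
#'
#' Convenience wrapper: finite-difference mass-weighted Hessian, normal
#' modes, zero-point energy and vibrational free energy at the requested
#' temperature.
#'
#' @param calc Cartesian calculator with forces.
#' @param coords Relaxed n x 3 coordinates (Angstrom).
#' @param masses Atomic masses (amu).
#' @param temperature Temperature, K (default 300).
#' @param delta Finite-difference displacement, Angstrom (default 0.0025).
#' @return List of class `vibrational_result`: `hbar_omega`, `zpe`,
#'   `f_vib`, `temperature`, `n_imaginary`, `suspicious`.
#' @export
vibrational_analysis <- function(calc, coords, masses, temperature = 300,
                                 delta = 0.0025) {
  H <- hessian_finite_difference(calc, coords, masses, delta)
  nm <- normal_modes(H, coords, masses)
  structure(list(hbar_omega = nm$hbar_omega,
                 zpe = zero_point_energy(nm$hbar_omega),
                 f_vib = vibrational_free_energy(nm$hbar_omega, temperature),
                 temperature = temperature,
                 n_imaginary = nm$n_imaginary,
                 suspicious = nm$suspicious),
            class = "vibrational_result")
}

#' Attach high-level single-point corrections to conformer records
#'
#' The correction for each labelled conformer is
#' \eqn{\Delta = E_{high} - E_{opt}} (e.g. a coupled-cluster single point
#' minus the relaxation-level energy); it is added on top of the
#' vibrational corrections in the final hierarchy stage. Records without
#' a supplied high-level energy keep `NA` and are excluded from that
#' stage.
#'
#' @param records Data frame with at least `label` and `E_opt` columns.
#' @param highlevel Data frame with columns `label` and `energy` (eV), or
#'   a path to a two-column CSV.
#' @return `records` with a `delta_cc` column.
#' @export
apply_singlepoint_delta <- function(records, highlevel) {
  if (is.character(highlevel))
    highlevel <- utils::read.csv(highlevel, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "energy") %in% names(highlevel)))
  unmatched <- setdiff(highlevel$label, records$label)
  if (length(unmatched))
    stop("apply_singlepoint_delta: no record for label(s): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  i <- match(records$label, highlevel$label)
  records$delta_cc <- highlevel$energy[i] - records$E_opt
  records
}

#' Assemble the staged conformer energy hierarchy
#'
#' Builds the per-stage relative energies and ranks: the search
#' (surrogate) prediction, the relaxed energy, the relaxed energy plus
#' zero-point energy (+VE(0 K)), plus the 300 K vibrational free energy
#' (+VE(300 K)), and plus the high-level correction. For each stage the
#' most stable conformer defines the zero of energy. Stages whose
#' ingredients are absent from `records` are skipped. Ranks are assigned
#' ascending with ties broken by label; the result is independent of the
#' input row order.
#'
#' @param records Data frame with columns `label`, `E_opt`, and optionally
#'   `E_surrogate`, `zpe`, `f_vib`, `delta_cc`.
#' @return List of class `conformer_hierarchy` with `table` (one row per
#'   conformer, per-stage absolute/relative energies and ranks) and
#'   `stages` (character vector of stage names among `search`, `opt`,
#'   `ve0`, `ve300`, `cc`).
#' @export
assemble_hierarchy <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("label", "E_opt") %in% names(records)))
  records <- records[order(records$label), , drop = FALSE]
  stage_energy <- list()
  if ("E_surrogate" %in% names(records))
    stage_energy$search <- records$E_surrogate
  stage_energy$opt <- records$E_opt
  has_vib <- all(c("zpe", "f_vib") %in% names(records)) &&
    !all(is.na(records$zpe))
  if (has_vib) {
    stage_energy$ve0 <- records$E_opt + records$zpe
    stage_energy$ve300 <- records$E_opt + records$f_vib
    if ("delta_cc" %in% names(records) && any(!is.na(records$delta_cc)))
      stage_energy$cc <- records$E_opt + records$f_vib + records$delta_cc
  } else if ("delta_cc" %in% names(records) &&
             any(!is.na(records$delta_cc))) {
    stage_energy$cc <- records$E_opt + records$delta_cc
  }
  tab <- records
  for (st in names(stage_energy)) {
    e <- stage_energy[[st]]
    rel <- e - min(e, na.rm = TRUE)
    rnk <- rep(NA_integer_, length(e))
    ok <- !is.na(e)
    rnk[ok] <- order(order(e[ok], records$label[ok]))
    tab[[paste0("E_", st)]] <- e
    tab[[paste0("rel_", st)]] <- rel
    tab[[paste0("rank_", st)]] <- rnk
  }
  rownames(tab) <- NULL
  structure(list(table = tab, stages = names(stage_energy)),
            class = "conformer_hierarchy")
}

#' @export
print.conformer_hierarchy <- function(x, ...) {
  cat("conformer_hierarchy:", nrow(x$table), "conformer(s); stages:",
      paste(x$stages, collapse = " -> "), "\n")
  cols <- c("label", paste0("rel_", x$stages))
  print(x$table[order(x$table[[paste0("rank_", x$stages[length(x$stages)])]]),
                intersect(cols, names(x$table))], row.names = FALSE)
  invisible(x)
}
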
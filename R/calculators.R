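# Pluggable energy backends. Two families share one contract:
#   * torsion calculators  - energy as a function of a torsion vector
#                            (degrees); used directly by the search loop.
#   * cartesian calculators - energy (and forces) as a function of an
#                            n x 3 coordinate matrix (Angstrom); used for
#                            relaxation and vibrations, and for the search
#                            via set_torsions().
# Energies are eV, forces eV/Angstrom. Deterministic backends return the
# same output for the same input; failures are signalled by a non-finite
# energy or an R error.

#' Evaluate a calculator's energy
#' @param calc A calculator object.
#' @param x Torsion vector (degrees) for torsion calculators, or an n x 3
#'   coordinate matrix for Cartesian calculators.
#' @param ... Backend-specific arguments.
#' @return Scalar energy in eV.
#' @export
calc_energy <- function(calc, x, ...) UseMethod("calc_energy")

#' Evaluate a calculator's forces
#'
#' Backends without analytic forces fall back to central finite
#' differences of the energy (step 1e-6 Angstrom).
#'
#' @inheritParams calc_energy
#' @param x n x 3 coordinate matrix (Angstrom).
#' @return n x 3 matrix of forces (eV/Angstrom), the negative energy
#'   gradient.
#' @export
calc_forces <- function(calc, x, ...) UseMethod("calc_forces")

#' @export
calc_forces.default <- function(calc, x, ..., h = 1e-6) {
  x <- as.matrix(x)
  f <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) for (j in 1:3) {
    xp <- x; xp[i, j] <- xp[i, j] + h
    xm <- x; xm[i, j] <- xm[i, j] - h
    f[i, j] <- -(calc_energy(calc, xp, ...) - calc_energy(calc, xm, ...)) / (2 * h)
  }
  f
}

#' Does a calculator act on torsion vectors (rather than coordinates)?
#' @param calc A calculator object.
#' @return Logical.
#' @export
is_torsion_calculator <- function(calc) inherits(calc, "torsion_calculator")

# Energy at a torsion vector, routing through set_torsions() for
# Cartesian backends.
eval_torsion_energy <- function(calc, torsions, model = NULL) {
  if (is_torsion_calculator(calc)) return(calc_energy(calc, torsions))
  if (is.null(model))
    stop("a molecule_model is required for a Cartesian calculator",
         call. = FALSE)
  calc_energy(calc, set_torsions(model, torsions))
}

# --- analytic torsional PES --------------------------------------------

#' Analytic torsional potential energy surface
#'
#' A smooth, 360-degree-periodic multi-well landscape:
#' \deqn{E(d) = \sum_j \sum_{k=1}^{3} a_{jk} \cos(k \theta_j + \phi_{jk})
#'   + \sum_{i<j} c_{ij} \cos(\theta_i - \theta_j)}
#' with \eqn{\theta} in radians. Cosine orders 1-3 reproduce the 1-, 2-
#' and 3-fold barriers typical of rotations about single bonds; the
#' pairwise difference couplings correlate neighbouring torsions. Minima
#' are enumerable by dense grid scan, which makes these surfaces exact
#' test fixtures for the search machinery.
#'
#' @param amplitudes N x 3 matrix of cosine amplitudes `a_jk` (eV).
#' @param phases N x 3 matrix of phase offsets (radians).
#' @param couplings N x N matrix of pairwise coupling strengths (eV); only
#'   the upper triangle is used. `NULL` for no coupling.
#' @param seed Optional integer recorded for provenance.
#' @return A torsion calculator of class `analytic_torsion_pes`.
#' @seealso [generate_test_pes()], [grid_local_minima()]
#' @export
analytic_torsion_pes <- function(amplitudes, phases, couplings = NULL,
                                 seed = NULL) {
  amplitudes <- as.matrix(amplitudes)
  phases <- as.matrix(phases)
  stopifnot(ncol(amplitudes) == 3, all(dim(amplitudes) == dim(phases)))
  n <- nrow(amplitudes)
  if (!is.null(couplings)) {
    couplings <- as.matrix(couplings)
    stopifnot(all(dim(couplings) == c(n, n)))
  }
  structure(list(dim = n, amplitudes = amplitudes, phases = phases,
                 couplings = couplings, seed = seed),
            class = c("analytic_torsion_pes", "torsion_calculator"))
}

#' @export
calc_energy.analytic_torsion_pes <- function(calc, x, ...) {
  th <- as.numeric(x) * pi / 180
  stopifnot(length(th) == calc$dim)
  e <- 0
  for (j in seq_len(calc$dim))
    e <- e + sum(calc$amplitudes[j, ] * cos((1:3) * th[j] + calc$phases[j, ]))
  if (!is.null(calc$couplings) && calc$dim > 1) {
    for (i in seq_len(calc$dim - 1)) for (j in seq.int(i + 1, calc$dim)) {
      cij <- calc$couplings[i, j]
      if (cij != 0) e <- e + cij * cos(th[i] - th[j])
    }
  }
  e
}

#' Analytic gradient of an analytic torsional PES
#' @param calc An [analytic_torsion_pes()].
#' @param x Torsion vector (degrees).
#' @return Gradient vector, eV per degree.
#' @export
pes_gradient <- function(calc, x) {
  stopifnot(inherits(calc, "analytic_torsion_pes"))
  th <- as.numeric(x) * pi / 180
  g <- numeric(calc$dim)
  for (j in seq_len(calc$dim))
    g[j] <- -sum(calc$amplitudes[j, ] * (1:3) *
                   sin((1:3) * th[j] + calc$phases[j, ]))
  if (!is.null(calc$couplings) && calc$dim > 1) {
    for (i in seq_len(calc$dim - 1)) for (j in seq.int(i + 1, calc$dim)) {
      cij <- calc$couplings[i, j]
      if (cij != 0) {
        s <- cij * sin(th[i] - th[j])
        g[i] <- g[i] - s
        g[j] <- g[j] + s
      }
    }
  }
  g * pi / 180
}

#' Enumerate grid local minima of a torsion calculator by brute force
#'
#' Scans the full periodic grid and reports every point strictly below all
#' of its 3^N - 1 cyclic neighbours.
#'
#' @param calc A torsion calculator.
#' @param step Grid spacing in degrees (must divide 360).
#' @return A list with `torsions` (matrix, one minimum per row, degrees),
#'   `energies` (eV) and `step`; rows sorted by energy.
#' @export
grid_local_minima <- function(calc, step = 1) {
  n <- calc$dim %||% stop("calculator must carry a 'dim' field")
  m <- as.integer(round(360 / step))
  axes <- lapply(seq_len(n), function(j) -180 + 360 * (0:(m - 1)) / m)
  grid <- as.matrix(do.call(expand.grid, axes))
  E <- apply(grid, 1, function(t) calc_energy(calc, t))
  arr <- array(E, dim = rep(m, n))
  is_min <- array(TRUE, dim = rep(m, n))
  shifts <- as.matrix(do.call(expand.grid, rep(list(-1:1), n)))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  roll <- function(a, sh) {
    idx <- lapply(seq_len(n), function(j) {
      i <- seq_len(m)
      ((i - 1 - sh[j]) %% m) + 1
    })
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (r in seq_len(nrow(shifts)))
    is_min <- is_min & (arr < roll(arr, shifts[r, ]))
  sel <- which(as.vector(is_min))
  o <- order(E[sel])
  list(torsions = grid[sel[o], , drop = FALSE], energies = E[sel[o]],
       step = step)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random multi-well torsional test surface
#'
#' Draws cosine-series coefficients until the brute-force grid minima
#' count falls in the requested range. The scan resolution is 1 degree for
#' 1-2 torsions and 5 degrees for 3-4 (coarser scans are the caller's
#' responsibility above that). Coefficients and the seed are stored in the
#' returned object, so a fixture is fully reproducible.
#'
#' @param dimension Number of torsions (1-6).
#' @param seed Integer seed for the coefficient draw.
#' @param minima_range Length-2 integer vector; accepted range (inclusive)
#'   for the number of grid local minima.
#' @param couple Logical; include pairwise difference couplings (default
#'   `TRUE` for dimension > 1).
#' @param max_draws Redraw limit before giving up.
#' @return An [analytic_torsion_pes()] with an attached `minima` attribute
#'   (the grid enumeration used for acceptance).
#' @export
generate_test_pes <- function(dimension, seed, minima_range = c(2, 8),
                              couple = dimension > 1, max_draws = 50) {
  stopifnot(dimension >= 1, dimension <= 6)
  step <- if (dimension <= 2) 1 else if (dimension <= 4) 5 else 15
  set.seed(seed)
  for (draw in seq_len(max_draws)) {
    amp <- matrix(stats::runif(dimension * 3, 0.02, 0.12) *
                    sample(c(-1, 1), dimension * 3, replace = TRUE),
                  dimension, 3)
    ph <- matrix(stats::runif(dimension * 3, 0, 2 * pi), dimension, 3)
    cpl <- NULL
    if (couple && dimension > 1) {
      cpl <- matrix(0, dimension, dimension)
      cpl[upper.tri(cpl)] <- stats::runif(sum(upper.tri(cpl)), -0.03, 0.03)
    }
    pes <- analytic_torsion_pes(amp, ph, cpl, seed = seed)
    mins <- grid_local_minima(pes, step = step)
    k <- length(mins$energies)
    if (k >= minima_range[1] && k <= minima_range[2]) {
      attr(pes, "minima") <- mins
      return(pes)
    }
  }
  stop("could not generate a surface with ", minima_range[1], "-",
       minima_range[2], " minima in ", max_draws, " draws", call. = FALSE)
}

#' One-dimensional cysteine-like torsional profile
#'
#' A fixed three-well profile emulating the rotation of a single side-chain
#' dihedral of an amino acid: a dominant 3-fold barrier (sp3 rotor) with 1-
#' and 2-fold components that break the well degeneracy, giving one global
#' and two higher local minima within ~0.3 eV. Used as the cheap
#' deterministic stand-in for a quantum-chemistry backend in examples and
#' validation runs.
#'
#' @return An [analytic_torsion_pes()] of dimension 1.
#' @export
cysteine_d1_profile <- function() {
  analytic_torsion_pes(
    amplitudes = matrix(c(0.050, 0.022, 0.085), 1, 3),
    phases = matrix(c(0.9, 0.4, 0.0), 1, 3)
  )
}

#' Optional contrast transform for plotting PES maps
#'
#' Raises non-negative relative energies to the 3/4 power to increase the
#' visual contrast of low-energy features in map exports. Never used in any
#' computation.
#'
#' @param E Numeric vector/matrix of relative energies (>= 0).
#' @return Transformed energies.
#' @export
map_contrast <- function(E) {
  if (any(E < 0, na.rm = TRUE))
    stop("map_contrast expects relative energies >= 0", call. = FALSE)
  E^0.75
}

#' Evaluate a calculator on a regular 1D/2D torsion grid
#'
#' Builds the full regular grid over \eqn{[-180, 180)} for one or two
#' selected dihedrals (points at \eqn{-180 + 360 i/n}; the periodic
#' endpoint is not duplicated), holding all other dihedrals fixed, and
#' returns energies relative to the grid minimum. A reference map of this
#' kind (e.g. 30 x 30 = 900 single-point calculations for two dihedrals)
#' is the standard exhaustive baseline against which the active-learning
#' search is validated.
#'
#' @param calc A torsion calculator, or a Cartesian calculator with
#'   `model` supplied.
#' @param n Number of grid points per dimension (>= 2).
#' @param dihedrals Indices of the 1 or 2 dihedrals to scan.
#' @param fixed Full-length torsion vector supplying the values of the
#'   non-scanned dihedrals (defaults to all zeros).
#' @param model A [molecule_model()] when `calc` is Cartesian.
#' @return List with `axes` (grid values per scanned dimension), `energies`
#'   (vector for 1D, n x n matrix for 2D; eV relative to the grid minimum;
#'   `NA` where the backend failed), `n_evaluations` (always `n^dims`),
#'   `n_failed`, `dihedrals` and `fixed`.
#' @export
grid_reference_map <- function(calc, n, dihedrals = 1, fixed = NULL,
                               model = NULL) {
  stopifnot(n >= 2, length(dihedrals) %in% c(1, 2))
  ndim <- if (is_torsion_calculator(calc)) calc$dim
          else length(model$dihedrals)
  if (is.null(fixed)) fixed <- rep(0, ndim)
  stopifnot(length(fixed) == ndim, all(dihedrals <= ndim))
  axis <- -180 + 360 * (0:(n - 1)) / n
  dims <- length(dihedrals)
  pts <- as.matrix(do.call(expand.grid, rep(list(axis), dims)))
  E <- rep(NA_real_, nrow(pts))
  nfail <- 0L
  for (i in seq_len(nrow(pts))) {
    t <- fixed
    t[dihedrals] <- pts[i, ]
    val <- tryCatch(eval_torsion_energy(calc, t, model),
                    error = function(e) NA_real_)
    if (!is.finite(val)) { nfail <- nfail + 1L; val <- NA_real_ }
    E[i] <- val
  }
  E <- E - min(E, na.rm = TRUE)
  if (dims == 2) E <- matrix(E, n, n)
  list(axes = rep(list(axis), dims), energies = E,
       n_evaluations = as.integer(n^dims), n_failed = nfail,
       dihedrals = dihedrals, fixed = fixed)
}

#' Serialize / restore an analytic PES fixture as JSON
#' @param pes An [analytic_torsion_pes()].
#' @param path Output (input) path.
#' @return `path` invisibly; `read_pes_json` returns the PES.
#' @export
write_pes_json <- function(pes, path) {
  jsonlite::write_json(
    list(dim = pes$dim, amplitudes = pes$amplitudes, phases = pes$phases,
         couplings = pes$couplings, seed = pes$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pes_json
#' @export
read_pes_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v, nr, nc) {
    if (is.null(v)) NULL
    else if (is.matrix(v)) v
    else matrix(unlist(v), nr, nc, byrow = TRUE)
  }
  analytic_torsion_pes(as_mat(x$amplitudes, x$dim, 3),
                       as_mat(x$phases, x$dim, 3),
                       as_mat(x$couplings, x$dim, x$dim), seed = x$seed)
}

# --- simple Cartesian calculators --------------------------------------

#' Isotropic harmonic-well calculator
#'
#' \eqn{E = \tfrac{1}{2} k \sum_i |r_i - r_i^0|^2}; analytic forces.
#' A closed-form fixture for relaxation and Hessian tests.
#'
#' @param center n x 3 matrix of well centres (Angstrom).
#' @param k Force constant, eV/Angstrom^2.
#' @return A Cartesian calculator.
#' @export
harmonic_well_calculator <- function(center, k = 1) {
  structure(list(center = as.matrix(center), k = k),
            class = c("harmonic_well_calculator", "cartesian_calculator"))
}

#' @export
calc_energy.harmonic_well_calculator <- function(calc, x, ...)
  0.5 * calc$k * sum((as.matrix(x) - calc$center)^2)

#' @export
calc_forces.harmonic_well_calculator <- function(calc, x, ...)
  -calc$k * (as.matrix(x) - calc$center)

#' Pairwise harmonic-spring calculator
#'
#' \eqn{E = \sum_b \tfrac{1}{2} k_b (|r_i - r_j| - r^0_b)^2} over a bond
#' list; analytic forces. The classic reduced-mass oscillator fixture.
#'
#' @param bonds Two-column matrix of 1-based atom pairs.
#' @param k Spring constants (recycled), eV/Angstrom^2.
#' @param r0 Equilibrium lengths (recycled), Angstrom.
#' @return A Cartesian calculator.
#' @export
spring_calculator <- function(bonds, k, r0) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  structure(list(bonds = bonds, k = rep_len(k, nrow(bonds)),
                 r0 = rep_len(r0, nrow(bonds))),
            class = c("spring_calculator", "cartesian_calculator"))
}

#' @export
calc_energy.spring_calculator <- function(calc, x, ...) {
  x <- as.matrix(x)
  d <- sqrt(rowSums((x[calc$bonds[, 1], , drop = FALSE] -
                     x[calc$bonds[, 2], , drop = FALSE])^2))
  sum(0.5 * calc$k * (d - calc$r0)^2)
}

#' @export
calc_forces.spring_calculator <- function(calc, x, ...) {
  x <- as.matrix(x)
  f <- matrix(0, nrow(x), 3)
  for (b in seq_len(nrow(calc$bonds))) {
    i <- calc$bonds[b, 1]; j <- calc$bonds[b, 2]
    v <- x[i, ] - x[j, ]
    d <- sqrt(sum(v^2))
    fb <- -calc$k[b] * (d - calc$r0[b]) * v / d
    f[i, ] <- f[i, ] + fb
    f[j, ] <- f[j, ] - fb
  }
  f
}

#' Simple molecular-mechanics force field bound to a molecule model
#'
#' Harmonic bond and angle terms referenced to the model's input geometry
#' plus cosine torsion terms on the searchable dihedrals:
#' \deqn{E = \sum_b \tfrac{k_b}{2}(r - r_0)^2
#'   + \sum_a \tfrac{k_a}{2}(\theta - \theta_0)^2
#'   + \sum_t \sum_{k=1}^{3} a_{tk} \cos(k d_t + \phi_{tk}).}
#' With the geometry built rigidly by [set_torsions()], the bond and angle
#' terms vanish and the torsional profile is recovered exactly, so the
#' same backend serves the search (via torsions) and the refinement (full
#' Cartesian relaxation, finite-difference Hessian).
#'
#' @param model A [molecule_model()].
#' @param torsion_amplitudes N x 3 matrix of torsion amplitudes (eV).
#' @param torsion_phases N x 3 matrix of phases (radians).
#' @param bond_k,angle_k Force constants (eV/Angstrom^2, eV/rad^2).
#' @return A Cartesian calculator.
#' @export
mm_calculator <- function(model, torsion_amplitudes, torsion_phases,
                          bond_k = 30, angle_k = 3) {
  stopifnot(inherits(model, "molecule_model"))
  n <- length(model$dihedrals)
  torsion_amplitudes <- matrix(torsion_amplitudes, n, 3)
  torsion_phases <- matrix(torsion_phases, n, 3)
  # angle triples j-i-k for every atom i with >= 2 neighbours
  bonds <- model$bonds
  nb <- lapply(seq_along(model$elements), function(i)
    sort(unique(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))))
  triples <- list()
  for (i in seq_along(nb)) {
    if (length(nb[[i]]) < 2) next
    prs <- utils::combn(nb[[i]], 2)
    for (m in seq_len(ncol(prs)))
      triples[[length(triples) + 1L]] <- c(prs[1, m], i, prs[2, m])
  }
  ref <- model$coords
  r0 <- bond_lengths(ref, bonds)
  th0 <- vapply(triples, function(tr) {
    v1 <- unit3(ref[tr[1], ] - ref[tr[2], ])
    v2 <- unit3(ref[tr[3], ] - ref[tr[2], ])
    acos(pmin(1, pmax(-1, sum(v1 * v2))))
  }, numeric(1))
  structure(list(model = model, amp = torsion_amplitudes,
                 phase = torsion_phases, bond_k = bond_k, angle_k = angle_k,
                 triples = triples, r0 = r0, th0 = th0),
            class = c("mm_calculator", "cartesian_calculator"))
}

#' @export
calc_energy.mm_calculator <- function(calc, x, ...) {
  x <- as.matrix(x)
  model <- calc$model
  d <- bond_lengths(x, model$bonds)
  e <- sum(0.5 * calc$bond_k * (d - calc$r0)^2)
  for (m in seq_along(calc$triples)) {
    tr <- calc$triples[[m]]
    v1 <- unit3(x[tr[1], ] - x[tr[2], ])
    v2 <- unit3(x[tr[3], ] - x[tr[2], ])
    th <- acos(pmin(1, pmax(-1, sum(v1 * v2))))
    e <- e + 0.5 * calc$angle_k * (th - calc$th0[m])^2
  }
  tor <- measure_torsions(x, model$dihedrals) * pi / 180
  for (t in seq_along(tor))
    e <- e + sum(calc$amp[t, ] * cos((1:3) * tor[t] + calc$phase[t, ]))
  e
}

# --- file-exchange bridge ----------------------------------------------

#' File-exchange calculator for external codes
#'
#' Bridges to an external (e.g. quantum-chemistry) program through the
#' file system: each evaluation writes `eval_NNNNNN.xyz` and a matching
#' `eval_NNNNNN_request.json` into `workdir`, then polls for
#' `eval_NNNNNN_result.json`, which must contain a JSON object with an
#' `energy` field (eV) and, when forces are requested, a `forces` field
#' (n x 3 nested array, eV/Angstrom).
#'
#' @param workdir Writable exchange directory.
#' @param elements Element symbols of the structure being evaluated.
#' @param timeout Seconds to wait for a result before failing.
#' @param poll Poll interval in seconds.
#' @return A Cartesian calculator.
#' @export
file_exchange_calculator <- function(workdir, elements, timeout = 60,
                                     poll = 0.05) {
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  env <- new.env()
  env$counter <- 0L
  structure(list(workdir = workdir, elements = elements, timeout = timeout,
                 poll = poll, state = env),
            class = c("file_exchange_calculator", "cartesian_calculator"))
}

file_exchange_round_trip <- function(calc, x, need_forces) {
  calc$state$counter <- calc$state$counter + 1L
  tag <- sprintf("eval_%06d", calc$state$counter)
  geom <- file.path(calc$workdir, paste0(tag, ".xyz"))
  write_xyz(list(elements = calc$elements, coords = as.matrix(x)), geom,
            comments = tag)
  jsonlite::write_json(
    list(id = tag, geometry = basename(geom),
         want = if (need_forces) "energy+forces" else "energy"),
    file.path(calc$workdir, paste0(tag, "_request.json")),
    auto_unbox = TRUE)
  result <- file.path(calc$workdir, paste0(tag, "_result.json"))
  t0 <- Sys.time()
  while (!file.exists(result)) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > calc$timeout)
      stop("file-exchange timeout waiting for ", result, call. = FALSE)
    Sys.sleep(calc$poll)
  }
  out <- tryCatch(jsonlite::read_json(result, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed result file ", result, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(out$energy) || !is.numeric(out$energy))
    stop("result file ", result, " lacks a numeric 'energy' field",
         call. = FALSE)
  if (need_forces && is.null(out$forces))
    stop("result file ", result, " lacks the requested 'forces' block",
         call. = FALSE)
  out
}

#' @export
calc_energy.file_exchange_calculator <- function(calc, x, ...)
  file_exchange_round_trip(calc, x, need_forces = FALSE)$energy

#' @export
calc_forces.file_exchange_calculator <- function(calc, x, ...) {
  out <- file_exchange_round_trip(calc, x, need_forces = TRUE)
  f <- out$forces
  if (is.matrix(f)) f else matrix(unlist(f), ncol = 3, byrow = TRUE)
}
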
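# The active-learning loop: energy transform, eLCB acquisition,
# acquisition optimization, iteration control and convergence tracking.

#' Search configuration
#'
#' @param budget Total number of energy evaluations, initial design
#'   included.
#' @param n_init Number of initial space-filling design points; default
#'   `max(5, 2 N)` (resolved at run time from the search dimension).
#' @param e_cut Energy cutoff for the damping transform, eV (default 2.0).
#' @param de_tol Convergence threshold on the predicted global-minimum
#'   energy, eV (default 0.025).
#' @param dd_tol Convergence threshold on each predicted dihedral, degrees
#'   (default 10).
#' @param window Number of consecutive iterations over which both
#'   thresholds must hold (default 10).
#' @param beta_delta Confidence parameter of the eLCB exploration
#'   schedule (default 0.1).
#' @param continuous_transform Use the continuous variant of the energy
#'   transform (default `FALSE`, i.e. the plain piecewise form).
#' @param seed Integer seed governing all randomness of the run.
#' @return A `search_config` list.
#' @export
search_config <- function(budget = 100, n_init = NULL, e_cut = 2.0,
                          de_tol = 0.025, dd_tol = 10, window = 10,
                          beta_delta = 0.1, continuous_transform = FALSE,
                          seed = 1) {
  stopifnot(e_cut > 0, de_tol > 0, dd_tol > 0, window >= 2, budget >= 2)
  structure(list(budget = as.integer(budget), n_init = n_init,
                 e_cut = e_cut, de_tol = de_tol, dd_tol = dd_tol,
                 window = as.integer(window), beta_delta = beta_delta,
                 continuous_transform = continuous_transform,
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Damp high relative energies for surrogate fitting
#'
#' Steric clashes produce energy spikes that spoil GP fitting. Energies
#' (relative to the lowest observation, so non-negative) above `e_cut` are
#' damped logarithmically:
#' \deqn{E_{new} = E_{cut} + \log_{10} E \quad (E > E_{cut}),}
#' while energies at or below the cutoff pass through unchanged. The
#' piecewise form has a step at \eqn{E = E_{cut}}; setting
#' `continuous = TRUE` subtracts \eqn{\log_{10} E_{cut}} on the damped
#' branch, which removes the step while keeping the same asymptotics.
#'
#' @param E Numeric vector of relative energies (eV).
#' @param e_cut Cutoff energy, eV (> 0).
#' @param continuous Use the continuous variant (default `FALSE`).
#' @return Transformed energies (eV).
#' @export
transform_energy <- function(E, e_cut = 2.0, continuous = FALSE) {
  stopifnot(is.numeric(E), e_cut > 0)
  if (any(!is.finite(E)))
    stop("transform_energy: non-finite energy", call. = FALSE)
  hi <- E > e_cut
  if (any(hi) && any(E[hi] <= 0))
    stop("transform_energy: log10 undefined for non-positive energy",
         call. = FALSE)
  out <- E
  out[hi] <- e_cut + log10(E[hi]) - if (continuous) log10(e_cut) else 0
  out
}

# Inverse of the (piecewise) transform, for reporting on the raw scale.
inverse_transform_energy <- function(Et, e_cut = 2.0, continuous = FALSE) {
  out <- Et
  hi <- Et > e_cut
  out[hi] <- 10^(Et[hi] - e_cut + if (continuous) log10(e_cut) else 0)
  out
}

#' eLCB exploration weight schedule
#'
#' \eqn{\beta_t = 2 \log( t^{N/2+2} \pi^2 / (3\delta) )}, the standard
#' lower-confidence-bound schedule whose exploration weight grows slowly
#' with the iteration count `t` and the search dimension `N`.
#'
#' @param iteration Iteration count t (>= 1).
#' @param ndim Search dimension N.
#' @param delta Confidence parameter (default 0.1).
#' @return Scalar beta_t.
#' @export
beta_schedule <- function(iteration, ndim, delta = 0.1) {
  stopifnot(iteration >= 1)
  2 * ((ndim / 2 + 2) * log(iteration) + log(pi^2 / (3 * delta)))
}

#' Exploratory lower confidence bound acquisition function
#'
#' \eqn{\mathrm{eLCB}(x) = \mu(x) - \sqrt{\beta_t}\,\sigma(x)}; its
#' minimizer is the next point to evaluate. With `beta = 0` this is pure
#' exploitation of the posterior mean.
#'
#' @param model Fitted `surrogate_gp`.
#' @param x Torsion vector or matrix of points (degrees).
#' @param iteration Iteration count used by the schedule (ignored when
#'   `beta` is given).
#' @param beta Optional explicit exploration weight.
#' @param delta Schedule confidence parameter.
#' @return Acquisition values (eV), one per row of `x`.
#' @export
elcb <- function(model, x, iteration = 1, beta = NULL, delta = 0.1) {
  if (!inherits(model, "surrogate_gp"))
    stop("elcb: model is not a fitted surrogate_gp", call. = FALSE)
  if (is.null(beta)) beta <- beta_schedule(iteration, ncol(model$X), delta)
  p <- gp_posterior(model, x)
  p$mean - sqrt(beta) * sqrt(p$variance)
}

# Gradient of elcb at a single point (eV/deg).
elcb_gradient <- function(model, x, beta) {
  gmu <- gp_posterior_gradient(model, x)
  if (beta <= 0) return(gmu)
  v <- gp_posterior(model, x)$variance
  if (v < 1e-16) return(gmu)
  gmu - sqrt(beta) * gp_variance_gradient(model, x) / (2 * sqrt(v))
}

# Multi-start bounded-free local minimization of a function over the
# periodic torsion space; periodicity makes unconstrained optimization
# valid, results are wrapped. Returns list(x, value).
minimize_periodic <- function(fn, gr, starts) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn = fn, gr = gr, method = "L-BFGS-B",
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("acquisition failure: every local minimization start failed",
         call. = FALSE)
  list(x = wrap_angle(best$par), value = best$value)
}

#' Select the next acquisition point
#'
#' Minimizes the eLCB acquisition function by multi-start L-BFGS from the
#' best observed sample plus uniformly drawn random starts; deterministic
#' given the R random-number state.
#'
#' @param model Fitted `surrogate_gp`.
#' @param iteration Iteration count for the exploration schedule.
#' @param n_starts Number of local-minimization starts (default 8).
#' @param delta Schedule confidence parameter.
#' @param beta Optional explicit exploration weight overriding the
#'   schedule.
#' @return Torsion vector (degrees, wrapped) minimizing the acquisition.
#' @export
next_acquisition <- function(model, iteration, n_starts = 8, delta = 0.1,
                             beta = NULL) {
  N <- ncol(model$X)
  if (is.null(beta)) beta <- beta_schedule(iteration, N, delta)
  starts <- rbind(model$X[which.min(model$y), , drop = FALSE],
                  matrix(stats::runif((n_starts - 1) * N, -180, 180),
                         ncol = N))
  minimize_periodic(function(t) elcb(model, t, beta = beta),
                    function(t) elcb_gradient(model, t, beta = beta),
                    starts)$x
}

# Predicted global minimum of the posterior mean (surrogate scale).
predict_global_minimum <- function(model, extra_starts = NULL, n_random = 3) {
  N <- ncol(model$X)
  starts <- rbind(model$X[which.min(model$y), , drop = FALSE],
                  extra_starts,
                  matrix(stats::runif(n_random * N, -180, 180), ncol = N))
  minimize_periodic(function(t) gp_posterior(model, t)$mean,
                    function(t) gp_posterior_gradient(model, t),
                    starts)
}

#' Run the active-learning conformer search
#'
#' Executes the initial space-filling design followed by the eLCB
#' acquisition loop. At every iteration the raw energies are shifted to
#' be relative to the lowest observation, damped by [transform_energy()],
#' and a periodic-kernel GP is refitted; the acquisition minimizer is the
#' next single-point evaluation. The predicted global minimum (multi-start
#' minimization of the posterior mean) is tracked per iteration, and
#' windowed convergence of its energy and dihedrals is reported.
#'
#' @param calculator A torsion calculator, or a Cartesian calculator with
#'   `model` supplied; evaluated geometries are then built by
#'   [set_torsions()].
#' @param config A [search_config()].
#' @param model A [molecule_model()] (required for Cartesian calculators;
#'   also defines the search dimension).
#' @param ndim Search dimension when `calculator` is a torsion calculator
#'   without a `dim` field.
#' @param refit_every_after Past this many samples, hyperparameters are
#'   refitted only every 10th iteration (default 200).
#' @param track_prediction Track the predicted global minimum each
#'   iteration (default `TRUE`; the basis of convergence monitoring).
#' @param verbose Log each acquisition (iteration, torsions, energy,
#'   seed) via [message()] (default `FALSE`).
#' @return A list of class `search_result`: `trace` (one row per
#'   evaluation), `X`, `E_raw`, `E_transformed`, `gp` (final surrogate),
#'   `converged_at` (iteration or `NA`), `fraction_transformed`, `config`.
#' @export
run_search <- function(calculator, config = search_config(), model = NULL,
                       ndim = NULL, refit_every_after = 200,
                       track_prediction = TRUE, verbose = FALSE) {
  N <- if (!is.null(model)) length(model$dihedrals)
       else calculator$dim %||% ndim
  if (is.null(N)) stop("cannot determine search dimension", call. = FALSE)
  n_init <- config$n_init %||% max(5L, 2L * N)
  stopifnot(config$budget >= n_init)
  set.seed(config$seed)

  evaluate <- function(t) {
    val <- tryCatch(eval_torsion_energy(calculator, t, model),
                    error = function(e) NA_real_)
    if (!is.finite(val)) NA_real_ else val
  }

  X <- wrap_angle(lhs::randomLHS(n_init, N) * 360 - 180)
  E_raw <- apply(X, 1, evaluate)

  budget <- config$budget
  pred <- matrix(NA_real_, budget, N)
  pred_E <- rep(NA_real_, budget)
  pred_E_raw <- rep(NA_real_, budget)
  gp <- NULL
  hyp <- NULL
  prev_pred <- NULL

  fit_data <- function(E_raw) {
    fin <- is.finite(E_raw)
    base <- min(E_raw[fin])
    Erel <- E_raw - base
    # failed evaluations: treated as lying far above the cutoff
    Erel[!fin] <- max(config$e_cut * 10,
                      if (any(fin)) max(Erel[fin]) * 2 else 0) + 10
    Et <- transform_energy(Erel, config$e_cut, config$continuous_transform)
    list(Et = Et, base = base, damped = Erel > config$e_cut)
  }

  for (it in seq.int(n_init, budget)) {
    fd <- fit_data(E_raw)
    refit <- nrow(X) <= refit_every_after || it %% 10L == 0L
    gp <- gp_fit(X, fd$Et, optimize = refit, init = hyp)
    hyp <- list(lengthscales = gp$lengthscales, sigma_f = gp$sigma_f)
    if (track_prediction) {
      pm <- predict_global_minimum(gp, extra_starts = prev_pred)
      prev_pred <- rbind(pm$x)
      pred[it, ] <- pm$x
      pred_E[it] <- pm$value
      pred_E_raw[it] <-
        inverse_transform_energy(pm$value, config$e_cut,
                                 config$continuous_transform) + fd$base
    }
    if (it == budget) break
    x_next <- next_acquisition(gp, iteration = it + 1L)
    e_next <- evaluate(x_next)
    if (verbose)
      message(sprintf("[seed %d] iteration %d: acquired (%s) -> E = %s eV",
                      config$seed, it + 1L,
                      paste(sprintf("%.1f", x_next), collapse = ", "),
                      format(e_next)))
    X <- rbind(X, x_next)
    E_raw <- c(E_raw, e_next)
  }

  fd <- fit_data(E_raw)
  best_E <- cummin(ifelse(is.finite(E_raw), E_raw, Inf))
  trace <- data.frame(iteration = seq_len(nrow(X)))
  for (j in seq_len(N)) trace[[paste0("d", j)]] <- X[, j]
  trace$E_raw <- E_raw
  trace$E_transformed <- fd$Et
  trace$transformed <- fd$damped
  trace$best_E <- best_E
  for (j in seq_len(N)) trace[[paste0("pred_d", j)]] <- pred[seq_len(nrow(X)), j]
  trace$pred_E <- pred_E[seq_len(nrow(X))]
  trace$pred_E_raw <- pred_E_raw[seq_len(nrow(X))]

  res <- list(trace = trace, X = X, E_raw = E_raw, E_transformed = fd$Et,
              gp = gp, config = config, ndim = N,
              fraction_transformed = mean(fd$damped),
              n_failed = sum(!is.finite(E_raw)))
  res$converged_at <- check_convergence(trace, config)
  class(res) <- "search_result"
  res
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(paste0(
    "search_result: %d evaluations in %dD; best E %.6g eV; ",
    "converged at %s; %.2g%% damped acquisitions\n"),
    nrow(x$X), x$ndim, min(x$E_raw, na.rm = TRUE),
    ifelse(is.na(x$converged_at), "never", x$converged_at),
    100 * x$fraction_transformed))
  invisible(x)
}

#' Windowed convergence check of the predicted global minimum
#'
#' The search is converged at the first iteration `i` such that, over the
#' window of iterations ending at `i`, the predicted global-minimum
#' energy varies by less than `de_tol` and every predicted dihedral varies
#' by less than `dd_tol` (periodic distance).
#'
#' @param trace Trace data frame from [run_search()] (columns `pred_E`
#'   and `pred_d*`).
#' @param config A [search_config()] supplying `de_tol`, `dd_tol` and
#'   `window`.
#' @return The convergence iteration, or `NA` if never satisfied.
#' @export
check_convergence <- function(trace, config) {
  stopifnot(nrow(trace) >= 1)
  w <- config$window
  pcols <- grep("^pred_d", names(trace))
  for (i in seq_len(nrow(trace))) {
    if (i < w) next
    rows <- (i - w + 1L):i
    pe <- trace$pred_E[rows]
    if (any(is.na(pe))) next
    if (diff(range(pe)) >= config$de_tol) next
    ok <- TRUE
    for (j in pcols) {
      v <- trace[[j]][rows]
      spread <- max(outer(v, v, periodic_distance))
      if (spread >= config$dd_tol) { ok <- FALSE; break }
    }
    if (ok) return(i)
  }
  NA_integer_
}
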
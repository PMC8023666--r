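# Extraction of all local minima of the learned surrogate by multi-start
# L-BFGS minimization of the posterior mean, followed by duplicate purging.
# The surrogate and its gradients are cheap, so every acquisition location
# can serve as a start: models built from more data carry more basins, and
# dense starting improves the chance of visiting each one.

#' Extract local minima of the surrogate posterior mean
#'
#' Runs an L-BFGS minimization of the posterior mean from every start
#' point (default: all training inputs), with periodic wrapping. A
#' candidate qualifies as a minimum when the posterior-mean gradient norm
#' at the terminus is below `grad_tol`; non-converged starts are counted
#' and excluded.
#'
#' @param model Fitted `surrogate_gp`.
#' @param starts Matrix of start points (degrees), one per row; defaults
#'   to the model's training inputs (the acquisition locations).
#' @param grad_tol Gradient-norm tolerance defining "is a minimum"
#'   (eV/degree, default 1e-4).
#' @return Data frame of candidates with columns `d1..dN`, `energy`
#'   (surrogate scale, eV), `start` (index of the originating start) and
#'   `grad_norm`, sorted by energy; the number of excluded starts is in
#'   `attr(, "n_failed")`.
#' @export
extract_minima <- function(model, starts = NULL, grad_tol = 1e-4) {
  if (!inherits(model, "surrogate_gp"))
    stop("extract_minima: model is not a fitted surrogate_gp", call. = FALSE)
  if (is.null(starts)) starts <- model$X
  starts <- rbind(starts)
  N <- ncol(model$X)
  stopifnot(ncol(starts) == N)
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ],
                   fn = function(t) gp_posterior(model, t)$mean,
                   gr = function(t) gp_posterior_gradient(model, t),
                   method = "L-BFGS-B",
                   control = list(maxit = 300, factr = 1e4)),
      error = function(e) NULL)
    gn <- if (is.null(res)) Inf
          else sqrt(sum(gp_posterior_gradient(model, res$par)^2))
    if (is.null(res) || gn >= grad_tol) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <-
      c(wrap_angle(res$par), res$value, i, gn)
  }
  out <- as.data.frame(do.call(rbind, rows))
  if (nrow(out))
    names(out) <- c(paste0("d", seq_len(N)), "energy", "start", "grad_norm")
  else
    out <- stats::setNames(
      as.data.frame(matrix(numeric(0), 0, N + 3)),
      c(paste0("d", seq_len(N)), "energy", "start", "grad_norm"))
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

torsion_columns <- function(df) grep("^d[0-9]+$", names(df), value = TRUE)

#' Purge duplicate minimum candidates
#'
#' Greedy clustering in ascending energy order: a candidate is a duplicate
#' of an already-kept representative when every dihedral differs by less
#' than `d_tol` (periodic distance) and the energies differ by less than
#' `e_tol`. The lowest-energy representative of each cluster is kept, so
#' the result is deterministic and idempotent.
#'
#' @param candidates Data frame from [extract_minima()] (columns `d*` and
#'   `energy`).
#' @param d_tol Angular duplicate threshold, degrees (default 15; merges
#'   numerical jitter but keeps chemically distinct rotamers apart).
#' @param e_tol Energy duplicate threshold, eV (default 0.01).
#' @return Data frame of unique minima sorted ascending by energy.
#' @export
purge_duplicates <- function(candidates, d_tol = 15, e_tol = 0.01) {
  stopifnot(d_tol > 0, e_tol > 0)
  dc <- torsion_columns(candidates)
  cand <- candidates[order(candidates$energy), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (k in keep) {
      ang_close <- all(periodic_distance(
        as.numeric(cand[i, dc]), as.numeric(cand[k, dc])) < d_tol)
      if (ang_close && abs(cand$energy[i] - cand$energy[k]) < e_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Energy-versus-conformer-index convergence curves
#'
#' The convergence indicator for the low-energy part of the PES: for each
#' search budget, the minima energies are sorted ascending and expressed
#' relative to that budget's own minimum; the offset of each budget's
#' minimum relative to a reference budget is reported separately (a
#' non-zero offset means the cheaper budget found the wrong global
#' minimum). Consecutive budgets are compared index-by-index below an
#' energy ceiling, and the maximum deviation is returned: once the curves
#' stop moving below the ceiling, the low-energy minima are converged.
#'
#' @param minima_by_budget Named list (names = budgets) of either numeric
#'   energy vectors or data frames with an `energy` column.
#' @param reference Name or index of the reference budget (default: the
#'   last one).
#' @param ceiling Energy ceiling below which curves are compared, eV
#'   (default 0.25).
#' @return List with `curves` (per-budget sorted relative energies),
#'   `min_offsets` (each budget's minimum relative to the reference
#'   minimum, eV), and `deviations` (max index-wise deviation below the
#'   ceiling between consecutive budgets; named "b1->b2").
#' @export
energy_vs_index_curve <- function(minima_by_budget, reference = NULL,
                                  ceiling = 0.25) {
  stopifnot(length(minima_by_budget) >= 1)
  energies <- lapply(minima_by_budget, function(m)
    sort(if (is.data.frame(m)) m$energy else as.numeric(m)))
  if (any(!vapply(energies, length, 1L)))
    return(list(curves = lapply(energies, function(e) numeric(0)),
                min_offsets = NULL, deviations = NULL))
  if (is.null(reference)) reference <- length(energies)
  ref_min <- min(energies[[reference]])
  curves <- lapply(energies, function(e) e - min(e))
  min_offsets <- vapply(energies, function(e) min(e) - ref_min, numeric(1))
  deviations <- NULL
  if (length(curves) > 1) {
    deviations <- numeric(length(curves) - 1)
    nms <- names(curves) %||% as.character(seq_along(curves))
    for (i in seq_len(length(curves) - 1)) {
      a <- curves[[i]]; b <- curves[[i + 1]]
      n <- min(length(a), length(b))
      sel <- pmin(a[seq_len(n)], b[seq_len(n)]) <= ceiling
      deviations[i] <- if (any(sel)) max(abs(a[seq_len(n)] - b[seq_len(n)])[sel])
                       else 0
    }
    names(deviations) <- paste0(nms[-length(nms)], "->", nms[-1])
  }
  list(curves = curves, min_offsets = min_offsets, deviations = deviations)
}
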
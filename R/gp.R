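# Gaussian-process regression over periodic torsion space.
#
# Kernel: product over dimensions of the exp-sine-squared periodic kernel
# with the period fixed at 360 degrees,
#   k(x, y) = sigma_f^2 prod_j exp(-2 sin^2(pi (x_j - y_j)/360) / s_j^2),
# with s_j = 2 pi l_j / 360 so that the per-dimension lengthscale l_j is
# expressed in degrees (for separations much smaller than the period the
# kernel reduces to the squared-exponential exp(-d^2 / (2 l^2))).
# Hyperparameters (lengthscales, signal sd) are fitted by maximizing the
# log marginal likelihood from a fixed multi-start schedule; observation
# noise is a small fixed numerical floor because the energy backends are
# deterministic.

kernel_state <- function(lengthscales) 2 * pi * lengthscales / 360

#' Evaluate the periodic kernel
#'
#' @param hyp List with `lengthscales` (degrees, one per dimension) and
#'   `sigma_f` (signal standard deviation, eV).
#' @param x,y Torsion vectors (degrees) or matrices with one point per row.
#' @return Covariance matrix (eV^2), `nrow(x)` by `nrow(y)`.
#' @export
kernel_eval <- function(hyp, x, y) {
  x <- rbind(x); y <- rbind(y)
  if (ncol(x) != ncol(y))
    stop("kernel_eval: dimension mismatch (", ncol(x), " vs ", ncol(y), ")",
         call. = FALSE)
  s <- kernel_state(hyp$lengthscales)
  K <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(ncol(x))) {
    D <- outer(x[, j], y[, j], `-`)
    K <- K - 2 * sin(pi * D / 360)^2 / s[j]^2
  }
  hyp$sigma_f^2 * exp(K)
}

gp_chol <- function(Kf, noise_var, sigma_f) {
  n <- nrow(Kf)
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    K <- Kf + diag(noise_var + jit * sigma_f^2, n)
    L <- tryCatch(t(chol(K)), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
  }
  stop("Gram matrix is singular even after jitter escalation", call. = FALSE)
}

# Value and gradient share one factorization per theta; optim calls fn and
# gr at the same points, so the last evaluation is cached.
gp_nll_cached <- function(X, yc, noise_var) {
  last_theta <- NULL
  last <- NULL
  function(theta) {
    if (!is.null(last_theta) && identical(theta, last_theta)) return(last)
    out <- gp_neg_log_ml(theta, X, yc, noise_var)
    last_theta <<- theta
    last <<- out
    out
  }
}

gp_neg_log_ml <- function(theta, X, yc, noise_var) {
  N <- ncol(X)
  hyp <- list(lengthscales = exp(theta[1:N]), sigma_f = exp(theta[N + 1]))
  Kf <- kernel_eval(hyp, X, X)
  ch <- tryCatch(gp_chol(Kf, noise_var, hyp$sigma_f),
                 error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, N + 1)))
  L <- ch$L
  alpha <- backsolve(t(L), forwardsolve(L, yc))
  nll <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) +
    0.5 * length(yc) * log(2 * pi)
  # grad: -0.5 tr((alpha alpha' - K^-1) dK/dtheta)
  Kinv <- chol2inv(t(L))
  A <- tcrossprod(alpha) - Kinv
  s <- kernel_state(hyp$lengthscales)
  g <- numeric(N + 1)
  for (j in seq_len(N)) {
    D <- outer(X[, j], X[, j], `-`)
    dK <- Kf * (4 * sin(pi * D / 360)^2 / s[j]^2)
    g[j] <- -0.5 * sum(A * dK)
  }
  g[N + 1] <- -0.5 * sum(A * (2 * Kf))
  list(value = nll, grad = g)
}

#' Fit a periodic-kernel GP surrogate to energy samples
#'
#' @param X Matrix of torsion vectors, one sample per row (degrees).
#' @param y Energies (eV; typically transformed relative energies during a
#'   search).
#' @param noise_var Fixed observation-noise variance (eV^2). The default is
#'   the square of a 1e-4 eV numerical floor.
#' @param optimize Optimize hyperparameters by marginal likelihood (default
#'   `TRUE`); when `FALSE` the initial values are used as-is.
#' @param init Optional list with `lengthscales` and `sigma_f` used as a
#'   warm start (and as the values when `optimize = FALSE`).
#' @return Object of class `surrogate_gp`.
#' @export
gp_fit <- function(X, y, noise_var = 1e-8, optimize = TRUE, init = NULL) {
  X <- rbind(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("gp_fit: non-finite inputs", call. = FALSE)
  X <- wrap_angle(X)
  N <- ncol(X)
  m <- mean(y)
  yc <- y - m
  sy <- max(stats::sd(y), 1e-6)
  if (optimize) {
    # fixed multi-start schedule: a warm start from the previous fit plus a
    # mid-range cold start; the full cold-start sweep runs when no warm
    # start exists (first fit of a search).
    starts <- list()
    if (!is.null(init))
      starts[[1L]] <- c(log(init$lengthscales), log(init$sigma_f))
    if (is.null(init))
      for (l0 in c(40, 90, 160))
        starts[[length(starts) + 1L]] <- c(rep(log(l0), N), log(sy))
    else
      starts[[length(starts) + 1L]] <- c(rep(log(90), N), log(sy))
    lower <- c(rep(log(5), N), log(1e-3 * sy))
    upper <- c(rep(log(720), N), log(1e3 * sy))
    nll <- gp_nll_cached(X, yc, noise_var)
    best <- NULL
    for (st in starts) {
      st <- pmin(pmax(st, lower), upper)
      fit <- tryCatch(
        stats::optim(st,
                     fn = function(th) nll(th)$value,
                     gr = function(th) nll(th)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 50)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best))
      stop("hyperparameter optimization failed from every start", call. = FALSE)
    theta <- best$par
    hyp <- list(lengthscales = exp(theta[1:N]), sigma_f = exp(theta[N + 1]))
  } else {
    hyp <- init %||% list(lengthscales = rep(90, N), sigma_f = sy)
  }
  Kf <- kernel_eval(hyp, X, X)
  ch <- gp_chol(Kf, noise_var, hyp$sigma_f)
  alpha <- backsolve(t(ch$L), forwardsolve(ch$L, yc))
  structure(list(X = X, y = y, mean = m, lengthscales = hyp$lengthscales,
                 sigma_f = hyp$sigma_f, noise_var = noise_var,
                 jitter = ch$jitter, L = ch$L, alpha = alpha),
            class = "surrogate_gp")
}

#' @export
print.surrogate_gp <- function(x, ...) {
  cat(sprintf(
    "surrogate_gp: %d samples, %dD; lengthscales [%s] deg, sigma_f %.4g eV\n",
    nrow(x$X), ncol(x$X), paste(sprintf("%.1f", x$lengthscales),
                                collapse = ", "), x$sigma_f))
  invisible(x)
}

#' Posterior mean and variance of a fitted surrogate
#'
#' @param model A fitted `surrogate_gp`.
#' @param x Torsion vector (degrees) or matrix with one point per row.
#' @return List with `mean` (eV) and `variance` (eV^2, clamped at 0),
#'   vectors over the rows of `x`.
#' @export
gp_posterior <- function(model, x) {
  if (!inherits(model, "surrogate_gp"))
    stop("gp_posterior: model is not a fitted surrogate_gp", call. = FALSE)
  x <- rbind(x)
  hyp <- list(lengthscales = model$lengthscales, sigma_f = model$sigma_f)
  ks <- kernel_eval(hyp, model$X, x)          # n_train x n_query
  mu <- model$mean + drop(crossprod(ks, model$alpha))
  v <- forwardsolve(model$L, ks)
  var <- pmax(model$sigma_f^2 - colSums(v^2), 0)
  list(mean = unname(mu), variance = unname(var))
}

#' @export
predict.surrogate_gp <- function(object, newdata, ...) gp_posterior(object, newdata)

# d k(x, X_i) / d x_j for a single query point: n_train x N matrix.
kernel_grad_query <- function(model, x) {
  hyp <- list(lengthscales = model$lengthscales, sigma_f = model$sigma_f)
  ks <- drop(kernel_eval(hyp, model$X, x))    # length n_train
  s <- kernel_state(model$lengthscales)
  N <- ncol(model$X)
  dk <- matrix(0, nrow(model$X), N)
  for (j in seq_len(N)) {
    D <- x[j] - model$X[, j]
    dk[, j] <- -ks * (2 * pi / (360 * s[j]^2)) * sin(2 * pi * D / 360)
  }
  list(ks = ks, dk = dk)
}

#' Analytic gradient of the posterior mean
#'
#' @param model A fitted `surrogate_gp`.
#' @param x A single torsion vector (degrees).
#' @return Gradient vector, eV per degree; 360-degree periodic in every
#'   coordinate.
#' @export
gp_posterior_gradient <- function(model, x) {
  if (!inherits(model, "surrogate_gp"))
    stop("gp_posterior_gradient: model is not a fitted surrogate_gp",
         call. = FALSE)
  x <- as.numeric(x)
  kg <- kernel_grad_query(model, x)
  drop(crossprod(kg$dk, model$alpha))
}

# Gradient of the posterior variance at a single point (eV^2/deg).
gp_variance_gradient <- function(model, x) {
  kg <- kernel_grad_query(model, x)
  Kinv_ks <- backsolve(t(model$L), forwardsolve(model$L, kg$ks))
  drop(-2 * crossprod(kg$dk, Kinv_ks))
}

#' Save / load a surrogate checkpoint
#'
#' Serializes the training data and hyperparameters as JSON so a search
#' can resume; the factorization is rebuilt on load.
#'
#' @param model A fitted `surrogate_gp`.
#' @param path Checkpoint path (JSON).
#' @return `path` invisibly; `gp_load` returns the restored model.
#' @export
gp_save <- function(model, path) {
  jsonlite::write_json(
    list(X = model$X, y = model$y,
         lengthscales = model$lengthscales, sigma_f = model$sigma_f,
         noise_var = model$noise_var),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gp_save
#' @export
gp_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(unlist(x$X), ncol = length(x$lengthscales), byrow = TRUE)
  gp_fit(X, x$y, noise_var = x$noise_var, optimize = FALSE,
         init = list(lengthscales = x$lengthscales, sigma_f = x$sigma_f))
}
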
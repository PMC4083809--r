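#' Chan-Vese baseline segmentation
#'
#' Independent implementation of the piecewise-constant two-phase model: the
#' gradient flow
#' \eqn{\partial\phi/\partial t = \delta_\epsilon(\phi)[\mu\,
#' \mathrm{div}(\nabla\phi/|\nabla\phi|) - (I-c_1)^2 + (I-c_2)^2]}
#' with the region means \eqn{c_1, c_2} recomputed each iteration and
#' \eqn{\lambda_1 = \lambda_2 = 1}. Deliberately self-contained (its own
#' Heaviside, means and update code): it serves as an equivalence oracle for
#' the hybrid evolution with the local term switched off, where `mu` plays
#' the role of the hybrid's length weight `omega`.
#'
#' @inheritParams evolve
#' @param mu Length-penalty weight.
#' @param dt Time step.
#' @param eps Heaviside regularization width.
#' @param max_iters Iteration cap.
#' @param tol Converged when the fraction of label changes over the last
#'   `check_every` iterations drops below this.
#' @param check_every Iterations between convergence checks.
#' @return A `levelset_evolution` object (model `"cv"`). Its energy trace
#'   stores the CV fitting residual in `global`, zeros in the local columns.
#' @export
cv_evolve <- function(I, phi0, mu = 0.1, dt = 0.45, eps = 1,
                      max_iters = 2000, tol = 1e-4, check_every = 20) {
  check_same_shape(I, phi0)
  stopifnot(dt > 0, eps > 0, mu >= 0, max_iters >= 0)
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z / eps))
  D <- function(z) (1 / pi) * eps / (eps^2 + z^2)
  dr <- function(m) {
    nr <- nrow(m)
    (m[c(2:nr, nr), , drop = FALSE] - m[c(1, 1:(nr - 1)), , drop = FALSE]) / 2
  }
  dc <- function(m) {
    nc <- ncol(m)
    (m[, c(2:nc, nc), drop = FALSE] - m[, c(1, 1:(nc - 1)), drop = FALSE]) / 2
  }
  kap <- function(p) {
    px <- dc(p); py <- dr(p)
    nrm <- sqrt(px^2 + py^2 + 1e-8^2)
    dc(px / nrm) + dr(py / nrm)
  }
  len <- function(p) sum(D(p) * sqrt(dc(p)^2 + dr(p)^2))
  fit <- function(p, c1, c2) {
    h <- H(p)
    sum(h * (I - c1)^2 + (1 - h) * (I - c2)^2)
  }
  rec <- function(p, it) {
    h <- H(p)
    c1 <- sum(I * h) / sum(h); c2 <- sum(I * (1 - h)) / sum(1 - h)
    l <- len(p)
    tibble::tibble(iteration = as.integer(it),
                   total = fit(p, c1, c2) + mu * l,
                   global = fit(p, c1, c2), local_printed = 0,
                   local_residual = 0, length = l)
  }

  phi <- phi0
  npix <- length(I)
  trace <- list(rec(phi, 0L))
  mask_ref <- phi > 0
  converged <- FALSE
  iters <- 0L
  max_iters <- as.integer(max_iters)
  while (iters < max_iters) {
    h <- H(phi)
    c1 <- sum(I * h) / sum(h)
    c2 <- sum(I * (1 - h)) / sum(1 - h)
    phi_prev <- phi
    phi <- phi + dt * (D(phi) * (mu * kap(phi) - (I - c1)^2 + (I - c2)^2))
    if (!all(is.finite(phi))) {
      stop("non-finite values in the CV update; try a smaller dt", call. = FALSE)
    }
    iters <- iters + 1L
    if (iters %% check_every == 0 || iters == max_iters) {
      trace[[length(trace) + 1L]] <- rec(phi, iters)
      mask_now <- phi > 0
      changed <- sum(mask_now != mask_ref)
      ahead <- sum(((phi + (max_iters - iters) * (phi - phi_prev)) > 0) != mask_now)
      mask_ref <- mask_now
      if (iters %% check_every == 0 &&
          changed < tol * npix && ahead < tol * npix) {
        converged <- TRUE
        break
      }
    }
  }
  params <- hybrid_params(alpha = 1, beta = 0, omega = mu, dt = dt,
                          eps = eps, max_iters = max_iters, tol = tol,
                          check_every = check_every)
  res <- new_levelset_evolution(phi, do.call(rbind, trace), iters, converged,
                                params, "cv")
  res
}

#' Local-only baseline segmentation
#'
#' The hybrid evolution with the global weight forced to zero: only the
#' ball-localized statistics and the length penalty drive the contour. This
#' mirrors localized region-based active contours, which segment
#' inhomogeneous objects well but can get trapped in local minima when the
#' initialization is far from parts of the object.
#'
#' @inheritParams evolve
#' @return A `levelset_evolution` object (model `"local"`), bit-identical to
#'   `evolve()` with `alpha = 0`.
#' @export
local_evolve <- function(I, phi0, params = hybrid_params()) {
  stopifnot(inherits(params, "hybrid_params"))
  p <- params
  p$alpha <- 0
  if (p$beta == 0 && p$omega == 0) {
    stop("local_evolve needs beta or omega positive", call. = FALSE)
  }
  res <- evolve(I, phi0, p)
  res$model <- "local"
  res
}
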
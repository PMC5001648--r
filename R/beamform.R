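#' Sample covariance of a recording
#'
#' Demeaned per-channel sample covariance `C = cov(m)` with the `N - 1`
#' divisor; the data covariance approximating `<m m^T>` in the beamformer.
#'
#' @param recording a `meg_recording` (or channels x samples matrix).
#' @return symmetric positive semidefinite channels x channels matrix.
#' @export
estimate_covariance <- function(recording) {
  m <- if (inherits(recording, "meg_recording")) recording$data else
    as.matrix(recording)
  nsamp <- ncol(m)
  if (nsamp < 2L) stop("need at least 2 samples to estimate a covariance")
  if (nsamp < nrow(m)) {
    warning("fewer samples (", nsamp, ") than channels (", nrow(m),
            "); covariance is rank deficient")
  }
  mc <- m - rowMeans(m)
  cc <- tcrossprod(mc) / (nsamp - 1)
  (cc + t(cc)) / 2
}

#' LCMV beamformer weights
#'
#' Minimum-variance weights with a unit-gain constraint on the (possibly
#' perturbed) lead field used for weight computation:
#' `w = (C + mu Sigma)^-1 l / (l^T (C + mu Sigma)^-1 l)`.
#' The solve uses a Cholesky factorisation of the regularised covariance
#' (never an explicit inverse), falling back to an eigenvalue
#' pseudo-inverse with a warning if the matrix is numerically singular.
#'
#' @param c_mat data covariance (channels x channels).
#' @param lead_field lead-field vector or `lead_field` object used for the
#'   weights (the perturbed one when simulating forward-model error).
#' @param sigma noise model: diagonal matrix, per-channel variance vector,
#'   or scalar variance (`Sigma = sigma * I`).
#' @param mu dimensionless regularisation parameter (default 0.001, small
#'   to maximise spatial resolution).
#' @return a `beamformer_weights` object: `w`, `mu`, plus the achieved
#'   unit gain.
#' @export
compute_weights <- function(c_mat, lead_field, sigma, mu = 0.001) {
  l <- lf_values(lead_field)
  if (all(l == 0)) stop("lead field is zero: unit-gain constraint infeasible")
  cr <- regularised_covariance(c_mat, sigma, mu)
  w0 <- spd_solve(cr, l)
  gain <- sum(l * w0)
  w <- w0 / gain
  structure(list(w = as.numeric(w), mu = mu, gain = sum(l * w)),
            class = "beamformer_weights")
}

regularised_covariance <- function(c_mat, sigma, mu) {
  n <- nrow(c_mat)
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == n)
    c_mat + mu * sigma
  } else if (length(sigma) == n) {
    c_mat + diag(mu * as.numeric(sigma), n)
  } else if (length(sigma) == 1L) {
    c_mat + diag(mu * as.numeric(sigma), n)
  } else {
    stop("sigma must be a scalar, per-channel vector, or diagonal matrix")
  }
}

# symmetric positive-definite solve via Cholesky, with pseudo-inverse
# fallback; x may be a vector or matrix of right-hand sides
spd_solve <- function(a, x) {
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, forwardsolve(t(ch), x)))
  }
  warning("regularised covariance is numerically singular; ",
          "using an eigenvalue pseudo-inverse")
  ei <- eigen(a, symmetric = TRUE)
  pos <- ei$values > max(ei$values) * 1e-12
  ei$vectors[, pos, drop = FALSE] %*%
    ((t(ei$vectors[, pos, drop = FALSE]) %*% x) / ei$values[pos])
}

#' Reconstruct a source time course
#'
#' `q_hat = w^T m`, the beamformer estimate of the source amplitude at the
#' weight's target location, in A m.
#'
#' @param weights a `beamformer_weights` (or numeric weight vector).
#' @param recording a `meg_recording` (or channels x samples matrix).
#' @return numeric vector of length N.
#' @export
reconstruct_source <- function(weights, recording) {
  w <- if (inherits(weights, "beamformer_weights")) weights$w else
    as.numeric(weights)
  m <- if (inherits(recording, "meg_recording")) recording$data else
    as.matrix(recording)
  stopifnot(length(w) == nrow(m))
  as.numeric(crossprod(w, m))
}

# --- internal correlation algebra on sample moments ------------------------
#
# For linear reconstructions q_hat = w^T m, Pearson correlations are exact
# functions of the demeaned sample moments: these helpers are the moment-
# domain equivalents of cor() on explicit time courses.

# cor(q_s, w^T m) from moments
moment_recon_cor <- function(mom, w, s) {
  num <- sum(w * mom$s_mq[, s])
  den <- sqrt(mom$s_qq[s, s] * drop(crossprod(w, mom$C %*% w)))
  if (den == 0) stop("zero variance in correlation")
  num / den
}

# cor(w1^T m, w2^T m) from moments
moment_leak_cor <- function(mom, w1, w2) {
  cw2 <- mom$C %*% w2
  num <- drop(crossprod(w1, cw2))
  den <- sqrt(drop(crossprod(w1, mom$C %*% w1)) * drop(crossprod(w2, cw2)))
  if (den == 0) stop("zero variance in correlation")
  num / den
}

# --- two-source population-covariance evaluator ----------------------------
#
# In the N -> infinity limit everything lives in span{l_k, l_n}; leakage and
# per-source reconstruction correlations reduce to 2x2 algebra over the
# Gram matrix, vectorised over candidate second sources. Unit-tested
# against the generic Cholesky path.
two_source_population_metrics <- function(l_k, l_cand, sigma_q, sigma_e,
                                          mu = 0.001) {
  l_cand <- as.matrix(l_cand)
  a <- sum(l_k * l_k)
  b <- as.numeric(crossprod(l_cand, l_k))
  cc <- colSums(l_cand * l_cand)
  s <- sigma_e^2 * (1 + mu)
  q2 <- sigma_q^2

  # u = (s I + q2 G)^-1 e1 / e2, with G = [[a, b], [b, c]]
  g11 <- s + q2 * a
  g12 <- q2 * b
  g22 <- s + q2 * cc
  det <- g11 * g22 - g12 * g12
  uk1 <- g22 / det; uk2 <- -g12 / det       # weights for l_k (unnormalised)
  un1 <- -g12 / det; un2 <- g11 / det       # weights for l_n

  # x^T C y = u^T M v with M = sigma_e^2 G + q2 G G
  m11 <- sigma_e^2 * a + q2 * (a * a + b * b)
  m12 <- sigma_e^2 * b + q2 * (a * b + b * cc)
  m22 <- sigma_e^2 * cc + q2 * (b * b + cc * cc)

  vkk <- uk1 * (m11 * uk1 + m12 * uk2) + uk2 * (m12 * uk1 + m22 * uk2)
  vnn <- un1 * (m11 * un1 + m12 * un2) + un2 * (m12 * un1 + m22 * un2)
  vkn <- uk1 * (m11 * un1 + m12 * un2) + uk2 * (m12 * un1 + m22 * un2)
  leakage <- vkn / sqrt(vkk * vnn)

  # cor(q_k, q_hat_k) = sigma_q * u_k^T G e1 / sqrt(u_k^T M u_k)
  gk <- uk1 * a + uk2 * b
  gn <- un1 * b + un2 * cc
  r_k <- sigma_q * gk / sqrt(vkk)
  r_n <- sigma_q * gn / sqrt(vnn)
  list(leakage = leakage, r_k = r_k, r_n = r_n)
}
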
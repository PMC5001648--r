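#' Perturb a lead field within the orthogonal hyperplane
#'
#' Forward-model error is injected as a vector `delta_l` confined to the
#' hyperplane orthogonal to the true lead field `l`: a standard Gaussian
#' vector `r` is projected onto the hyperplane and scaled,
#' `delta_l = xi * (r - l (l^T l)^-1 l^T r)`, and the erroneous forward
#' field is `l_hat = l + delta_l`. Because `delta_l` is orthogonal to `l`,
#' `|l_hat|^2 = |l|^2 + |delta_l|^2` and the fractional error
#' `|delta_l| / |l|` equals `tan` of the angle between `l_hat` and `l`.
#'
#' @param l true lead field (numeric vector or `lead_field`).
#' @param xi perturbation scale (finite).
#' @param seed integer seed for the random direction `r`.
#' @return list with `l_hat` (a `lead_field` of flavour "perturbed") and
#'   `result`, a `perturbation_result`: `delta`, `xi`, `fraction`
#'   (`|delta|/|l|`), `alpha` (angle between `l_hat` and `delta`, rad),
#'   `beta` (angle between `l` and `r`, rad), `seed`.
#' @export
perturb_lead_field <- function(l, xi, seed) {
  lv <- lf_values(l)
  ll <- sum(lv^2)
  if (ll == 0) stop("cannot perturb a zero lead field")
  stopifnot(is.finite(xi))
  pr <- hyperplane_projection(lv, seed)
  delta <- xi * pr$p
  lhat <- lv + delta
  nd <- sqrt(sum(delta^2))
  res <- structure(list(delta = delta, xi = xi,
                        fraction = nd / sqrt(ll),
                        alpha = vec_angle(lhat, delta),
                        beta = pr$beta,
                        seed = as.integer(seed)),
                   class = "perturbation_result")
  list(l_hat = new_lead_field(lhat,
                              source = if (inherits(l, "lead_field"))
                                l$source else NA_integer_,
                              kind = if (inherits(l, "lead_field")) l$kind
                              else NA_character_,
                              flavour = "perturbed", delta = delta),
       result = res)
}

# projection of a seeded standard Gaussian vector onto the hyperplane
# orthogonal to l; redraws (with incremented child stream) in the
# probability-zero event that r is parallel to l
hyperplane_projection <- function(lv, seed) {
  ll <- sum(lv^2)
  for (try in 0:9) {
    r <- with_seed(child_seed(seed, "r", try), rnorm(length(lv)))
    p <- r - lv * (sum(lv * r) / ll)
    if (sum(p^2) > 0) {
      if (try > 0L) {
        message("random vector parallel to lead field; redrew (attempt ",
                try + 1L, ")")
      }
      return(list(p = p, beta = vec_angle(lv, r)))
    }
  }
  stop("could not draw a random vector off the lead-field axis")
}

vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

#' Calibrate the perturbation scale for an exact fractional error
#'
#' Because `delta_l` is linear in `xi`, the scale achieving a requested
#' fractional error for a given random draw is
#' `xi = fraction * |l| / |P r|`, where `P r` is the unscaled hyperplane
#' projection for that seed. [perturb_lead_field()] with the returned `xi`
#' and the same seed reproduces the target fraction to 1e-10 relative.
#'
#' @param l true lead field (numeric vector or `lead_field`).
#' @param target_fraction requested `|delta_l| / |l|` (>= 0).
#' @param seed integer seed (must match the later perturbation call).
#' @return scalar `xi`.
#' @export
calibrate_fractional_error <- function(l, target_fraction, seed) {
  stopifnot(target_fraction >= 0)
  lv <- lf_values(l)
  if (sum(lv^2) == 0) stop("cannot perturb a zero lead field")
  if (target_fraction == 0) return(0)
  pr <- hyperplane_projection(lv, seed)
  target_fraction * sqrt(sum(lv^2)) / sqrt(sum(pr$p^2))
}
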
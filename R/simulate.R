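#' Source configuration for simulated recordings
#'
#' Describes the dipoles feeding a simulated recording: vertex indices into
#' a source space, per-source Gaussian amplitude standard deviations (A m)
#' and roles, plus the sampling scheme. `N = f * duration` samples are
#' generated.
#'
#' @param vertices integer vertex indices.
#' @param sigma_q amplitude standard deviation(s), A m (default 5 nAm).
#' @param role per-source role, "target" or "interferer".
#' @param duration recording length (s, default 600).
#' @param f sampling frequency (Hz, default 600).
#' @param n_samples optional explicit sample count; overrides `duration`
#'   (`duration = n_samples / f`).
#' @return a `source_config` list with `N` filled in.
#' @export
source_config <- function(vertices, sigma_q = 5e-9, role = "target",
                          duration = 600, f = 600, n_samples = NULL) {
  n <- length(vertices)
  sigma_q <- rep_len(sigma_q, n)
  role <- rep_len(role, n)
  if (!is.null(n_samples)) {
    nsamp <- as.integer(n_samples)
    duration <- nsamp / f
  } else {
    nsamp <- as.integer(round(f * duration))
  }
  stopifnot(nsamp >= 1L, all(sigma_q >= 0), all(role %in% c("target",
                                                            "interferer")))
  structure(list(vertices = as.integer(vertices), sigma_q = sigma_q,
                 role = role, duration = duration, f = f, N = nsamp),
            class = "source_config")
}

#' Gaussian dipole time course
#'
#' Zero-mean i.i.d. Gaussian source amplitude sequence, the elementary
#' source model of all experiments (sources are temporally white, so two
#' independent draws are orthogonal in expectation).
#'
#' @param n number of samples (>= 2).
#' @param sigma_q standard deviation (A m).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
gaussian_source <- function(n, sigma_q, seed) {
  stopifnot(n >= 2L, sigma_q >= 0)
  with_seed(seed, rnorm(n, 0, sigma_q))
}

# draw the source matrix (S x N) exactly as simulate_recording does; each
# source is drawn as a contiguous block so the first source's time course
# is identical whether or not further sources are configured (this is what
# makes "interference amplitude zero" reproduce the single-dipole runs at
# matched seeds)
draw_sources <- function(config, seed) {
  s <- length(config$vertices)
  q <- with_seed(seed, {
    out <- matrix(0, s, config$N)
    for (i in seq_len(s)) out[i, ] <- rnorm(config$N)
    out
  })
  q * config$sigma_q
}

#' Simulate a multichannel MEG recording
#'
#' `m = sum_s l_s q_s + e`: each source's Gaussian time course is projected
#' through its lead-field column and i.i.d. Gaussian sensor noise of
#' standard deviation `sigma_e` is added per channel and sample. Source
#' time courses are drawn with R's RNG from `seed`; sensor noise uses the
#' package's fast seeded generator on a child stream of the same seed, so
#' a recording is fully reproducible from `(config, lead_fields, sigma_e,
#' seed)`.
#'
#' @param config a [source_config()].
#' @param lead_fields `n_channels x n_sources` matrix whose columns match
#'   `config$vertices` (T per A m).
#' @param sigma_e sensor noise standard deviation (T, default 50 fT).
#' @param seed integer seed.
#' @return a `meg_recording`: `data` (channels x N, tesla), `sigma_e`,
#'   `seed`, `ground_truth` (sources x N, A m), `config`.
#' @export
simulate_recording <- function(config, lead_fields, sigma_e = 50e-15, seed) {
  l <- as.matrix(lead_fields)
  if (ncol(l) != length(config$vertices)) {
    stop("need one lead-field column per source entry (got ", ncol(l),
         " columns for ", length(config$vertices), " sources)")
  }
  q <- draw_sources(config, seed)
  m <- l %*% q
  if (sigma_e > 0) {
    m <- m + noise_matrix(nrow(l), config$N, sigma_e,
                          child_seed(seed, "noise"))
  }
  structure(list(data = m, sigma_e = sigma_e, seed = as.integer(seed),
                 ground_truth = q, config = config),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("meg_recording: %d channels x %d samples, %d source(s), sigma_e = %.3g fT\n",
              nrow(x$data), ncol(x$data), nrow(x$ground_truth),
              x$sigma_e * 1e15))
  invisible(x)
}

# Demeaned sample second moments of a simulated recording, computed without
# materialising the channels x N data matrix. Algebraically identical to
# forming the recording and taking sample covariances (unit-tested).
# Returns C (sample covariance of m), s_mq (cross-covariance of m with each
# source), s_qq (source sample covariance).
sim_moments <- function(lead_fields, config, sigma_e, seed) {
  l <- as.matrix(lead_fields)
  q <- draw_sources(config, seed)
  nsamp <- config$N
  qc <- q - rowMeans(q)
  s_qq <- tcrossprod(qc) / (nsamp - 1)
  if (sigma_e > 0) {
    # fused draw + BLAS cross products; because qc is row-centred,
    # E qc^T equals the centred cross product exactly
    nm <- .noise_crossmoments(nrow(l), nsamp, sigma_e,
                              child_seed(seed, "noise"), qc)
    ebar <- nm$rowsums / nsamp
    s_ee <- (nm$eet - nsamp * tcrossprod(ebar)) / (nsamp - 1)
    s_eq <- nm$eq / (nsamp - 1)               # n_ch x S
    lq <- l %*% s_qq
    cc <- lq %*% t(l) + l %*% t(s_eq) + s_eq %*% t(l) + s_ee
    s_mq <- lq + s_eq
  } else {
    cc <- l %*% s_qq %*% t(l)
    s_mq <- l %*% s_qq
  }
  list(C = (cc + t(cc)) / 2, s_mq = s_mq, s_qq = s_qq, N = nsamp)
}

# population (N -> infinity) limit of sim_moments
pop_moments <- function(lead_fields, config, sigma_e) {
  l <- as.matrix(lead_fields)
  s_qq <- diag(config$sigma_q^2, length(config$sigma_q))
  lq <- l %*% s_qq
  list(C = lq %*% t(l) + diag(sigma_e^2, nrow(l)), s_mq = lq, s_qq = s_qq,
       N = Inf)
}

#' Select interference ("brain noise") source vertices
#'
#' Five interfering dipoles accompanying a target dipole:
#' * `case = "proximity"`: one random cortex vertex per 6-mm Euclidean
#'   distance shell from the target (0-6, 6-12, 12-18, 18-24, 24-30 mm).
#' * `case = "deep"`: the target must lie 4-6 cm from the nearest on-scalp
#'   sensor; the five interferers are drawn from vertices closer than 4 cm
#'   to it (interference shallower than the source of interest).
#'
#' @param sources a `source_space` (with `depth` computed against
#'   `opm_array` for the deep case).
#' @param target_j target vertex index.
#' @param case "proximity" or "deep".
#' @param opm_array on-scalp array defining sensor distances (used if the
#'   source space has no depths).
#' @param seed integer seed.
#' @return integer vector of 5 interferer vertex indices.
#' @export
select_interferers <- function(sources, target_j,
                               case = c("proximity", "deep"),
                               opm_array = NULL, seed) {
  case <- match.arg(case)
  pos <- sources$positions
  depth <- sources$depth
  if (all(is.na(depth))) {
    if (is.null(opm_array)) stop("need depths or an opm_array")
    depth <- min_sensor_distance(pos, opm_array)
  }
  if (case == "proximity") {
    d <- sqrt(colSums((t(pos) - pos[target_j, ])^2))
    picks <- integer(5L)
    for (k in 1:5) {
      lo <- 0.006 * (k - 1)
      hi <- 0.006 * k
      cand <- which(d > lo & d <= hi & seq_along(d) != target_j)
      cand <- setdiff(cand, picks)
      if (length(cand) == 0L) {
        stop(sprintf("no cortex vertex in the %d-%d mm shell around vertex %d",
                     1000 * lo, 1000 * hi, target_j))
      }
      picks[k] <- with_seed(child_seed(seed, "shell", k),
                            cand[sample.int(length(cand), 1L)])
    }
    picks
  } else {
    if (depth[target_j] < 0.04 || depth[target_j] > 0.06) {
      stop("deep case requires a target 4-6 cm from the nearest sensor ",
           sprintf("(vertex %d is at %.1f cm)", target_j,
                   100 * depth[target_j]))
    }
    cand <- which(depth < 0.04 & seq_along(depth) != target_j)
    if (length(cand) < 5L) stop("fewer than 5 vertices shallower than 4 cm")
    with_seed(child_seed(seed, "deep"), cand[sample.int(length(cand), 5L)])
  }
}

#' Channel-level SNR of a simulated source
#'
#' Defined as the standard deviation of the signal at the
#' maximally affected channel divided by the sensor noise standard
#' deviation, i.e. `sigma_q * max_i |l_i| / sigma_e`.
#'
#' @param lead_field lead-field vector (or `lead_field` object), T per A m.
#' @param sigma_q source amplitude std (A m).
#' @param sigma_e sensor noise std (T); must be > 0.
#' @return scalar SNR.
#' @export
channel_snr <- function(lead_field, sigma_q, sigma_e) {
  stopifnot(sigma_e > 0, sigma_q >= 0)
  sigma_q * max(abs(lf_values(lead_field))) / sigma_e
}
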
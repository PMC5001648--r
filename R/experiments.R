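#' Pearson correlation between two time courses
#'
#' Contract-checking wrapper around the product-moment correlation: inputs
#' must have equal length >= 3 and non-zero variance.
#'
#' @param a,b numeric vectors.
#' @return scalar correlation between -1 and 1.
#' @export
pearson_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  stats::cor(a, b)
}

#' Assemble a simulation study
#'
#' Bundles the head model, source space, sensor arrays, local-sphere fits
#' and precomputed lead-field matrices used by the experiment drivers. By
#' default this is the canonical comparison pair: the helmet gradiometer
#' array (`squid`) and the scalp-projected magnetometer array (`opm`),
#' with source depths measured against the on-scalp sensors.
#'
#' @param head a `head_model` (default: the reference synthetic head).
#' @param patch_radius local-sphere patch radius (m).
#' @param mu default beamformer regularisation.
#' @param squid_args,opm_args extra arguments for [build_squid_array()] and
#'   [build_opm_array()].
#' @return an `opm_study` list: `head`, `sources`, `arrays`, `spheres`,
#'   `leadfields` (T per A m matrices), `mu`.
#' @export
build_study <- function(head = build_synthetic_head(), patch_radius = 0.09,
                        mu = 0.001, squid_args = list(), opm_args = list()) {
  squid <- do.call(build_squid_array, c(list(head), squid_args))
  opm <- do.call(build_opm_array, c(list(squid, head), opm_args))
  sp_squid <- fit_local_spheres(head, squid, patch_radius)
  sp_opm <- fit_local_spheres(head, opm, patch_radius)
  sources <- make_source_space(head, reference_array = opm)
  study <- structure(list(head = head, sources = sources,
                          arrays = list(squid = squid, opm = opm),
                          spheres = list(squid = sp_squid, opm = sp_opm),
                          leadfields = list(
                            squid = leadfield_matrix(sources, squid, sp_squid),
                            opm = leadfield_matrix(sources, opm, sp_opm)),
                          patch_radius = patch_radius, mu = mu),
                     class = "opm_study")
  study
}

#' @export
print.opm_study <- function(x, ...) {
  cat(sprintf("opm_study: %d dipoles; arrays: %s\n",
              nrow(x$sources$positions),
              paste(sprintf("%s (%d ch)", names(x$arrays),
                            vapply(x$arrays, n_channels, 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Add an array to a study
#'
#' Fits local spheres and computes the lead-field matrix for an extra
#' array (e.g. an EEG-layout variant for channel-count experiments).
#'
#' @param study an `opm_study`.
#' @param name name under which the array is stored.
#' @param array a `sensor_array`.
#' @return the augmented study.
#' @export
add_study_array <- function(study, name, array) {
  sp <- fit_local_spheres(study$head, array, study$patch_radius)
  study$arrays[[name]] <- array
  study$spheres[[name]] <- sp
  study$leadfields[[name]] <- leadfield_matrix(study$sources, array, sp)
  study
}

# long-format result row constructor (MetricsTable schema)
metrics_rows <- function(experiment, array, metric, value,
                         vertex = NA_integer_, vertex2 = NA_integer_,
                         distance = NA_real_, fraction = NA_real_,
                         depth_class = NA_character_, bin = NA_integer_,
                         replicate = 1L, seed = NA_integer_) {
  data.frame(experiment = experiment, array = array, metric = metric,
             vertex = vertex, vertex2 = vertex2, distance = distance,
             fraction = fraction, depth_class = depth_class, bin = bin,
             replicate = replicate, seed = seed, value = value)
}

depth_class_of <- function(depth) {
  ifelse(depth < 0.04, "shallow", ifelse(depth <= 0.06, "deep", "very_deep"))
}

#' Single-dipole reconstruction accuracy
#'
#' For each tested vertex and array, simulates a recording with one
#' Gaussian dipole plus sensor noise, beamforms at the true location with
#' the exact lead field, and reports the signed Pearson correlation
#' between simulated and reconstructed time courses. With
#' `point_spread = TRUE` it additionally reconstructs at the vertex's
#' nearest mesh neighbours (|r| versus distance, the spatial point-spread
#' profile).
#'
#' @param study an `opm_study`.
#' @param vertices vertex indices to test.
#' @param arrays names of study arrays to run (default squid + opm).
#' @param n_samples recording length in samples (default 360000, i.e.
#'   600 s at 600 Hz).
#' @param sigma_q dipole amplitude std (A m; default 5 nAm).
#' @param sigma_e sensor noise std (T; default 50 fT).
#' @param seed master seed.
#' @param point_spread also profile the 44 nearest neighbours.
#' @param n_neighbours neighbour count for the point-spread profile.
#' @return a MetricsTable data.frame (`metric` = "r_recon", and
#'   "r_point_spread" rows when requested).
#' @export
run_recon_accuracy <- function(study, vertices,
                               arrays = c("squid", "opm"),
                               n_samples = 360000L, sigma_q = 5e-9,
                               sigma_e = 50e-15, seed = 1L,
                               point_spread = FALSE, n_neighbours = 44L) {
  stopifnot(length(vertices) >= 1L)
  out <- vector("list", length(vertices) * length(arrays))
  i <- 0L
  pos <- study$sources$positions
  for (a in arrays) {
    l_mat <- study$leadfields[[a]]
    for (j in vertices) {
      sj <- child_seed(seed, "recon", a, j)
      cfg <- source_config(j, sigma_q, "target", n_samples = n_samples)
      mom <- sim_moments(l_mat[, j, drop = FALSE], cfg, sigma_e, sj)
      w <- compute_weights(mom$C, l_mat[, j], sigma_e^2, study$mu)
      rows <- metrics_rows("recon_accuracy", a, "r_recon",
                           moment_recon_cor(mom, w$w, 1L),
                           vertex = j, seed = sj,
                           depth_class =
                             depth_class_of(study$sources$depth[j]))
      if (point_spread) {
        d <- sqrt(colSums((t(pos) - pos[j, ])^2))
        nb <- order(d)[seq_len(n_neighbours + 1L)]
        ps <- vapply(nb, function(v) {
          wv <- compute_weights(mom$C, l_mat[, v], sigma_e^2, study$mu)
          abs(moment_recon_cor(mom, wv$w, 1L))
        }, numeric(1L))
        rows <- rbind(rows,
                      metrics_rows("recon_accuracy", a, "r_point_spread",
                                   ps, vertex = j, vertex2 = nb,
                                   distance = d[nb], seed = sj))
      }
      i <- i + 1L
      out[[i]] <- rows
    }
  }
  do.call(rbind, out)
}

#' Reconstruction accuracy with interfering brain sources
#'
#' Adds five interfering dipoles ("brain noise") to each target simulation
#' (proximity shells or deep-source configuration, see
#' [select_interferers()]) and reports, per vertex and array: the target
#' reconstruction correlation with and without interference (matched
#' seeds), and the magnitude of correlation between the reconstruction and
#' each interferer time course (`r_int`, interference leakage).
#'
#' @inheritParams run_recon_accuracy
#' @param case "proximity" or "deep".
#' @param int_amplitude interferer amplitude std (A m; defaults to
#'   `sigma_q`, as in the reference simulations).
#' @return a MetricsTable data.frame with metrics "r_recon_with",
#'   "r_recon_without" and "r_int" (replicate = interferer index k).
#' @export
run_brain_noise <- function(study, vertices, case = c("proximity", "deep"),
                            arrays = c("squid", "opm"),
                            n_samples = 360000L, sigma_q = 5e-9,
                            int_amplitude = sigma_q, sigma_e = 50e-15,
                            seed = 1L) {
  case <- match.arg(case)
  stopifnot(length(vertices) >= 1L)
  out <- list()
  pos <- study$sources$positions
  for (j in vertices) {
    ints <- select_interferers(study$sources, j, case,
                               opm_array = study$arrays$opm,
                               seed = child_seed(seed, "int", j))
    d_int <- sqrt(colSums((t(pos[ints, , drop = FALSE]) - pos[j, ])^2))
    for (a in arrays) {
      l_mat <- study$leadfields[[a]]
      sj <- child_seed(seed, "recon", a, j)
      cfg6 <- source_config(c(j, ints),
                            c(sigma_q, rep(int_amplitude, 5L)),
                            c("target", rep("interferer", 5L)),
                            n_samples = n_samples)
      mom6 <- sim_moments(l_mat[, c(j, ints), drop = FALSE], cfg6, sigma_e,
                          sj)
      w6 <- compute_weights(mom6$C, l_mat[, j], sigma_e^2, study$mu)
      cfg1 <- source_config(j, sigma_q, "target", n_samples = n_samples)
      mom1 <- sim_moments(l_mat[, j, drop = FALSE], cfg1, sigma_e, sj)
      w1 <- compute_weights(mom1$C, l_mat[, j], sigma_e^2, study$mu)
      r_int <- vapply(1:5, function(k) {
        if (int_amplitude == 0) return(NA_real_)
        abs(moment_recon_cor(mom6, w6$w, 1L + k))
      }, numeric(1L))
      out[[length(out) + 1L]] <- rbind(
        metrics_rows("brain_noise", a, "r_recon_with",
                     moment_recon_cor(mom6, w6$w, 1L), vertex = j,
                     seed = sj, depth_class =
                       depth_class_of(study$sources$depth[j])),
        metrics_rows("brain_noise", a, "r_recon_without",
                     moment_recon_cor(mom1, w1$w, 1L), vertex = j,
                     seed = sj),
        metrics_rows("brain_noise", a, "r_int", r_int, vertex = j,
                     vertex2 = ints, distance = d_int, replicate = 1:5,
                     seed = sj))
    }
  }
  do.call(rbind, out)
}

#' Reconstruction accuracy under forward-model error
#'
#' Sweeps calibrated fractional lead-field errors (perturbations confined
#' to the hyperplane orthogonal to the true lead field): the data are
#' always generated with the true lead field, while the beamformer weights
#' use the perturbed one. Results are reported per vertex, array,
#' fractional error and realisation, with vertices classed by distance to
#' the nearest on-scalp sensor (shallow < 4 cm, deep 4-6 cm).
#'
#' @inheritParams run_recon_accuracy
#' @param vertices vertex indices (e.g. random draws from one hemisphere).
#' @param fractions fractional-error grid (default 20 values spanning
#'   0-0.5).
#' @param n_realisations random-direction draws per (vertex, fraction).
#' @return a MetricsTable data.frame (metric "r_recon", `fraction` and
#'   `depth_class` filled).
#' @export
run_forward_error <- function(study, vertices,
                              arrays = c("squid", "opm"),
                              fractions = seq(0, 0.5, length.out = 20L),
                              n_realisations = 5L, n_samples = 360000L,
                              sigma_q = 5e-9, sigma_e = 50e-15, seed = 1L) {
  stopifnot(length(vertices) >= 1L)
  out <- list()
  for (a in arrays) {
    l_mat <- study$leadfields[[a]]
    for (j in vertices) {
      sj <- child_seed(seed, "fe", a, j)
      cfg <- source_config(j, sigma_q, "target", n_samples = n_samples)
      mom <- sim_moments(l_mat[, j, drop = FALSE], cfg, sigma_e, sj)
      dc <- depth_class_of(study$sources$depth[j])
      l_true <- l_mat[, j]
      vals <- matrix(NA_real_, length(fractions), n_realisations)
      for (t in seq_along(fractions)) {
        for (r in seq_len(n_realisations)) {
          rs <- child_seed(seed, "rvec", j, t, r)
          if (fractions[t] == 0) {
            l_hat <- l_true
          } else {
            xi <- calibrate_fractional_error(l_true, fractions[t], rs)
            l_hat <- perturb_lead_field(l_true, xi, rs)$l_hat$values
          }
          w <- compute_weights(mom$C, l_hat, sigma_e^2, study$mu)
          vals[t, r] <- moment_recon_cor(mom, w$w, 1L)
        }
      }
      out[[length(out) + 1L]] <-
        metrics_rows("forward_error", a, "r_recon", as.numeric(vals),
                     vertex = j,
                     fraction = rep(fractions, n_realisations),
                     depth_class = dc,
                     replicate = rep(seq_len(n_realisations),
                                     each = length(fractions)),
                     seed = sj)
    }
  }
  do.call(rbind, out)
}

#' Crossover fractional error between two arrays
#'
#' Averages [run_forward_error()] results into mean correlation-versus-
#' fraction curves per array and depth class, and linearly interpolates
#' the fractional error at which the first-named array's curve first falls
#' below the second's.
#'
#' @param tbl result of [run_forward_error()].
#' @param better,worse array names (default "opm" over "squid").
#' @return list with `curves` (data.frame array/depth_class/fraction/mean_r)
#'   and `crossover` (data.frame depth_class/fraction).
#' @export
forward_error_crossover <- function(tbl, better = "opm", worse = "squid") {
  tbl <- tbl[tbl$metric == "r_recon", ]
  curves <- stats::aggregate(value ~ array + depth_class + fraction,
                             data = tbl, FUN = mean)
  names(curves)[names(curves) == "value"] <- "mean_r"
  classes <- unique(curves$depth_class)
  cross <- data.frame(depth_class = classes, fraction = NA_real_)
  for (i in seq_along(classes)) {
    cb <- curves[curves$array == better & curves$depth_class == classes[i], ]
    cw <- curves[curves$array == worse & curves$depth_class == classes[i], ]
    cb <- cb[order(cb$fraction), ]
    cw <- cw[order(cw$fraction), ]
    if (nrow(cb) < 2L || nrow(cb) != nrow(cw)) next
    dd <- cb$mean_r - cw$mean_r
    k <- which(dd[-1L] < 0 & dd[-length(dd)] >= 0)
    if (length(k) == 0L) next
    k <- k[1L]
    f1 <- cb$fraction[k]; f2 <- cb$fraction[k + 1L]
    cross$fraction[i] <- f1 + (f2 - f1) * dd[k] / (dd[k] - dd[k + 1L])
  }
  list(curves = curves, crossover = cross)
}

#' Two-source spatial resolution (leakage versus separation)
#'
#' Repeatedly simulates two temporally orthogonal Gaussian dipoles at
#' random cortical locations whose Euclidean separation falls in a
#' prescribed distance bin, beamforms both locations, and measures the
#' magnitude of correlation between the two reconstructions (source
#' leakage) plus each source's own reconstruction accuracy. Sources are
#' resolvable where leakage < 1/sqrt(2).
#'
#' @inheritParams run_recon_accuracy
#' @param array name of the study array to run.
#' @param n_bins number of separation bins (default 30).
#' @param bin_width bin width (m, default 0.002).
#' @param repeats_per_bin simulated pairs per bin (default 100).
#' @param sigma_e sensor noise std (T; default 35 fT, the two-source
#'   setting).
#' @param vertices_pool candidate vertices for the first source (default:
#'   whole cortex).
#' @param max_tries rejection-sampling attempts per pair.
#' @return a MetricsTable data.frame (metrics "leakage", "r_recon_k",
#'   "r_recon_n"; `bin` = bin index, `distance` = realised separation).
#' @export
run_resolution <- function(study, array = "opm", n_bins = 30L,
                           bin_width = 0.002, repeats_per_bin = 100L,
                           n_samples = 360000L, sigma_q = 5e-9,
                           sigma_e = 35e-15, seed = 1L,
                           vertices_pool = NULL, max_tries = 200L) {
  l_mat <- study$leadfields[[array]]
  pos <- study$sources$positions
  if (is.null(vertices_pool)) vertices_pool <- seq_len(nrow(pos))
  out <- list()
  for (b in seq_len(n_bins)) {
    lo <- (b - 1L) * bin_width
    hi <- b * bin_width
    for (rep_i in seq_len(repeats_per_bin)) {
      ps <- child_seed(seed, "pair", array, b, rep_i)
      pair <- with_seed(ps, {
        res <- NULL
        for (try in seq_len(max_tries)) {
          k <- vertices_pool[sample.int(length(vertices_pool), 1L)]
          d <- sqrt(colSums((t(pos) - pos[k, ])^2))
          cand <- which(d > max(lo, 1e-12) & d <= hi)
          if (length(cand) > 0L) {
            res <- c(k, cand[sample.int(length(cand), 1L)])
            break
          }
        }
        res
      })
      if (is.null(pair)) break  # no admissible pair in this bin at all
      k <- pair[1L]; n <- pair[2L]
      cfg <- source_config(c(k, n), sigma_q, "target", n_samples = n_samples)
      mom <- sim_moments(l_mat[, c(k, n), drop = FALSE], cfg, sigma_e, ps)
      wk <- compute_weights(mom$C, l_mat[, k], sigma_e^2, study$mu)
      wn <- compute_weights(mom$C, l_mat[, n], sigma_e^2, study$mu)
      d_kn <- sqrt(sum((pos[k, ] - pos[n, ])^2))
      out[[length(out) + 1L]] <- rbind(
        metrics_rows("resolution", array, "leakage",
                     abs(moment_leak_cor(mom, wk$w, wn$w)),
                     vertex = k, vertex2 = n, distance = d_kn, bin = b,
                     replicate = rep_i, seed = ps),
        metrics_rows("resolution", array, "r_recon_k",
                     moment_recon_cor(mom, wk$w, 1L), vertex = k,
                     vertex2 = n, distance = d_kn, bin = b,
                     replicate = rep_i, seed = ps),
        metrics_rows("resolution", array, "r_recon_n",
                     moment_recon_cor(mom, wn$w, 2L), vertex = n,
                     vertex2 = k, distance = d_kn, bin = b,
                     replicate = rep_i, seed = ps))
    }
    if (length(out) == 0L || !any(vapply(out, function(x)
      any(x$bin == b), logical(1L)))) {
      warning("no admissible vertex pair for bin ", b, " (",
              1000 * lo, "-", 1000 * hi, " mm); bin skipped")
    }
  }
  do.call(rbind, out)
}

#' Summarise a resolution run
#'
#' Per-bin mean leakage and the smallest bin midpoint whose mean leakage
#' falls below the resolvability threshold.
#'
#' @param tbl result of [run_resolution()] (possibly several arrays).
#' @param bin_width bin width used in the run (m).
#' @param threshold resolvability threshold (default 1/sqrt(2)).
#' @return list with `per_bin` (array/bin/midpoint_mm/mean_leakage/n) and
#'   `resolved_at` (array/separation_mm).
#' @export
resolution_summary <- function(tbl, bin_width = 0.002,
                               threshold = 1 / sqrt(2)) {
  lk <- tbl[tbl$metric == "leakage", ]
  per_bin <- stats::aggregate(value ~ array + bin, data = lk, FUN = mean)
  names(per_bin)[names(per_bin) == "value"] <- "mean_leakage"
  cnt <- stats::aggregate(value ~ array + bin, data = lk, FUN = length)
  per_bin$n <- cnt$value[match(paste(per_bin$array, per_bin$bin),
                               paste(cnt$array, cnt$bin))]
  per_bin$midpoint_mm <- (per_bin$bin - 0.5) * bin_width * 1000
  arrays <- unique(per_bin$array)
  res <- data.frame(array = arrays, separation_mm = NA_real_)
  for (i in seq_along(arrays)) {
    pb <- per_bin[per_bin$array == arrays[i], ]
    pb <- pb[order(pb$bin), ]
    ok <- which(pb$mean_leakage < threshold)
    if (length(ok)) res$separation_mm[i] <- pb$midpoint_mm[ok[1L]]
  }
  list(per_bin = per_bin[order(per_bin$array, per_bin$bin), ],
       resolved_at = res)
}

#' Minimum resolvable separation per seed vertex
#'
#' For each seed vertex k, escalates through the other cortex vertices in
#' order of Euclidean distance (nearest neighbour first) simulating a
#' two-source recording per pair, until the reconstruction leakage
#' `|r(q_hat_k, q_hat_n)|` falls below 1/sqrt(2); reports that separation
#' and the leakage at it. With `n_samples = Inf` (default) the
#' population-covariance limit is used, matching the long recordings of
#' the sampled procedure with negligible sampling error and no RNG.
#'
#' @inheritParams run_resolution
#' @param seed_vertices seed vertex indices (one hemisphere).
#' @param n_samples samples per pair simulation, or `Inf` for the
#'   population limit.
#' @param max_radius search radius (m, default 0.06); seeds with no
#'   resolvable neighbour within it are flagged unresolved (value NA).
#' @return a MetricsTable data.frame (metrics "min_separation" (m) and
#'   "leakage_at_min"; unresolved seeds carry NA values).
#' @export
run_min_separation <- function(study, array = "squid", seed_vertices,
                               n_samples = Inf, sigma_q = 5e-9,
                               sigma_e = 35e-15, seed = 1L,
                               max_radius = 0.06) {
  l_mat <- study$leadfields[[array]]
  pos <- study$sources$positions
  out <- list()
  for (k in seed_vertices) {
    d <- sqrt(colSums((t(pos) - pos[k, ])^2))
    cand <- which(d > 1e-12 & d <= max_radius)
    cand <- cand[order(d[cand])]
    sep <- NA_real_
    leak_at <- NA_real_
    if (is.infinite(n_samples)) {
      met <- two_source_population_metrics(l_mat[, k],
                                           l_mat[, cand, drop = FALSE],
                                           sigma_q, sigma_e, study$mu)
      hit <- which(abs(met$leakage) < 1 / sqrt(2))
      if (length(hit)) {
        sep <- d[cand[hit[1L]]]
        leak_at <- abs(met$leakage[hit[1L]])
      }
    } else {
      for (idx in seq_along(cand)) {
        n <- cand[idx]
        ps <- child_seed(seed, "minsep", array, k, idx)
        cfg <- source_config(c(k, n), sigma_q, "target",
                             n_samples = n_samples)
        mom <- sim_moments(l_mat[, c(k, n), drop = FALSE], cfg, sigma_e, ps)
        wk <- compute_weights(mom$C, l_mat[, k], sigma_e^2, study$mu)
        wn <- compute_weights(mom$C, l_mat[, n], sigma_e^2, study$mu)
        lk <- abs(moment_leak_cor(mom, wk$w, wn$w))
        if (lk < 1 / sqrt(2)) {
          sep <- d[n]
          leak_at <- lk
          break
        }
      }
    }
    out[[length(out) + 1L]] <- rbind(
      metrics_rows("min_separation", array, "min_separation", sep,
                   vertex = k, seed = seed,
                   depth_class = depth_class_of(study$sources$depth[k])),
      metrics_rows("min_separation", array, "leakage_at_min", leak_at,
                   vertex = k, seed = seed))
  }
  do.call(rbind, out)
}

#' Summarise a minimum-separation run
#'
#' @param tbl result of [run_min_separation()].
#' @return data.frame per array: mean minimum separation (mm), mean
#'   leakage at it, number of seeds, number unresolved.
#' @export
min_separation_summary <- function(tbl) {
  ms <- tbl[tbl$metric == "min_separation", ]
  lk <- tbl[tbl$metric == "leakage_at_min", ]
  arrays <- unique(ms$array)
  data.frame(
    array = arrays,
    mean_min_separation_mm = vapply(arrays, function(a)
      mean(ms$value[ms$array == a], na.rm = TRUE) * 1000, numeric(1L)),
    mean_leakage_at_min = vapply(arrays, function(a)
      mean(lk$value[lk$array == a], na.rm = TRUE), numeric(1L)),
    n_seeds = vapply(arrays, function(a) sum(ms$array == a), numeric(1L)),
    n_unresolved = vapply(arrays, function(a)
      sum(is.na(ms$value[ms$array == a])), numeric(1L)),
    row.names = NULL)
}
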
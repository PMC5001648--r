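#' Fit a multiple local sphere head model
#'
#' For each channel (sensing and reference), a sphere is fitted by
#' algebraic least squares to the scalp vertices lying within
#' `patch_radius` of the channel's inner coil; if fewer than 50 vertices
#' fall in the patch the whole scalp is used. The algebraic fit minimises
#' `(|v|^2 - 2 c.v - t)^2` which is linear in the centre `c` and
#' `t = R^2 - |c|^2`, and is exact on spherical data.
#'
#' @param head a `head_model` (scalp must be closed).
#' @param array a `sensor_array`.
#' @param patch_radius patch radius (m, default 0.09); `Inf` fits one
#'   common sphere to the whole scalp.
#' @return an object of class `local_spheres`: `centres` (n x 3), `radii`
#'   (n), `labels`; rows ordered sensing channels then reference channels.
#' @export
fit_local_spheres <- function(head, array, patch_radius = 0.09) {
  stopifnot(patch_radius > 0)
  v <- head$scalp$vertices
  if (nrow(v) == 0L) stop("empty scalp mesh")
  all_ch <- c(array$channels, array$reference_channels)
  centres <- matrix(0, length(all_ch), 3L)
  radii <- numeric(length(all_ch))
  for (i in seq_along(all_ch)) {
    p <- all_ch[[i]]$coil_positions[1L, ]
    if (is.infinite(patch_radius)) {
      sel <- rep(TRUE, nrow(v))
    } else {
      d2 <- (v[, 1L] - p[1L])^2 + (v[, 2L] - p[2L])^2 + (v[, 3L] - p[3L])^2
      sel <- d2 <= patch_radius^2
      if (sum(sel) < 50L) sel <- rep(TRUE, nrow(v))
    }
    fit <- sphere_fit(v[sel, , drop = FALSE])
    centres[i, ] <- fit$centre
    radii[i] <- fit$radius
  }
  structure(list(centres = centres, radii = radii,
                 labels = vapply(all_ch, `[[`, character(1L), "label"),
                 n_sense = n_channels(array)),
            class = "local_spheres")
}

# algebraic (linear least-squares) sphere fit
sphere_fit <- function(pts) {
  a <- cbind(2 * pts, 1)
  b <- rowSums(pts * pts)
  coef <- .lm.fit(a, b)$coefficients
  centre <- coef[1:3]
  r2 <- coef[4L] + sum(centre^2)
  if (r2 <= 0) stop("degenerate sphere fit")
  list(centre = centre, radius = sqrt(r2))
}

#' Magnetic field of a current dipole in a conducting sphere (Sarvas)
#'
#' Closed-form external field of a current dipole inside a homogeneous
#' conducting sphere. Radial dipoles (moment parallel to the sphere-centred
#' position vector) are externally silent, and the radial field component
#' equals that of the free-space current-dipole field because volume
#' currents contribute no radial field in a sphere.
#'
#' Vectorised over dipoles: `dipole_pos` and `dipole_moment` may be n x 3
#' matrices (recycled against each other), with a single field point.
#'
#' @param dipole_pos dipole location(s), 3-vector or n x 3 matrix (m).
#' @param dipole_moment dipole moment(s) (A m), same shape rules.
#' @param sphere_centre conductor sphere centre (3-vector, m).
#' @param field_point measurement point (3-vector, m); must lie strictly
#'   outside the sphere radius containing the dipole and not coincide with
#'   it.
#' @param check enforce the field-point-outside-dipole-radius
#'   precondition (default TRUE). The lead-field engine disables it for
#'   channels whose patch-fitted sphere centre is far from a distant
#'   dipole; the singularity guard on the Sarvas denominator always
#'   applies.
#' @return n x 3 matrix of magnetic field vectors (tesla).
#' @export
sarvas_field <- function(dipole_pos, dipole_moment, sphere_centre,
                         field_point, check = TRUE) {
  r0 <- if (is.null(dim(dipole_pos))) matrix(dipole_pos, 1L) else
    as.matrix(dipole_pos)
  q <- if (is.null(dim(dipole_moment))) matrix(dipole_moment, 1L) else
    as.matrix(dipole_moment)
  n <- max(nrow(r0), nrow(q))
  if (nrow(r0) == 1L && n > 1L) r0 <- r0[rep(1L, n), , drop = FALSE]
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  r0 <- sweep(r0, 2L, sphere_centre)      # dipole, sphere-centred
  r <- as.numeric(field_point) - as.numeric(sphere_centre)
  rl <- sqrt(sum(r * r))
  r0l <- row_norms(r0)
  if (check && any(rl <= r0l)) {
    stop("field point lies inside the sphere radius containing the dipole")
  }
  a_vec <- matrix(r, n, 3L, byrow = TRUE) - r0  # r - r0
  al <- row_norms(a_vec)
  if (any(al == 0)) stop("field point coincides with a dipole position")
  adotr <- a_vec[, 1L] * r[1L] + a_vec[, 2L] * r[2L] + a_vec[, 3L] * r[3L]
  r0dotr <- r0[, 1L] * r[1L] + r0[, 2L] * r[2L] + r0[, 3L] * r[3L]
  f <- al * (rl * al + rl^2 - r0dotr)
  if (any(abs(f) < 1e-30)) {
    stop("Sarvas denominator F ~ 0 (field point too close to the dipole axis)")
  }
  c1 <- al^2 / rl + adotr / al + 2 * al + 2 * rl
  c2 <- al + 2 * rl + adotr / al
  gradf <- cbind(c1 * r[1L], c1 * r[2L], c1 * r[3L]) -
    cbind(c2 * r0[, 1L], c2 * r0[, 2L], c2 * r0[, 3L])
  qxr0 <- cross3(q, r0)
  qxr0dotr <- qxr0[, 1L] * r[1L] + qxr0[, 2L] * r[2L] + qxr0[, 3L] * r[3L]
  1e-7 / f^2 * (f * qxr0 - qxr0dotr * gradf)
}

#' Lead fields for a set of dipoles and an array
#'
#' The lead field `l_j` is the vector of channel responses to a unit-moment
#' (1 A m) dipole at source j oriented along its source-space orientation.
#' Each channel response sums, over its coils, the coil weight times the
#' Sarvas field (computed in that channel's own local sphere) projected on
#' the coil axis; reference balancing weights, when non-zero, subtract the
#' weighted reference responses.
#'
#' Per-channel evaluation always uses that channel's own sphere (the
#' standard multiple-local-sphere convention). A source lying outside
#' *every* channel's fitted sphere is not inside the conductor model at
#' all and raises an error; sources outside some individual channel's
#' sphere are unavoidable with patch-fitted spheres on a non-spherical
#' head and are evaluated with the Sarvas formula as usual.
#'
#' @param sources a `source_space`, or a list with `positions` and
#'   `orientations` matrices.
#' @param array a `sensor_array`.
#' @param spheres a `local_spheres` fit for `array`.
#' @return `n_channels x n_sources` matrix (T per A m), with attribute
#'   `units = "T/(A.m)"`.
#' @export
leadfield_matrix <- function(sources, array, spheres) {
  pos <- sources$positions
  ori <- sources$orientations
  stopifnot(nrow(pos) == nrow(ori))
  all_ch <- c(array$channels, array$reference_channels)
  if (length(all_ch) != length(spheres$radii)) {
    stop("channel count mismatch between array and local sphere model")
  }
  n_src <- nrow(pos)
  n_sen <- n_channels(array)
  use_refs <- length(array$reference_channels) > 0L &&
    any(array$reference_weights != 0)
  idx <- if (use_refs) seq_along(all_ch) else seq_len(n_sen)

  inside_any <- rep(FALSE, n_src)
  l_all <- matrix(0, length(idx), n_src)
  for (i in idx) {
    ch <- all_ch[[i]]
    ctr <- spheres$centres[i, ]
    r0l <- row_norms(sweep(pos, 2L, ctr))
    inside_any <- inside_any | (r0l < spheres$radii[i])
    acc <- numeric(n_src)
    for (k in seq_len(nrow(ch$coil_positions))) {
      b <- sarvas_field(pos, ori, ctr, ch$coil_positions[k, ], check = FALSE)
      acc <- acc + ch$coil_weights[k] *
        (b[, 1L] * ch$coil_orientations[k, 1L] +
         b[, 2L] * ch$coil_orientations[k, 2L] +
         b[, 3L] * ch$coil_orientations[k, 3L])
    }
    l_all[i, ] <- acc
  }
  if (!all(inside_any)) {
    stop(sum(!inside_any), " source(s) lie outside every channel's local ",
         "sphere (outside the conductor model)")
  }
  l <- l_all[seq_len(n_sen), , drop = FALSE]
  if (use_refs) {
    l <- l - array$reference_weights %*%
      l_all[n_sen + seq_along(array$reference_channels), , drop = FALSE]
  }
  structure(l, units = "T/(A.m)")
}

#' Lead field of a single source
#'
#' Convenience wrapper around [leadfield_matrix()] returning a `lead_field`
#' object for one source.
#'
#' @param j source index into `sources`.
#' @inheritParams leadfield_matrix
#' @return a `lead_field`: `values` (per sensing channel, T per A m),
#'   `source` index, `kind` of the array, `flavour` ("exact").
#' @export
compute_lead_field <- function(sources, j, array, spheres) {
  sub <- list(positions = sources$positions[j, , drop = FALSE],
              orientations = sources$orientations[j, , drop = FALSE])
  v <- leadfield_matrix(sub, array, spheres)
  new_lead_field(as.numeric(v), source = j, kind = array$kind,
                 flavour = "exact")
}

new_lead_field <- function(values, source = NA_integer_, kind = NA_character_,
                           flavour = c("exact", "perturbed", "delta"),
                           delta = NULL) {
  flavour <- match.arg(flavour)
  stopifnot(all(is.finite(values)))
  if (flavour == "perturbed") {
    stopifnot(!is.null(delta))
    l0 <- values - delta
    lhs <- sum(values^2)
    rhs <- sum(l0^2) + sum(delta^2)
    if (abs(lhs - rhs) > 1e-9 * max(lhs, rhs)) {
      stop("perturbed lead field violates the orthogonal-decomposition norm")
    }
  }
  structure(list(values = as.numeric(values), source = source, kind = kind,
                 flavour = flavour, delta = delta),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field (%s, %s): %d channels, |l| = %.3g fT/nAm\n",
              x$kind, x$flavour, length(x$values),
              sqrt(sum(x$values^2)) * 1e6))
  invisible(x)
}

# extract numeric lead-field values from vector or lead_field
lf_values <- function(l) {
  if (inherits(l, "lead_field")) l$values else as.numeric(l)
}

#' Lead-field norm (SNR) gain map
#'
#' For every source j, the root-sum-square over channels (Frobenius norm)
#' `f_j` of the lead field for each array, scaled to a 1 nAm dipole, and
#' the ratio `f_a / f_b`. With equal sensor noise floors the ratio is the
#' SNR gain of array a over array b. Sources that are externally silent
#' for array b (f_b = 0) get `ratio = NA` and are excluded from summaries.
#'
#' @param sources a `source_space`.
#' @param array_a,array_b the two arrays (for the canonical sensitivity
#'   comparison both are axial-gradiometer configurations).
#' @param spheres_a,spheres_b matching `local_spheres` fits.
#' @param dipole_moment dipole moment used for reporting (A m; default
#'   1 nAm).
#' @return data.frame: `vertex`, `x`, `y`, `z`, `f_a`, `f_b` (tesla for
#'   `dipole_moment`), `ratio`.
#' @export
snr_gain_map <- function(sources, array_a, array_b, spheres_a, spheres_b,
                         dipole_moment = 1e-9) {
  la <- leadfield_matrix(sources, array_a, spheres_a)
  lb <- leadfield_matrix(sources, array_b, spheres_b)
  f_a <- sqrt(colSums(la^2)) * dipole_moment
  f_b <- sqrt(colSums(lb^2)) * dipole_moment
  ratio <- ifelse(f_b == 0, NA_real_, f_a / f_b)
  data.frame(vertex = seq_len(nrow(sources$positions)),
             x = sources$positions[, 1L], y = sources$positions[, 2L],
             z = sources$positions[, 3L],
             f_a = f_a, f_b = f_b, ratio = ratio)
}

#' Export a lead-field matrix or SNR map as CSV
#'
#' Lead fields are written in fT/nAm (one row per channel); SNR maps are
#' written as-is with fields in fT.
#'
#' @param l matrix from [leadfield_matrix()].
#' @param labels channel labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_leadfield_csv <- function(l, labels, path) {
  df <- data.frame(channel = labels, unclass(l) * 1e6)  # T/(A.m) -> fT/nAm
  names(df)[-1L] <- sprintf("src%05d", seq_len(ncol(l)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield_csv
#' @param map data.frame from [snr_gain_map()].
#' @export
write_snr_map_csv <- function(map, path) {
  out <- map
  out$f_a <- out$f_a * 1e15
  out$f_b <- out$f_b * 1e15
  names(out)[names(out) %in% c("f_a", "f_b")] <- c("f_a_fT", "f_b_fT")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
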
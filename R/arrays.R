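#' Sensor channels and arrays
#'
#' A channel is a set of point pickup coils: positions (k x 3, m), unit
#' sensitive-axis orientations (k x 3) and signed weights (length k). A
#' magnetometer has one coil with weight +1; a first-order axial
#' gradiometer has two coaxial coils with weights (+1, -1) separated along
#' the shared axis by the baseline. Coils are treated as point sensors (the
#' field is sampled at the coil position and projected on the axis).
#'
#' @param coil_positions k x 3 matrix (m).
#' @param coil_orientations k x 3 matrix of unit vectors.
#' @param coil_weights numeric length k.
#' @param label channel label.
#' @return a `sensor_channel` list.
#' @export
sensor_channel <- function(coil_positions, coil_orientations, coil_weights,
                           label) {
  coil_positions <- matrix(as.numeric(coil_positions), ncol = 3L)
  coil_orientations <- matrix(as.numeric(coil_orientations), ncol = 3L)
  stopifnot(nrow(coil_positions) == nrow(coil_orientations),
            nrow(coil_positions) == length(coil_weights))
  if (any(abs(row_norms(coil_orientations) - 1) > 1e-9)) {
    stop("coil orientations must be unit vectors (1e-9)")
  }
  structure(list(coil_positions = coil_positions,
                 coil_orientations = coil_orientations,
                 coil_weights = as.numeric(coil_weights),
                 label = as.character(label)),
            class = "sensor_channel")
}

new_sensor_array <- function(channels, reference_channels = list(),
                             kind = c("squid_helmet", "opm_scalp",
                                      "eeg_layout"),
                             reference_weights = NULL, meta = list()) {
  kind <- match.arg(kind)
  labels <- vapply(channels, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (is.null(reference_weights)) {
    reference_weights <- matrix(0, length(channels),
                                length(reference_channels))
  }
  stopifnot(all(is.finite(reference_weights)))
  structure(list(channels = channels,
                 reference_channels = reference_channels,
                 kind = kind,
                 reference_weights = reference_weights,
                 meta = meta),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  ncoil <- vapply(x$channels, function(ch) nrow(ch$coil_positions), 1L)
  cat(sprintf("sensor_array (%s): %d channels (%s), %d reference channels\n",
              x$kind, length(x$channels),
              if (all(ncoil == 1L)) "magnetometers" else
                if (all(ncoil == 2L)) "axial gradiometers" else "mixed",
              length(x$reference_channels)))
  invisible(x)
}

#' Number of channels in an array
#' @param array a `sensor_array`.
#' @return integer count.
#' @export
n_channels <- function(array) length(array$channels)

# inner-coil positions as a matrix
sensor_positions <- function(array) {
  t(vapply(array$channels, function(ch) ch$coil_positions[1L, ], numeric(3L)))
}

# greedy farthest-point subset of candidate points; deterministic
fps_select <- function(candidates, k, start) {
  n <- nrow(candidates)
  stopifnot(k <= n)
  sel <- integer(k)
  sel[1L] <- start
  d2 <- (candidates[, 1L] - candidates[start, 1L])^2 +
    (candidates[, 2L] - candidates[start, 2L])^2 +
    (candidates[, 3L] - candidates[start, 3L])^2
  if (k > 1L) for (i in 2:k) {
    nxt <- which.max(d2)
    sel[i] <- nxt
    d2 <- pmin(d2, (candidates[, 1L] - candidates[nxt, 1L])^2 +
                   (candidates[, 2L] - candidates[nxt, 2L])^2 +
                   (candidates[, 3L] - candidates[nxt, 3L])^2)
  }
  sel
}

#' Build a SQUID-style helmet gradiometer array
#'
#' Distributes `n_channels` radial first-order axial gradiometers
#' quasi-uniformly (greedy farthest-point sampling over the scalp
#' tessellation) on a helmet surface obtained by dilating the scalp along
#' its normals. The head sits displaced posteriorly inside the helmet: the
#' posterior scalp-coil gap equals `min_standoff` while the anterior gap is
#' `min_standoff + 2 * posterior_shift` (the head rests against the back of
#' the helmet). Coverage is restricted to sensors above an inferior cut
#' plane. A reference magnetometer array for synthetic higher-order
#' gradiometry is placed on a far dilated surface.
#'
#' @param head a `head_model`.
#' @param n_channels number of sensing channels (default 275).
#' @param baseline axial gradiometer baseline (m, default 0.05).
#' @param min_standoff minimum scalp-to-inner-coil distance (m, default
#'   0.017, the dewar constraint).
#' @param posterior_shift posterior displacement of the head inside the
#'   helmet (m); default 0.0065 makes the anterior gap ~3 cm.
#' @param inferior_cut z of the coverage cut plane relative to the fiducial
#'   plane (m, negative = below). Default -0.05 approximates full-helmet
#'   coverage down to ear/occiput level.
#' @param n_reference reference channel count (default 29).
#' @param ref_standoff scalp-to-reference distance (m, >= 0.15).
#' @return a `sensor_array` of kind `squid_helmet` with all-zero reference
#'   weights (pure first-order channels); see [form_reference_weights()].
#' @export
build_squid_array <- function(head, n_channels = 275L, baseline = 0.05,
                              min_standoff = 0.017, posterior_shift = 0.0065,
                              inferior_cut = -0.05, n_reference = 29L,
                              ref_standoff = 0.15) {
  stopifnot(n_channels >= 1L, baseline > 0, min_standoff > 0,
            posterior_shift >= 0, ref_standoff >= 0.15)
  if (posterior_shift >= min_standoff) {
    stop("helmet intersects scalp: posterior_shift must be < min_standoff")
  }
  scalp <- head$scalp
  fid_z <- mean(head$fiducials[, 3L])
  z_cut <- fid_z + inferior_cut
  shift <- c(0, posterior_shift, 0)

  d0 <- min_standoff + posterior_shift
  cand_pos <- scalp$vertices + d0 * scalp$normals +
    matrix(shift, nrow(scalp$vertices), 3L, byrow = TRUE)
  keep <- cand_pos[, 3L] > z_cut
  if (sum(keep) < n_channels) {
    stop("not enough helmet surface above the inferior cut for ",
         n_channels, " channels")
  }
  cand_pos <- cand_pos[keep, , drop = FALSE]
  cand_nrm <- scalp$normals[keep, , drop = FALSE]

  start <- which.min(cand_pos[, 2L])  # posterior-most: head touches the back
  sel <- fps_select(cand_pos, n_channels, start)
  channels <- lapply(seq_len(n_channels), function(i) {
    p <- cand_pos[sel[i], ]
    n <- cand_nrm[sel[i], ]
    sensor_channel(rbind(p, p + baseline * n), rbind(n, n), c(1, -1),
                   sprintf("SQ%03d", i))
  })

  dref <- ref_standoff + posterior_shift
  ref_pos <- scalp$vertices + dref * scalp$normals +
    matrix(shift, nrow(scalp$vertices), 3L, byrow = TRUE)
  keep_r <- ref_pos[, 3L] > z_cut
  ref_pos <- ref_pos[keep_r, , drop = FALSE]
  ref_nrm <- scalp$normals[keep_r, , drop = FALSE]
  sel_r <- fps_select(ref_pos, n_reference, which.max(ref_pos[, 3L]))
  refs <- lapply(seq_len(n_reference), function(i) {
    sensor_channel(ref_pos[sel_r[i], , drop = FALSE],
                   ref_nrm[sel_r[i], , drop = FALSE], 1,
                   sprintf("REF%02d", i))
  })

  new_sensor_array(channels, refs, "squid_helmet",
                   meta = list(baseline = baseline,
                               min_standoff = min_standoff,
                               posterior_shift = posterior_shift,
                               inferior_cut = inferior_cut,
                               ref_standoff = ref_standoff))
}

#' Build a scalp-conforming on-scalp (OPM-style) array
#'
#' One channel per input helmet channel, placed at the projection of the
#' helmet channel's inner coil onto the scalp (nearest scalp vertex),
#' offset outward along the local scalp normal by `standoff`, with the
#' sensitive axis along the scalp normal (radial). Magnetometer mode is
#' used for beamformer experiments; gradiometer mode (outer coil at
#' `baseline`) exists for like-for-like sensitivity comparison with the
#' helmet gradiometers.
#'
#' @param squid the helmet `sensor_array` whose layout is projected.
#' @param head a `head_model`.
#' @param standoff scalp-to-sensor distance (m, default 0.004).
#' @param mode "magnetometer" (default) or "gradiometer".
#' @param baseline gradiometer baseline (m, default 0.05).
#' @return a `sensor_array` of kind `opm_scalp` with no reference channels.
#' @export
build_opm_array <- function(squid, head, standoff = 0.004,
                            mode = c("magnetometer", "gradiometer"),
                            baseline = 0.05) {
  mode <- match.arg(mode)
  stopifnot(n_channels(squid) >= 1L, standoff > 0)
  scalp <- head$scalp
  inner <- sensor_positions(squid)
  pos <- matrix(0, nrow(inner), 3L)
  nrm <- matrix(0, nrow(inner), 3L)
  for (i in seq_len(nrow(inner))) {
    d2 <- (scalp$vertices[, 1L] - inner[i, 1L])^2 +
      (scalp$vertices[, 2L] - inner[i, 2L])^2 +
      (scalp$vertices[, 3L] - inner[i, 3L])^2
    j <- which.min(d2)
    nrm[i, ] <- scalp$normals[j, ]
    pos[i, ] <- scalp$vertices[j, ] + standoff * scalp$normals[j, ]
  }
  dmin <- as.matrix(stats::dist(pos))
  diag(dmin) <- Inf
  if (any(dmin < 1e-3)) {
    warning(sum(dmin < 1e-3) / 2, " sensor pair(s) closer than 1 mm after ",
            "scalp projection (overlap)")
  }
  channels <- lapply(seq_len(nrow(pos)), function(i) {
    if (mode == "magnetometer") {
      sensor_channel(pos[i, , drop = FALSE], nrm[i, , drop = FALSE], 1,
                     sprintf("OP%03d", i))
    } else {
      sensor_channel(rbind(pos[i, ], pos[i, ] + baseline * nrm[i, ]),
                     rbind(nrm[i, ], nrm[i, ]), c(1, -1),
                     sprintf("OP%03d", i))
    }
  })
  new_sensor_array(channels, list(), "opm_scalp",
                   meta = list(standoff = standoff, mode = mode,
                               baseline = if (mode == "gradiometer") baseline))
}

# ring tables for the proportional EEG-style layouts; counts match the
# published system sizes (81 / 329 / 1293)
eeg_ring_table <- function(scheme) {
  switch(scheme,
         "10-10"  = list(p = 0.10,  rings = 1:4,  keep = 8L * (1:4)),
         "10-5"   = list(p = 0.05,  rings = 1:9,  keep = c(8L * (1:8), 40L)),
         "10-2.5" = list(p = 0.025, rings = 1:18, keep = c(8L * (1:17), 68L)),
         stop("unknown EEG layout scheme: ", scheme))
}

#' Build an EEG-layout magnetometer array
#'
#' Proportional-system sensor layouts on the scalp: concentric rings about
#' the vertex at colatitude fractions `k * p` of the nasion-inion arc
#' (p = 10%, 5% or 2.5%), ring k carrying `8 k` positions, the lowest ring
#' azimuthally cropped away from the face so the channel counts equal the
#' published 10-10 / 10-5 / 10-2.5 system sizes (81, 329, 1293). Sensors
#' are radial magnetometers offset from the scalp by `standoff`.
#'
#' @param head a `head_model` (fiducials define anterior/vertex).
#' @param scheme one of "10-10", "10-5", "10-2.5".
#' @param standoff scalp-to-sensor distance (m, default 0.004).
#' @return a `sensor_array` of kind `eeg_layout`.
#' @export
build_eeg_layout_array <- function(head, scheme = c("10-10", "10-5", "10-2.5"),
                                   standoff = 0.004) {
  scheme <- match.arg(scheme)
  stopifnot(standoff > 0)
  tab <- eeg_ring_table(scheme)
  semi <- apply(abs(head$scalp$vertices), 2L, max)  # ellipsoid semi-axes

  theta <- c(0, tab$rings * tab$p * pi)
  pts <- list(c(0, 0))                 # (theta, phi); vertex electrode
  for (i in seq_along(tab$rings)) {
    k <- tab$rings[i]
    n_nom <- 8L * k
    n_keep <- tab$keep[i]
    if (n_keep == n_nom) {
      phi <- (seq_len(n_nom) - 1L) * 2 * pi / n_nom
    } else {
      # cropped ring: half-step offset so the kept set is left-right
      # symmetric; keep the positions farthest (in azimuth) from the nasion
      phi <- ((seq_len(n_nom) - 0.5) * 2 * pi / n_nom)
      wrapped <- abs(((phi + pi) %% (2 * pi)) - pi)  # distance from phi = 0
      phi <- phi[order(-wrapped)][seq_len(n_keep)]
    }
    pts[[i + 1L]] <- cbind(theta[i + 1L], phi)
  }
  tp <- do.call(rbind, lapply(pts, function(m) matrix(m, ncol = 2L)))
  # phi = 0 towards the nasion (+y), increasing towards +x (right)
  u <- cbind(sin(tp[, 1L]) * sin(tp[, 2L]),
             sin(tp[, 1L]) * cos(tp[, 2L]),
             cos(tp[, 1L]))
  v <- sweep(u, 2L, semi, `*`)
  n <- sweep(u, 2L, semi, `/`)
  n <- n / row_norms(n)
  pos <- v + standoff * n
  channels <- lapply(seq_len(nrow(pos)), function(i) {
    sensor_channel(pos[i, , drop = FALSE], n[i, , drop = FALSE], 1,
                   sprintf("E%04d", i))
  })
  new_sensor_array(channels, list(), "eeg_layout",
                   meta = list(scheme = scheme, standoff = standoff))
}

# response of one channel to a deterministic field B(x) (function of position)
channel_field_response <- function(channel, field_fun) {
  b <- t(apply(channel$coil_positions, 1L, field_fun))
  if (nrow(channel$coil_positions) == 1L) b <- matrix(b, 1L)
  sum(channel$coil_weights * rowSums(b * channel$coil_orientations))
}

# 8 basis fields: 3 uniform + 5 independent uniform first gradients
# (symmetric traceless, i.e. physical curl- and divergence-free gradients)
balance_basis_fields <- function() {
  gmats <- list(diag(c(1, -1, 0)), diag(c(0, 1, -1)),
                matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3L),
                matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3L),
                matrix(c(0, 0, 0, 0, 0, 1, 0, 1, 0), 3L))
  c(lapply(1:3, function(d) {
    e <- numeric(3L); e[d] <- 1
    function(x) e
  }),
  lapply(gmats, function(g) function(x) as.numeric(g %*% x)))
}

#' Synthetic reference balancing weights
#'
#' With `scheme = "off"` (the default elsewhere) the reference weights are
#' zero and channels are pure first-order gradiometers. With
#' `scheme = "balance"`, per-channel weights over the reference
#' magnetometers are chosen (minimum-norm least squares) so that the
#' balanced channel response to three uniform fields and five independent
#' uniform field gradients is nulled -- a documented stand-in for
#' recording-derived higher-order synthetic gradiometer coefficients.
#'
#' @param array a `sensor_array` with reference channels.
#' @param scheme "off" or "balance".
#' @return the array with its `reference_weights` replaced.
#' @export
form_reference_weights <- function(array, scheme = c("off", "balance")) {
  scheme <- match.arg(scheme)
  n_ref <- length(array$reference_channels)
  if (n_ref == 0L) stop("array has no reference channels")
  if (scheme == "off") {
    array$reference_weights <- matrix(0, n_channels(array), n_ref)
    return(array)
  }
  if (n_ref < 8L) {
    stop("balance scheme needs >= 8 reference channels, got ", n_ref)
  }
  basis <- balance_basis_fields()
  resp <- function(ch) vapply(basis, function(f) channel_field_response(ch, f),
                              numeric(1L))
  r_ref <- vapply(array$reference_channels, resp, numeric(8L))   # 8 x n_ref
  sv <- svd(r_ref)
  pos <- sv$d > max(sv$d) * 1e-12
  if (sum(pos) < 8L) {
    warning("reference response basis is rank ", sum(pos),
            " (< 8); balancing is least-squares, not exact")
  }
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  w <- t(vapply(array$channels, function(ch) as.numeric(pinv %*% resp(ch)),
                numeric(n_ref)))
  array$reference_weights <- w
  array
}

#' Serialise a sensor array
#'
#' JSON keeps the full structure (label, coil positions/orientations/
#' weights, kind, reference weights); CSV is a flat one-coil-per-row table.
#' Both round-trip losslessly through their readers.
#'
#' @param array a `sensor_array`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_array_json <- function(array, path) {
  ser_ch <- function(ch) list(label = ch$label,
                              coil_positions = ch$coil_positions,
                              coil_orientations = ch$coil_orientations,
                              coil_weights = ch$coil_weights)
  obj <- list(kind = array$kind,
              channels = lapply(array$channels, ser_ch),
              reference_channels = lapply(array$reference_channels, ser_ch),
              reference_weights = array$reference_weights,
              meta = array$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_array_json
#' @export
read_array_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  chs <- lapply(seq_len(length(obj$channels$label)), function(i) {
    sensor_channel(obj$channels$coil_positions[[i]],
                   obj$channels$coil_orientations[[i]],
                   obj$channels$coil_weights[[i]],
                   obj$channels$label[[i]])
  })
  nref <- length(obj$reference_channels$label)
  refs <- if (nref) lapply(seq_len(nref), function(i) {
    sensor_channel(obj$reference_channels$coil_positions[[i]],
                   obj$reference_channels$coil_orientations[[i]],
                   obj$reference_channels$coil_weights[[i]],
                   obj$reference_channels$label[[i]])
  }) else list()
  rw <- obj$reference_weights
  if (is.null(rw) || length(rw) == 0L) rw <- NULL else rw <- as.matrix(rw)
  new_sensor_array(chs, refs, obj$kind, reference_weights = rw,
                   meta = as.list(obj$meta))
}

#' @rdname write_array_json
#' @export
write_array_csv <- function(array, path) {
  rows <- list()
  emit <- function(ch, role) {
    k <- nrow(ch$coil_positions)
    data.frame(label = rep(ch$label, k), role = rep(role, k),
               coil = seq_len(k),
               x = ch$coil_positions[, 1L], y = ch$coil_positions[, 2L],
               z = ch$coil_positions[, 3L],
               ox = ch$coil_orientations[, 1L],
               oy = ch$coil_orientations[, 2L],
               oz = ch$coil_orientations[, 3L],
               weight = ch$coil_weights)
  }
  rows <- c(lapply(array$channels, emit, role = "sense"),
            lapply(array$reference_channels, emit, role = "reference"))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
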
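#' Build a synthetic head model
#'
#' Generates the anatomical substrate for the array simulations: a closed
#' "scalp" surface, a closed smooth "cortex" surface offset inward from it,
#' and three fiducial points (nasion, left/right pre-auricular). Surfaces
#' are geodesic octahedral tessellations mapped to an ellipsoid whose full
#' axis extents are `lr_width` (x, left-right), `ap_length` (y,
#' anterior-posterior) and `si_height` (z, superior-inferior), so the
#' requested head dimensions are matched exactly at the axis poles. The
#' cortex carries one prospective dipole per vertex, oriented along the
#' outward surface normal.
#'
#' The cortex surrogate carries deterministic band-limited radial
#' undulations (pseudo-folding): surface-normal dipoles on a perfectly
#' smooth offset surface would be nearly radial everywhere and therefore
#' almost externally silent in a spherical conductor model, which would
#' suppress every quantity this package studies. The undulations restore
#' the orientation diversity of folded cortex (normal tilts up to ~60
#' degrees) while keeping the surface closed and smooth at the mesh scale;
#' true sulcal geometry remains out of scope. Set
#' `cortex_wrinkle_amplitude = 0` for the exactly smooth (analytic-normal)
#' surrogate.
#'
#' Coordinates are right-handed: +x right, +y anterior, +z superior, origin
#' at the scalp centroid; metres throughout.
#'
#' @param ap_length anterior-posterior scalp extent (m); default the
#'   reference adult head, 0.213 m.
#' @param lr_width left-right scalp extent (m); default 0.146 m. Must be
#'   <= `ap_length`; equality (with `si_height` equal as well) gives a
#'   sphere.
#' @param si_height superior-inferior extent (m); not constrained by the
#'   reference geometry, default 0.18 m.
#' @param cortex_vertex_target requested cortex vertex count (>= 100). The
#'   subdivision frequency is chosen so the realised count (`4 f^2 + 2`) is
#'   as close as possible; 21401 gives 21316 vertices.
#' @param cortex_offset inward offset from scalp to cortex (m); default
#'   0.015 m, an average adult scalp-to-cortex distance.
#' @param scalp_vertex_target requested scalp vertex count.
#' @param bump_amplitude relative amplitude of smooth pseudo-random radial
#'   bumps on the scalp (0 = pure ellipsoid, the default). With bumps the
#'   normals are area-weighted mesh normals instead of analytic ones.
#' @param cortex_wrinkle_amplitude amplitude (m) of the cortical
#'   pseudo-folding displacement along the surface normal; default
#'   0.006 m (crests soft-bounded to ~2 amplitudes). 0 gives the exactly
#'   smooth offset surface with analytic normals.
#' @param cortex_wrinkle_frequency angular-frequency band of the folding
#'   (two numbers, dimensionless on the unit sphere; default c(10, 22),
#'   i.e. undulation wavelengths of roughly 2-5 cm on an adult cortex).
#' @param seed seed for the bump and wrinkle coefficients.
#' @return an object of class `head_model`: list with `scalp`, `cortex`
#'   (both [triangle_mesh()]), `fiducials` (3 x 3 named matrix), and the
#'   generating parameters.
#' @export
build_synthetic_head <- function(ap_length = 0.213, lr_width = 0.146,
                                 si_height = 0.18,
                                 cortex_vertex_target = 21401L,
                                 cortex_offset = 0.015,
                                 scalp_vertex_target = 10000L,
                                 bump_amplitude = 0,
                                 cortex_wrinkle_amplitude = 0.006,
                                 cortex_wrinkle_frequency = c(10, 22),
                                 seed = 1L) {
  stopifnot(ap_length >= lr_width, lr_width > 0, si_height > 0,
            cortex_vertex_target >= 100, cortex_offset > 0,
            bump_amplitude >= 0, bump_amplitude < 0.2,
            cortex_wrinkle_amplitude >= 0)
  semi_scalp <- c(lr_width, ap_length, si_height) / 2
  semi_cortex <- semi_scalp - cortex_offset
  if (any(semi_cortex <= 0)) {
    stop("geometric infeasibility: cortex_offset ", cortex_offset,
         " m leaves no room inside the scalp (cortex would intersect scalp)")
  }

  bump_coef <- if (bump_amplitude > 0) {
    with_seed(child_seed(seed, "bumps"), rnorm(6L))
  } else NULL

  scalp <- ellipsoid_mesh(semi_scalp, octa_frequency(scalp_vertex_target),
                          bump_amplitude, bump_coef)
  cortex <- ellipsoid_mesh(semi_cortex, octa_frequency(cortex_vertex_target))
  if (cortex_wrinkle_amplitude > 0) {
    # crests are soft-bounded to ~2 amplitudes and must stay inside the
    # (possibly bumped) scalp
    margin <- cortex_offset * (1 - bump_amplitude)
    if (cortex_wrinkle_amplitude * 2.05 >= margin) {
      stop("geometric infeasibility: cortex wrinkles of amplitude ",
           cortex_wrinkle_amplitude, " m could reach the scalp ",
           "(cortex would intersect scalp)")
    }
    cortex <- wrinkle_mesh(cortex, cortex_wrinkle_amplitude,
                           cortex_wrinkle_frequency,
                           child_seed(seed, "wrinkles"))
  }

  if (bump_amplitude > 0) {
    # conservative containment check under bumps
    r_unit <- row_norms(sweep(cortex$vertices, 2L, semi_scalp, `/`))
    if (any(r_unit >= 1 - bump_amplitude)) {
      stop("geometric infeasibility: bumped scalp may intersect cortex")
    }
  }

  fid <- rbind(nasion = c(0, semi_scalp[2L], 0),
               lpa = c(-semi_scalp[1L], 0, 0),
               rpa = c(semi_scalp[1L], 0, 0))
  if (bump_amplitude > 0) {
    # snap fiducials to the (bumped) scalp surface
    for (i in 1:3) {
      d <- colSums((t(scalp$vertices) - fid[i, ])^2)
      fid[i, ] <- scalp$vertices[which.min(d), ]
    }
  }
  colnames(fid) <- c("x", "y", "z")

  structure(list(scalp = scalp, cortex = cortex, fiducials = fid,
                 params = list(ap_length = ap_length, lr_width = lr_width,
                               si_height = si_height,
                               cortex_offset = cortex_offset,
                               bump_amplitude = bump_amplitude,
                               cortex_wrinkle_amplitude =
                                 cortex_wrinkle_amplitude,
                               cortex_wrinkle_frequency =
                                 cortex_wrinkle_frequency,
                               seed = as.integer(seed))),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf(paste0("head_model: scalp %d vertices, cortex %d vertices, ",
                     "extents %.1f x %.1f x %.1f mm\n"),
              nrow(x$scalp$vertices), nrow(x$cortex$vertices),
              1000 * x$params$lr_width, 1000 * x$params$ap_length,
              1000 * x$params$si_height))
  invisible(x)
}

# subdivision frequency whose 4 f^2 + 2 vertex count is nearest the target
octa_frequency <- function(target) {
  f0 <- sqrt((as.numeric(target) - 2) / 4)
  cand <- unique(pmax(1L, c(floor(f0), ceiling(f0))))
  cand[which.min(abs(4 * cand^2 + 2 - target))]
}

# Unit octasphere mapped to an ellipsoid (optionally with smooth radial
# bumps). Normals are analytic for the pure ellipsoid, mesh-derived with
# bumps.
ellipsoid_mesh <- function(semi, freq, bump_amplitude = 0, bump_coef = NULL) {
  s <- octasphere(freq)
  u <- s$vertices                       # unit directions
  if (bump_amplitude > 0) {
    b <- bump_field(u, bump_coef)
    v <- sweep(u * (1 + bump_amplitude * b), 2L, semi, `*`)
    triangle_mesh(v, s$faces, validate = FALSE)
  } else {
    v <- sweep(u, 2L, semi, `*`)
    n <- sweep(u, 2L, semi, `/`)        # gradient of the implicit ellipsoid
    n <- n / row_norms(n)
    triangle_mesh(v, s$faces, normals = n, validate = FALSE)
  }
}

# Band-limited pseudo-folding: displace each vertex along its (smooth)
# surface normal by a seeded sum of random plane waves on the unit
# direction sphere, scaled to ~unit variance. Normal tilts of
# ~amplitude * frequency / radius emulate gyral/sulcal orientation
# diversity. Normals are recomputed from the displaced mesh.
wrinkle_mesh <- function(mesh, amplitude, freq_band, seed, n_waves = 24L) {
  coef <- with_seed(seed, list(a = rnorm(n_waves),
                               dir = matrix(rnorm(3L * n_waves), n_waves, 3L),
                               s = runif(n_waves, freq_band[1L], freq_band[2L]),
                               phase = runif(n_waves, 0, 2 * pi)))
  dirs <- coef$dir / row_norms(coef$dir)
  u <- mesh$vertices / row_norms(mesh$vertices)  # unit directions
  w <- numeric(nrow(u))
  for (i in seq_len(n_waves)) {
    w <- w + coef$a[i] * sin(coef$s[i] * (u %*% dirs[i, ]) + coef$phase[i])
  }
  w <- w / sqrt(sum(coef$a^2) / 2)     # ~unit variance
  w <- 2 * tanh(w / 2)                 # soft-bound crests to ~2 amplitudes
  v <- mesh$vertices + amplitude * as.numeric(w) * mesh$normals
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

# smooth low-order polynomial field on the unit sphere, values in [-1, 1]
bump_field <- function(u, coef) {
  x <- u[, 1L]; y <- u[, 2L]; z <- u[, 3L]
  raw <- coef[1L] * x * y + coef[2L] * y * z + coef[3L] * x * z +
    coef[4L] * (x^2 - y^2) + coef[5L] * (y^2 - z^2) + coef[6L] * x * y * z
  raw / max(abs(raw))
}

#' Build the dipole source space from a head model
#'
#' One prospective current dipole per cortex vertex, oriented along the
#' outward per-vertex normal (dipoles perpendicular to the cortical
#' surface). When a reference array is supplied, the per-vertex depth is
#' the Euclidean distance to the nearest sensor (inner-coil measurement
#' point) of that array.
#'
#' @param head a [build_synthetic_head()] result (or compatible list).
#' @param reference_array optional `sensor_array` used to compute depths.
#' @return an object of class `source_space`: `positions` (n x 3 m),
#'   `orientations` (n x 3 unit), `depth` (n, m, or NA), `hemisphere`
#'   (factor left/midline/right by sign of x).
#' @export
make_source_space <- function(head, reference_array = NULL) {
  cortex <- head$cortex
  validate_mesh(cortex)
  pos <- cortex$vertices
  ori <- cortex$normals
  depth <- rep(NA_real_, nrow(pos))
  if (!is.null(reference_array)) {
    depth <- min_sensor_distance(pos, reference_array)
  }
  hemi <- factor(ifelse(pos[, 1L] > 1e-12, "right",
                        ifelse(pos[, 1L] < -1e-12, "left", "midline")),
                 levels = c("left", "midline", "right"))
  structure(list(positions = pos, orientations = ori, depth = depth,
                 hemisphere = hemi),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d dipoles (%d left / %d midline / %d right)\n",
              nrow(x$positions), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "midline"), sum(x$hemisphere == "right")))
  if (!all(is.na(x$depth))) {
    cat(sprintf("  depth to nearest sensor: %.1f - %.1f mm\n",
                1000 * min(x$depth), 1000 * max(x$depth)))
  }
  invisible(x)
}

# distance from each point to the nearest sensing (inner) coil of the array
min_sensor_distance <- function(points, array) {
  sens <- t(vapply(array$channels, function(ch) ch$coil_positions[1L, ],
                   numeric(3L)))
  d <- matrix(Inf, nrow(points), 1L)
  for (i in seq_len(nrow(sens))) {
    di <- sqrt((points[, 1L] - sens[i, 1L])^2 +
               (points[, 2L] - sens[i, 2L])^2 +
               (points[, 3L] - sens[i, 3L])^2)
    d <- pmin(d, di)
  }
  as.numeric(d)
}

#' Serialise a head model to a directory
#'
#' Writes `scalp.off`, `cortex.off` and `fiducials.json` (named x/y/z
#' triples in metres).
#'
#' @param head a `head_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_head_model <- function(head, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(head$scalp, file.path(dir, "scalp.off"))
  write_mesh(head$cortex, file.path(dir, "cortex.off"))
  fid <- lapply(seq_len(nrow(head$fiducials)),
                function(i) unname(head$fiducials[i, ]))
  names(fid) <- rownames(head$fiducials)
  jsonlite::write_json(fid, file.path(dir, "fiducials.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_head_model
#' @export
read_head_model <- function(dir) {
  fid <- jsonlite::read_json(file.path(dir, "fiducials.json"),
                             simplifyVector = TRUE)
  fidm <- do.call(rbind, fid)
  colnames(fidm) <- c("x", "y", "z")
  structure(list(scalp = read_mesh(file.path(dir, "scalp.off")),
                 cortex = read_mesh(file.path(dir, "cortex.off")),
                 fiducials = fidm, params = list()),
            class = "head_model")
}
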
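# Synthetic hindfoot phantom with known ground truth. Bone-like surfaces are
# seeded-random smooth perturbations of ellipsoids; the talus analogue
# carries an exact cylindrical patch (the posterior-facet analogue) whose
# axis orientation is prescribed in the canonical foot frame. The calcaneus
# analogue moves between postures by a prescribed rotation about a known
# axis plus a translation along the facet cylinder axis; each posture is
# additionally given a global "foot placement" motion, which registration on
# the talus must remove, emulating repositioning between scans.

#' Phantom specification
#'
#' Defaults are the package's reference study conditions: an 18 degree
#' everted-to-inverted calcaneal rotation (the physiological range between
#' maximally everted and inverted postures) about an axis at 40 degrees
#' sagittal inclination and 20 degrees medial deviation — the classical
#' orientation of the subtalar axis — with a 3 mm translation along the
#' facet cylinder axis, here near-horizontal and anteromedial (0 and 60
#' degrees), giving the oblique geometry in which the two representations of
#' the motion differ materially.
#'
#' @param facet_radius Facet cylinder radius (mm).
#' @param facet_arc Angular extent of the facet patch (degrees).
#' @param facet_length Facet patch extent along its axis (mm).
#' @param facet_axis_orientation `(inclination, deviation)` of the facet
#'   cylinder axis, degrees in the canonical foot frame.
#' @param rotation_axis_orientation `(inclination, deviation)` of the
#'   subtalar rotation axis, degrees.
#' @param rotation_deg Total everted-to-inverted rotation (degrees); the
#'   postures sit at 0 (neutral) and +/- half this angle.
#' @param translation_mm Total everted-to-inverted translation along the
#'   facet axis (mm); postures at 0 and +/- half.
#' @param axis_point Point on the rotation axis (mm).
#' @param bone_point_count Approximate vertex count per bone (>= 100).
#' @param surface_noise_sigma Gaussian noise s.d. along vertex normals (mm).
#' @param placement_deg Magnitude of the per-posture global foot-placement
#'   rotation (degrees; emulates tibial inclination between scans).
#' @param seed Integer seed; identical specs generate identical phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(facet_radius = 15, facet_arc = 120,
                         facet_length = 25,
                         facet_axis_orientation = c(0, 60),
                         rotation_axis_orientation = c(40, 20),
                         rotation_deg = 18, translation_mm = 3,
                         axis_point = c(5, 0, -12),
                         bone_point_count = 700,
                         surface_noise_sigma = 0, placement_deg = 20,
                         seed = 1L) {
  stopifnot(facet_radius > 0, facet_arc > 0, facet_arc <= 360,
            facet_length > 0, bone_point_count >= 100,
            surface_noise_sigma >= 0, length(facet_axis_orientation) == 2,
            length(rotation_axis_orientation) == 2, length(axis_point) == 3)
  structure(list(facet_radius = facet_radius, facet_arc = facet_arc,
                 facet_length = facet_length,
                 facet_axis_orientation = facet_axis_orientation,
                 rotation_axis_orientation = rotation_axis_orientation,
                 rotation_deg = rotation_deg, translation_mm = translation_mm,
                 axis_point = as.numeric(axis_point),
                 bone_point_count = as.integer(bone_point_count),
                 surface_noise_sigma = surface_noise_sigma,
                 placement_deg = placement_deg, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth random radial bump field over the sphere: sum of low-frequency
# cosines of the unit direction
random_bump_field <- function(n_terms = 6, amp = 1.2, freq = 0.35) {
  dirs <- matrix(rnorm(3 * n_terms), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- runif(n_terms, 0.3, 1) * amp
  phases <- runif(n_terms, 0, 2 * pi)
  freqs <- runif(n_terms, 0.5, 1) * freq
  function(U) {  # U: n x 3 unit directions; returns radial offset per row
    out <- numeric(nrow(U))
    for (k in seq_len(n_terms))
      out <- out + amps[k] * cos(freqs[k] * 40 * (U %*% dirs[k, ]) + phases[k])
    as.numeric(out)
  }
}

# UV-sphere triangulation of an irregular blob; normals approximated as
# radial (exact enough to direct surface noise)
blob_mesh <- function(center, semiaxes, n_vertices, bump) {
  n_lat <- max(6L, round(sqrt(n_vertices / 2)))
  n_lon <- max(8L, round(n_vertices / n_lat))
  th <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]   # exclude poles
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[seq_len(n_lon)]
  grid <- expand.grid(th = th, ph = ph)
  U <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
             cos(grid$th))
  r <- 1 / sqrt((U[, 1] / semiaxes[1])^2 + (U[, 2] / semiaxes[2])^2 +
                  (U[, 3] / semiaxes[3])^2)
  r <- r + bump(U)
  V <- sweep(U * r, 2, center, "+")
  # poles
  np <- nrow(V)
  V <- rbind(V, center + c(0, 0, semiaxes[3]), center - c(0, 0, semiaxes[3]))
  idx <- function(i, j) (j - 1L) * n_lat + i   # i: lat row, j: lon col
  faces <- list()
  for (j in seq_len(n_lon)) {
    j2 <- if (j == n_lon) 1L else j + 1L
    for (i in seq_len(n_lat - 1L)) {
      faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j2))
      faces[[length(faces) + 1]] <- c(idx(i + 1, j), idx(i + 1, j2), idx(i, j2))
    }
    faces[[length(faces) + 1]] <- c(np + 1L, idx(1L, j), idx(1L, j2))
    faces[[length(faces) + 1]] <- c(np + 2L, idx(n_lat, j2), idx(n_lat, j))
  }
  normals <- rbind(U, c(0, 0, 1), c(0, 0, -1))
  surface_mesh(V, do.call(rbind, faces), normals = normals)
}

# rectangular grid patch on a cylinder: axis through `point` along unit `a`,
# arc centred on direction `e_arc` (unit, perpendicular to a)
cylinder_patch <- function(point, a, radius, arc_deg, length_mm, e_arc,
                           n_u = 24, n_v = 16) {
  e1 <- unitize(e_arc - sum(e_arc * a) * a)
  e2 <- cross3(a, e1)
  s <- seq(-length_mm / 2, length_mm / 2, length.out = n_u)
  th <- seq(-deg2rad(arc_deg) / 2, deg2rad(arc_deg) / 2, length.out = n_v)
  grid <- expand.grid(s = s, th = th)
  V <- t(vapply(seq_len(nrow(grid)), function(k) {
    point + grid$s[k] * a +
      radius * (cos(grid$th[k]) * e1 + sin(grid$th[k]) * e2)
  }, numeric(3)))
  normals <- t(vapply(seq_len(nrow(grid)), function(k) {
    -(cos(grid$th[k]) * e1 + sin(grid$th[k]) * e2)  # inward: concave facet
  }, numeric(3)))
  idx <- function(i, j) (j - 1L) * n_u + i
  faces <- list()
  for (j in seq_len(n_v - 1L)) for (i in seq_len(n_u - 1L)) {
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
    faces[[length(faces) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1),
                                    idx(i, j + 1))
  }
  surface_mesh(V, do.call(rbind, faces), normals = normals)
}

append_mesh <- function(m1, m2) {
  n1 <- nrow(m1$vertices)
  surface_mesh(rbind(m1$vertices, m2$vertices),
               rbind(m1$faces, m2$faces + n1),
               normals = if (!is.null(m1$normals) && !is.null(m2$normals))
                 rbind(m1$normals, m2$normals))
}

# motion of the calcaneus for one posture: rotation by `ang` about the line
# (axis_point, n) followed by translation `s` along `a`
posture_motion <- function(ang_rad, s, n, a, axis_point) {
  if (abs(ang_rad) < .THETA_MIN) return(rigid_transform(diag(3), s * a))
  H <- rodrigues_rotation(n, abs(ang_rad))
  if (ang_rad < 0) H <- t(H)
  rigid_transform(H, as.numeric((diag(3) - H) %*% axis_point) + s * a)
}

#' Generate a synthetic hindfoot phantom
#'
#' Builds a talus analogue (irregular blob plus an exact cylindrical facet
#' patch, whose vertex indices are recorded), a calcaneus analogue
#' (irregular blob), and three postures. Per posture the calcaneus moves
#' relative to the talus by the prescribed rotation about the known axis
#' plus the prescribed translation along the facet cylinder axis (neutral:
#' none; inverted/everted: plus/minus half the totals), and the whole
#' hindfoot additionally receives a seeded global placement motion. Gaussian
#' surface noise of the requested s.d. is applied along vertex normals,
#' independently per posture.
#'
#' The attached ground truth contains the exact everted-to-inverted
#' calcaneus transform in the talus frame: composing the inverted motion
#' with the inverse of the everted motion, whose rotation angle and
#' facet-axis translation equal `rotation_deg` and `translation_mm` exactly.
#'
#' @param spec A [phantom_spec].
#' @return Object of class `posture_set`: per-posture `talus` and
#'   `calcaneus` meshes (`$neutral`, `$inverted`, `$everted`),
#'   `facet_indices` (1-based talus vertex indices of the facet patch),
#'   `landmarks`, and `ground_truth` (axes, per-posture motions, and the
#'   everted-to-inverted transform).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  frame <- canonical_foot_frame()
  a_true <- direction_from_angles(spec$facet_axis_orientation[1],
                                  spec$facet_axis_orientation[2], frame)
  n_true <- direction_from_angles(spec$rotation_axis_orientation[1],
                                  spec$rotation_axis_orientation[2], frame)

  geo <- with_seed(spec$seed, {
    talus_bump <- random_bump_field(amp = 2.5)
    calc_bump <- random_bump_field(amp = 3.5)
    list(
      talus_blob = blob_mesh(c(0, 0, 0), c(25, 18, 14),
                             spec$bone_point_count, talus_bump),
      calc_blob = blob_mesh(c(-12, 2, -32), c(38, 20, 16),
                            spec$bone_point_count, calc_bump),
      placement = lapply(c(inverted = 1, everted = -1), function(sgn) {
        # repositioning between scans: coronal-plane inclination about a
        # near-anteroposterior axis plus a small table offset, both scaled
        # by placement_deg (0 = no repositioning)
        ax <- unitize(c(1, 0, 0) + 0.15 * rnorm(3))
        compose_transform(
          rigid_transform(diag(3), rnorm(3, sd = 2 * spec$placement_deg / 20)),
          rigid_transform(rodrigues_rotation(ax,
                                             sgn * deg2rad(spec$placement_deg)),
                          c(0, 0, 0)))
      }))
  })

  facet <- cylinder_patch(spec$axis_point + c(-3, 0, 9), a_true,
                          spec$facet_radius, spec$facet_arc,
                          spec$facet_length, e_arc = c(0, 0, -1))
  talus <- append_mesh(geo$talus_blob, facet)
  facet_idx <- nrow(geo$talus_blob$vertices) + seq_len(nrow(facet$vertices))

  half_rot <- deg2rad(spec$rotation_deg) / 2
  half_tr <- spec$translation_mm / 2
  motions <- list(
    neutral = identity_transform(),
    inverted = posture_motion(half_rot, half_tr, n_true, a_true,
                              spec$axis_point),
    everted = posture_motion(-half_rot, -half_tr, n_true, a_true,
                             spec$axis_point))
  placements <- list(neutral = identity_transform(),
                     inverted = geo$placement$inverted,
                     everted = geo$placement$everted)

  move_mesh <- function(mesh, T) {
    surface_mesh(apply_transform(T, mesh$vertices), mesh$faces,
                 normals = if (!is.null(mesh$normals))
                   mesh$normals %*% t(T$rotation))
  }
  add_noise <- function(mesh, sigma, seed) {
    if (sigma <= 0) return(mesh)
    d <- with_seed(seed, rnorm(nrow(mesh$vertices), sd = sigma))
    surface_mesh(mesh$vertices + d * mesh$normals, mesh$faces,
                 normals = mesh$normals)
  }

  postures <- list()
  for (p in c("neutral", "inverted", "everted")) {
    G <- placements[[p]]
    tal <- move_mesh(talus, G)
    cal <- move_mesh(geo$calc_blob, compose_transform(G, motions[[p]]))
    pseed <- spec$seed + match(p, c("neutral", "inverted", "everted")) * 1000L
    postures[[p]] <- list(
      talus = add_noise(tal, spec$surface_noise_sigma, pseed),
      calcaneus = add_noise(cal, spec$surface_noise_sigma, pseed + 500L))
  }

  T_ev_to_inv <- compose_transform(motions$inverted,
                                   invert_transform(motions$everted))
  landmarks <- foot_landmarks(c(-60, 0, -50), c(120, 0, -50), c(0, 0, -50),
                              c(0, 0, 1), side = "right")
  structure(list(neutral = postures$neutral, inverted = postures$inverted,
                 everted = postures$everted, facet_indices = facet_idx,
                 landmarks = landmarks,
                 ground_truth = list(
                   rotation_axis = n_true, translation_direction = a_true,
                   axis_point = spec$axis_point,
                   rotation_deg = spec$rotation_deg,
                   translation_mm = spec$translation_mm,
                   posture_motions = motions,
                   placements = placements,
                   everted_to_inverted = T_ev_to_inv),
                 spec = spec),
            class = "posture_set")
}

#' @export
print.posture_set <- function(x, ...) {
  cat(sprintf(
    "<posture_set> talus %d + calcaneus %d vertices per posture; facet patch %d vertices\n",
    nrow(x$neutral$talus$vertices), nrow(x$neutral$calcaneus$vertices),
    length(x$facet_indices)))
  cat(sprintf("  ground truth: %.1f deg about (%.3f, %.3f, %.3f), %.1f mm along (%.3f, %.3f, %.3f)\n",
              x$ground_truth$rotation_deg, x$ground_truth$rotation_axis[1],
              x$ground_truth$rotation_axis[2], x$ground_truth$rotation_axis[3],
              x$ground_truth$translation_mm,
              x$ground_truth$translation_direction[1],
              x$ground_truth$translation_direction[2],
              x$ground_truth$translation_direction[3]))
  invisible(x)
}

#' Write a phantom to disk in the pipeline's input formats
#'
#' Writes per-posture talus/calcaneus PLY meshes, the facet-patch index file
#' (0-based, one index per line), the landmark file, and a ground-truth
#' manifest (JSON), so the synthetic data can be consumed exactly like real
#' scans.
#'
#' @param phantom A `posture_set` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "posture_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (p in c("neutral", "inverted", "everted")) {
    for (b in c("talus", "calcaneus")) {
      f <- file.path(dir, sprintf("%s_%s.ply", p, b))
      write_mesh(phantom[[p]][[b]], f)
      files[sprintf("%s_%s", p, b)] <- f
    }
  }
  f <- file.path(dir, "facet_indices.txt")
  writeLines(as.character(phantom$facet_indices - 1L), f)
  files["facet_indices"] <- f
  f <- file.path(dir, "landmarks.txt")
  write_landmarks(phantom$landmarks, f)
  files["landmarks"] <- f
  gt <- phantom$ground_truth
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    rotation_axis = gt$rotation_axis,
    translation_direction = gt$translation_direction,
    axis_point = gt$axis_point, rotation_deg = gt$rotation_deg,
    translation_mm = gt$translation_mm,
    everted_to_inverted = list(rotation = gt$everted_to_inverted$rotation,
                               translation = gt$everted_to_inverted$translation)),
    f, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  files["ground_truth"] <- f
  invisible(files)
}

#' Read the facet-patch vertex index file
#'
#' Plain text, one 0-based vertex index per line, referencing the talus mesh
#' vertex order; returned 1-based for use in R.
#'
#' @param path Path to the index file.
#' @param n_vertices Optional vertex count for range validation.
#' @return Integer vector of 1-based indices.
#' @export
read_facet_indices <- function(path, n_vertices = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  idx <- suppressWarnings(as.integer(lines))
  if (!length(idx) || anyNA(idx) || any(idx < 0))
    stop(sprintf("'%s' must hold non-negative integers, one per line", path),
         call. = FALSE)
  idx <- idx + 1L
  if (!is.null(n_vertices) && any(idx > n_vertices))
    stop(sprintf("'%s' contains indices beyond the talus vertex count", path),
         call. = FALSE)
  idx
}
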
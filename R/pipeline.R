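# End-to-end subtalar analysis: from three posture surfaces to both axis
# representations and a per-foot report. The neutral posture is the
# registration reference; the motion analysed is the everted-to-inverted
# calcaneus transform in the (neutral) talus frame.

stage_error <- function(stage, e) {
  stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full subtalar-axis analysis
#'
#' Pipeline: (1) calcaneus motion for the everted and inverted postures via
#' two-step ICP registration against the neutral posture; (2) cylinder fit
#' to the posterior-facet patch of the neutral talus; (3) helical
#' decomposition of the everted-to-inverted calcaneus transform; (4) oblique
#' decomposition of the same transform with translation along the fitted
#' facet axis, including the forward/inverse axis pair; (5) foot frame from
#' landmarks and orientation angles of both axes. Any stage failure raises
#' an error naming the stage; no partial report is produced.
#'
#' @param postures A `posture_set` (from [generate_phantom()] or
#'   [read_posture_set()]): `$neutral`, `$inverted`, `$everted`, each with
#'   `talus` and `calcaneus` surfaces.
#' @param facet_indices 1-based vertex indices of the posterior-facet patch
#'   on the neutral talus (default: `postures$facet_indices`).
#' @param landmarks A [foot_landmarks] object (default:
#'   `postures$landmarks`).
#' @param params An [icp_params] object.
#' @param foot_id Label used in reports.
#' @return Object of class `subtalar_report`. Key fields: `rotation_deg`,
#'   `translation_facet_mm` (along the fitted facet axis),
#'   `translation_helical_mm`, `helical_axis`, `oblique_axis_forward`,
#'   `oblique_axis_inverse` (each point + direction, talus frame),
#'   `cylinder` summary, `registration_rms_mm`, and orientation angles of
#'   both axes in the foot frame.
#' @export
run_subtalar_analysis <- function(postures, facet_indices = NULL,
                                  landmarks = NULL, params = icp_params(),
                                  foot_id = "phantom") {
  if (is.null(facet_indices)) facet_indices <- postures$facet_indices
  if (is.null(landmarks)) landmarks <- postures$landmarks
  if (is.null(facet_indices))
    stage_error("inputs", simpleError("no facet-patch indices supplied"))
  if (is.null(landmarks))
    stage_error("inputs", simpleError("no landmarks supplied"))
  ntal <- as_points(postures$neutral$talus)
  if (max(facet_indices) > nrow(ntal) || min(facet_indices) < 1)
    stage_error("inputs",
                simpleError("facet indices outside the neutral talus"))

  T_inv <- tryCatch(calcaneus_motion(postures$neutral, postures$inverted,
                                     params),
                    error = function(e) stage_error("registration", e))
  T_ev <- tryCatch(calcaneus_motion(postures$neutral, postures$everted,
                                    params),
                   error = function(e) stage_error("registration", e))
  T_motion <- compose_transform(T_inv, invert_transform(T_ev))

  frame <- tryCatch(build_foot_frame(landmarks),
                    error = function(e) stage_error("foot_frame", e))
  anterior <- frame$basis[, 1]
  cyl <- tryCatch(
    fit_cylinder(ntal[facet_indices, , drop = FALSE], hint = anterior),
    error = function(e) stage_error("cylinder_fit", e))

  helical <- helical_decompose(T_motion)
  if (helical$pure_translation)
    stage_error("helical_decomposition",
                simpleError("motion is a pure translation"))
  obl <- tryCatch(oblique_decompose(T_motion, cyl$direction),
                  error = function(e) stage_error("oblique_decomposition", e))
  pair <- axis_pair(T_motion, cyl$direction)

  n <- helical$angle_axis$axis
  ori_helical <- axis_orientation_angles(n, frame)
  ori_facet <- axis_orientation_angles(obl$a, frame)

  structure(list(
    foot_id = foot_id,
    rotation_deg = rad2deg(helical$angle_axis$angle),
    translation_facet_mm = obl$alpha,
    translation_helical_mm = helical$L,
    helical_axis = list(point = helical$axis_point, direction = n),
    oblique_axis_forward = pair$forward,
    oblique_axis_inverse = pair$inverse,
    oblique_axis_separation_mm = pair$separation,
    facet_axis = obl$a,
    conditioning = obl$conditioning,
    cylinder = list(radius_mm = cyl$radius, rms_mm = cyl$rms_residual,
                    n_points = cyl$n_points,
                    point_on_axis = cyl$point_on_axis),
    registration_rms_mm = list(
      inverted = c(talus = attr(T_inv, "talus_rms"),
                   calcaneus = attr(T_inv, "calcaneus_rms")),
      everted = c(talus = attr(T_ev, "talus_rms"),
                  calcaneus = attr(T_ev, "calcaneus_rms"))),
    axis_orientation = list(
      helical = list(inclination_deg = ori_helical$sagittal_inclination,
                     deviation_deg = ori_helical$horizontal_deviation),
      facet = list(inclination_deg = ori_facet$sagittal_inclination,
                   deviation_deg = ori_facet$horizontal_deviation)),
    transform = T_motion),
    class = "subtalar_report")
}

#' @export
print.subtalar_report <- function(x, ...) {
  cat(sprintf("<subtalar_report> foot %s (everted -> inverted)\n", x$foot_id))
  cat(sprintf("  rotation: %.1f deg about (%.3f, %.3f, %.3f)\n",
              x$rotation_deg, x$helical_axis$direction[1],
              x$helical_axis$direction[2], x$helical_axis$direction[3]))
  cat(sprintf("  translation along facet axis: %.1f mm; along helical axis: %.1f mm\n",
              x$translation_facet_mm, x$translation_helical_mm))
  cat(sprintf("  facet cylinder: r = %.1f mm, fit rms = %.3g mm (%d points)\n",
              x$cylinder$radius_mm, x$cylinder$rms_mm, x$cylinder$n_points))
  cat(sprintf("  rotation axis: %.1f deg inclination, %.1f deg medial deviation\n",
              x$axis_orientation$helical$inclination_deg,
              x$axis_orientation$helical$deviation_deg))
  invisible(x)
}

#' Write an analysis report as JSON (and optionally a CSV summary row)
#'
#' The JSON carries full precision. The CSV summary mirrors the
#' three-column per-foot layout customary for this analysis — foot id,
#' rotation (degrees), translation along the talus posterior facet (mm),
#' translation along the helical axis (mm) — rounded to one decimal place.
#'
#' @param report A `subtalar_report`.
#' @param path Output JSON path.
#' @param csv Optional path for the one-row CSV summary.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = NULL) {
  stopifnot(inherits(report, "subtalar_report"))
  out <- unclass(report)
  out$transform <- list(rotation = report$transform$rotation,
                        translation = report$transform$translation)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  if (!is.null(csv)) {
    df <- data.frame(
      foot = report$foot_id,
      rotation_deg = sprintf("%.1f", report$rotation_deg),
      translation_facet_mm = sprintf("%.1f", report$translation_facet_mm),
      translation_helical_mm = sprintf("%.1f", report$translation_helical_mm))
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path Path written by [write_report()].
#' @return A `subtalar_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- x$transform$rotation
  if (!is.matrix(rot)) rot <- matrix(unlist(rot), 3, 3, byrow = TRUE)
  x$transform <- rigid_transform(rot, x$transform$translation)
  structure(x, class = "subtalar_report")
}

#' Format a report as the standard per-foot summary row
#'
#' @param report A `subtalar_report`.
#' @return Character scalar, e.g. `"A, 17.6, 4.0, 1.7"`.
#' @export
report_summary_row <- function(report) {
  sprintf("%s, %.1f, %.1f, %.1f", report$foot_id, report$rotation_deg,
          report$translation_facet_mm, report$translation_helical_mm)
}

#' Read a posture set from mesh files on disk
#'
#' @param paths Named list/vector with entries `neutral_talus`,
#'   `neutral_calcaneus`, `inverted_talus`, `inverted_calcaneus`,
#'   `everted_talus`, `everted_calcaneus` (STL or PLY paths), and optionally
#'   `facet_indices` and `landmarks`.
#' @return A `posture_set`.
#' @export
read_posture_set <- function(paths) {
  paths <- as.list(paths)
  need <- c("neutral_talus", "neutral_calcaneus", "inverted_talus",
            "inverted_calcaneus", "everted_talus", "everted_calcaneus")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("missing posture mesh paths: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list(
    neutral = list(talus = read_mesh(paths$neutral_talus),
                   calcaneus = read_mesh(paths$neutral_calcaneus)),
    inverted = list(talus = read_mesh(paths$inverted_talus),
                    calcaneus = read_mesh(paths$inverted_calcaneus)),
    everted = list(talus = read_mesh(paths$everted_talus),
                   calcaneus = read_mesh(paths$everted_calcaneus)))
  if (!is.null(paths$facet_indices))
    out$facet_indices <- read_facet_indices(paths$facet_indices,
                                            nrow(out$neutral$talus$vertices))
  if (!is.null(paths$landmarks))
    out$landmarks <- read_landmarks(paths$landmarks)
  structure(out, class = "posture_set")
}

#' Export an axis line as a two-vertex PLY segment for external viewers
#'
#' @param point,direction Axis line (mm, unit 3-vector).
#' @param path Output `.ply` path.
#' @param half_length Half-length of the exported segment (mm).
#' @return `path`, invisibly.
#' @export
write_axis_segment <- function(point, direction, path, half_length = 60) {
  direction <- unitize(direction)
  V <- rbind(point - half_length * direction, point + half_length * direction)
  # a degenerate triangle keeps the file a valid mesh
  write_ply(surface_mesh(rbind(V, V[2, ]), matrix(c(1L, 2L, 3L), 1)), path,
            ascii = TRUE)
  invisible(path)
}
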
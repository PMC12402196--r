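# Anatomical foot coordinate frame and axis-orientation reporting. The frame
# follows the classical convention for the subtalar axis: x along the long
# axis of the foot (calcaneal tuberosity to second metatarsal head, in the
# plantar plane), y perpendicular to x and parallel to the plantar surface,
# z their cross product (dorsal). Joint-axis orientation is then reported as
# sagittal inclination above the plantar plane and horizontal deviation from
# the long axis, medial positive.

#' Foot landmarks
#'
#' @param calcaneal_tuberosity,second_metatarsal_head 3-vectors (mm).
#' @param plantar_point Point on the plantar support plane (mm).
#' @param plantar_normal Normal of the plantar plane, pointing dorsally
#'   (toward the bones).
#' @param side `"left"` or `"right"`.
#' @return Object of class `foot_landmarks`.
#' @export
foot_landmarks <- function(calcaneal_tuberosity, second_metatarsal_head,
                           plantar_point, plantar_normal,
                           side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(length(calcaneal_tuberosity) == 3,
            length(second_metatarsal_head) == 3,
            length(plantar_point) == 3, length(plantar_normal) == 3)
  if (sqrt(sum((second_metatarsal_head - calcaneal_tuberosity)^2)) < 1e-9)
    stop("tuberosity and metatarsal head coincide", call. = FALSE)
  structure(list(calcaneal_tuberosity = as.numeric(calcaneal_tuberosity),
                 second_metatarsal_head = as.numeric(second_metatarsal_head),
                 plantar_point = as.numeric(plantar_point),
                 plantar_normal = unitize(as.numeric(plantar_normal)),
                 side = side),
            class = "foot_landmarks")
}

#' Build the foot coordinate frame from landmarks
#'
#' The x axis is the unit vector from the calcaneal tuberosity to the second
#' metatarsal head projected into the plantar plane; y is perpendicular to x
#' and parallel to the plantar plane; z = x cross y points dorsally. The
#' basis is always right-handed (det +1): y is the dorsal normal crossed
#' with x, which is the medial direction for right feet and the lateral one
#' for left feet — the medial-positive sign convention is applied when
#' reporting deviation angles, via the stored `side`. Origin is the
#' calcaneal tuberosity.
#'
#' @param landmarks A [foot_landmarks] object.
#' @return Object of class `foot_frame`: `origin` (mm), `basis` (3x3,
#'   columns x/y/z in the global frame), `side`.
#' @export
build_foot_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "foot_landmarks"))
  nrm <- landmarks$plantar_normal
  long <- landmarks$second_metatarsal_head - landmarks$calcaneal_tuberosity
  x <- long - sum(long * nrm) * nrm
  if (sqrt(sum(x^2)) < 1e-9)
    stop("foot long axis is (near) parallel to the plantar normal",
         call. = FALSE)
  x <- unitize(x)
  y <- cross3(nrm, x)              # in-plane, perpendicular to x
  z <- cross3(x, y)                # == nrm; dorsal by construction
  structure(list(origin = landmarks$calcaneal_tuberosity,
                 basis = cbind(x, y, z), side = landmarks$side),
            class = "foot_frame")
}

#' Orientation angles of a joint axis in the foot frame
#'
#' The axis (canonicalised to point anteriorly, i.e. positive x component in
#' the frame) is reported as its sagittal inclination above the plantar
#' plane, `asin(axis . z)`, and the horizontal deviation of its in-plane
#' projection from the long axis, with medial deviation positive for either
#' side.
#'
#' @param axis Unit 3-vector in global coordinates.
#' @param frame A [foot_frame].
#' @return Object of class `axis_orientation`: `sagittal_inclination` and
#'   `horizontal_deviation` (degrees), plus `deviation_defined` (FALSE when
#'   the axis is perpendicular to the plantar plane).
#' @export
axis_orientation_angles <- function(axis, frame) {
  stopifnot(inherits(frame, "foot_frame"), length(axis) == 3)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("`axis` must be a unit vector", call. = FALSE)
  u <- as.numeric(crossprod(frame$basis, axis))   # frame coordinates
  if (u[1] < 0) u <- -u
  inclination <- rad2deg(asin(min(1, max(-1, u[3]))))
  horiz <- sqrt(u[1]^2 + u[2]^2)
  if (horiz < 1e-9) {
    return(structure(list(sagittal_inclination = inclination,
                          horizontal_deviation = NA_real_,
                          deviation_defined = FALSE),
                     class = "axis_orientation"))
  }
  dev <- rad2deg(atan2(u[2], u[1]))
  if (frame$side == "left") dev <- -dev   # +y is lateral on left feet
  structure(list(sagittal_inclination = inclination,
                 horizontal_deviation = dev, deviation_defined = TRUE),
            class = "axis_orientation")
}

#' @export
print.axis_orientation <- function(x, ...) {
  cat(sprintf("<axis_orientation> inclination %.2f deg, deviation %s\n",
              x$sagittal_inclination,
              if (x$deviation_defined)
                sprintf("%.2f deg (medial positive)", x$horizontal_deviation)
              else "undefined (axis vertical)"))
  invisible(x)
}

#' Direction at given orientation angles in a foot frame
#'
#' Inverse of [axis_orientation_angles()]: builds the unit global-frame
#' direction with the requested sagittal inclination and (medial-positive)
#' horizontal deviation.
#'
#' @param inclination,deviation Angles in degrees.
#' @param frame A [foot_frame]; defaults to the canonical identity frame of
#'   a right foot.
#' @return Unit 3-vector in global coordinates.
#' @export
direction_from_angles <- function(inclination, deviation,
                                  frame = canonical_foot_frame()) {
  i <- deg2rad(inclination)
  d <- deg2rad(if (frame$side == "left") -deviation else deviation)
  u <- c(cos(i) * cos(d), cos(i) * sin(d), sin(i))
  as.numeric(frame$basis %*% u)
}

#' Canonical identity foot frame (right foot, axes = global axes)
#' @return A `foot_frame`.
#' @export
canonical_foot_frame <- function() {
  structure(list(origin = c(0, 0, 0), basis = diag(3), side = "right"),
            class = "foot_frame")
}

#' Read foot landmarks from a key-value text file
#'
#' Expected schema, one `key: x y z` entry per line (`side` takes a single
#' word); `#` starts a comment:
#' \preformatted{
#' calcaneal_tuberosity: -60 0 -50
#' second_metatarsal_head: 120 5 -48
#' plantar_point: 0 0 -50
#' plantar_normal: 0 0 1
#' side: right
#' }
#'
#' @param path Path to the landmark file.
#' @return A [foot_landmarks] object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("cannot parse '%s' line %d: expected 'key: value'",
                   path, i), call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  need <- c("calcaneal_tuberosity", "second_metatarsal_head",
            "plantar_point", "plantar_normal", "side")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop(sprintf("'%s' is missing landmark keys: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  vec <- function(key) {
    v <- suppressWarnings(as.numeric(strsplit(kv[[key]], "\\s+")[[1]]))
    if (length(v) != 3 || anyNA(v))
      stop(sprintf("'%s': key '%s' must hold three numbers", path, key),
           call. = FALSE)
    v
  }
  foot_landmarks(vec("calcaneal_tuberosity"), vec("second_metatarsal_head"),
                 vec("plantar_point"), vec("plantar_normal"),
                 side = kv[["side"]])
}

#' Write foot landmarks to the key-value text format
#'
#' @param landmarks A [foot_landmarks] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "foot_landmarks"))
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(c(
    paste("calcaneal_tuberosity:", fmt(landmarks$calcaneal_tuberosity)),
    paste("second_metatarsal_head:", fmt(landmarks$second_metatarsal_head)),
    paste("plantar_point:", fmt(landmarks$plantar_point)),
    paste("plantar_normal:", fmt(landmarks$plantar_normal)),
    paste("side:", landmarks$side)), path)
  invisible(path)
}
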
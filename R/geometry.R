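#' Detector pose
#'
#' The pose of the fragment tracker in the room frame: a rotation mapping
#' detector-local coordinates into the room frame, the position of the
#' detector face center, and the per-axis positioning uncertainty.
#'
#' @param rotation 3x3 orthonormal matrix (detector-local to room frame).
#' @param translation numeric length-3, face-center position, mm.
#' @param sigma_xyz numeric length-3, per-axis positioning sigma, mm
#'   (laser-tracker survey accuracy; nominally 1-1.5 mm).
#' @return An object of class `detector_pose`.
#' @export
detector_pose <- function(rotation, translation, sigma_xyz = c(1.5, 1.5, 1.5)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("pose rotation must be a 3x3 orthonormal matrix")
  }
  translation <- as.numeric(translation)
  sigma_xyz <- as.numeric(sigma_xyz)
  stopifnot(length(translation) == 3L, length(sigma_xyz) == 3L)
  if (any(sigma_xyz < 0)) stop("sigma_xyz components must be >= 0")
  structure(list(rotation = rotation, translation = translation,
                 sigma_xyz = sigma_xyz), class = "detector_pose")
}

#' Nominal tracker pose
#'
#' Builds the tracker's nominal clinical pose: face center at `distance`
#' from the isocenter along a direction tilted `tilt` degrees from the beam
#' axis and elevated `elevation` degrees, with the detector face normal
#' pointing back at the isocenter.
#'
#' @param distance face-center stand-off from the isocenter, mm.
#' @param tilt angle between the face-center direction and the beam (+z),
#'   degrees.
#' @param elevation upward elevation of the face-center direction, degrees.
#' @param sigma_xyz per-axis positioning sigma, mm.
#' @return A [detector_pose()].
#' @export
nominal_pose <- function(distance = 500, tilt = 60, elevation = 30,
                         sigma_xyz = c(1.5, 1.5, 1.5)) {
  th <- tilt * pi / 180
  el <- elevation * pi / 180
  # face-center direction: polar angle `tilt` from +z, transverse part split
  # between horizontal x and vertical y by the elevation angle
  u <- c(sin(th) * cos(el), sin(th) * sin(el), cos(th))
  centre <- distance * u
  # detector local frame: w = normal toward isocenter, (a, b) span the face
  w <- -u
  a <- c(-u[3], 0, u[1]) / sqrt(u[1]^2 + u[3]^2)  # horizontal-ish face axis
  b <- cross3(w, a)
  rot <- cbind(a, b, w)
  dimnames(rot) <- NULL
  detector_pose(rot, centre, sigma_xyz)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Construct a track table
#'
#' A track table holds one reconstructed fragment track per row: a point on
#' the fitted line (at the detector front face), a unit direction oriented
#' from the detector toward the patient, a timestamp since spill-sequence
#' start, and the pencil beam active when the track was recorded.
#'
#' @param x,y,z point on the track line, mm (room frame).
#' @param dx,dy,dz unit direction components.
#' @param t timestamp, s (>= 0).
#' @param pb_id pencil-beam identifier (integer).
#' @param fraction_id fraction identifier.
#' @return A `data.frame` with class `track_table`.
#' @export
track_table <- function(x, y, z, dx, dy, dz, t, pb_id, fraction_id) {
  tr <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
                   t = as.numeric(t), pb_id = as.integer(pb_id),
                   fraction_id = rep_len(as.character(fraction_id), length(x)))
  validate_tracks(tr)
  class(tr) <- c("track_table", "data.frame")
  tr
}

validate_tracks <- function(tr) {
  need <- c("x", "y", "z", "dx", "dy", "dz", "t", "pb_id", "fraction_id")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "))
  }
  nrm <- sqrt(tr$dx^2 + tr$dy^2 + tr$dz^2)
  if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-9)) {
    stop("track directions must be unit vectors (|d| = 1 within 1e-9)")
  }
  if (any(tr$t < 0)) stop("track timestamps must be >= 0")
  invisible(tr)
}

#' Transform tracks from detector-local to room frame
#'
#' Applies the pose rotation to points and directions and the translation to
#' points only.
#'
#' @param tracks a track table in detector-local coordinates.
#' @param pose a [detector_pose()].
#' @return The track table in room-frame coordinates.
#' @export
transform_track <- function(tracks, pose) {
  stopifnot(inherits(pose, "detector_pose"))
  R <- pose$rotation
  p <- as.matrix(tracks[, c("x", "y", "z")]) %*% t(R)
  d <- as.matrix(tracks[, c("dx", "dy", "dz")]) %*% t(R)
  tracks$x <- p[, 1] + pose$translation[1]
  tracks$y <- p[, 2] + pose$translation[2]
  tracks$z <- p[, 3] + pose$translation[3]
  tracks$dx <- d[, 1]; tracks$dy <- d[, 2]; tracks$dz <- d[, 3]
  tracks
}

#' Point of closest approach between two straight lines
#'
#' Closed-form mutual-perpendicular construction, vectorized over rows. For
#' each pair of lines (p1 + s*d1, p2 + u*d2) returns the midpoint of the
#' shortest segment joining them, the line-line distance, and the arc
#' lengths s (on line 1) and u (on line 2) of the segment feet. Pairs whose
#' directions are parallel within `tol` (|d1 x d2| < tol) are flagged
#' `degenerate` and reported at the perpendicular foot of p1 on line 2.
#'
#' @param p1,d1 n x 3 matrices: point and unit direction of the first line.
#' @param p2,d2 n x 3 matrices (or length-3 vectors recycled): point and
#'   unit direction of the second line.
#' @param tol degeneracy threshold on |d1 x d2|.
#' @return `data.frame` with columns `x`, `y`, `z` (midpoint), `miss`
#'   (line-line distance, mm), `s1`, `s2` (segment-foot arc lengths), and
#'   `degenerate`.
#' @export
closest_approach <- function(p1, d1, p2, d2, tol = 1e-9) {
  p1 <- rbind3(p1); d1 <- rbind3(d1); n <- nrow(p1)
  p2 <- rbind3(p2, n); d2 <- rbind3(d2, n)
  n1 <- rowSums(d1^2); n2 <- rowSums(d2^2)
  if (any(n1 < .Machine$double.eps) || any(n2 < .Machine$double.eps)) {
    stop("zero-length direction vector")
  }
  w0 <- p1 - p2
  b <- rowSums(d1 * d2)
  d <- rowSums(d1 * w0)
  e <- rowSums(d2 * w0)
  denom <- n1 * n2 - b^2              # = |d1 x d2|^2 for unit directions
  degen <- denom < tol^2
  s <- ifelse(degen, 0, (b * e - d * n2) / pmax(denom, .Machine$double.xmin))
  u <- ifelse(degen, e / n2, (e * n1 - b * d) / pmax(denom, .Machine$double.xmin))
  f1 <- p1 + s * d1
  f2 <- p2 + u * d2
  mid <- (f1 + f2) / 2
  if (any(degen)) mid[degen, ] <- f2[degen, ]  # foot on line 2 for parallels
  miss <- sqrt(rowSums((f1 - f2)^2))
  data.frame(x = mid[, 1], y = mid[, 2], z = mid[, 3],
             miss = miss, s1 = s, s2 = u, degenerate = degen)
}

rbind3 <- function(m, n = NULL) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3, byrow = TRUE)
  m <- as.matrix(m)
  if (!is.null(n) && nrow(m) == 1L && n > 1L) {
    m <- m[rep(1L, n), , drop = FALSE]
  }
  m
}

#' Compute PCA points of tracks against their pencil-beam axes
#'
#' For every track, computes the point of closest approach (PCA) between the
#' track line and the axis of the pencil beam active when the track was
#' recorded. The beam axis runs along +z through the spot's lateral position
#' at the isocenter plane, so `s_beam` (arc length along the axis from the
#' isocenter) equals the z coordinate of the axis foot.
#'
#' @param tracks a track table (room frame).
#' @param plan a plan table (see [plan_table()]) providing `pb_id`,
#'   `x_mm`, `y_mm` spot positions.
#' @return `data.frame` with one row per track: PCA `x`, `y`, `z`, `miss`
#'   distance (mm), `s_beam` (mm), `degenerate`, plus `t`, `pb_id`,
#'   `fraction_id` carried over.
#' @export
compute_pca <- function(tracks, plan) {
  validate_tracks(tracks)
  idx <- match(tracks$pb_id, plan$pb_id)
  if (anyNA(idx)) stop("track pb_id not present in plan")
  p1 <- as.matrix(tracks[, c("x", "y", "z")])
  d1 <- as.matrix(tracks[, c("dx", "dy", "dz")])
  p2 <- cbind(plan$x_mm[idx], plan$y_mm[idx], 0)
  d2 <- matrix(rep(c(0, 0, 1), each = nrow(p1)), ncol = 3)
  ca <- closest_approach(p1, d1, p2, d2)
  data.frame(x = ca$x, y = ca$y, z = ca$z, miss = ca$miss,
             s_beam = ca$s2, degenerate = ca$degenerate,
             t = tracks$t, pb_id = tracks$pb_id,
             fraction_id = tracks$fraction_id)
}
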
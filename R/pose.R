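# Pose (frame) objects and rigid-body pose estimation from marker triplets.

#' Create a pose (coordinate frame)
#'
#' A pose houses the tuple (origin, rotation) of a frame expressed with
#' respect to a parent frame. The transform convention follows the sensing
#' convention used throughout this package: a point `v` expressed in the
#' child frame maps to the parent frame as `R %*% v - origin`, i.e. the
#' stored origin is subtracted *after* rotation. The physical location of the
#' child frame's origin in the parent frame is therefore `-origin`; use
#' [pose_at()] to construct a pose from that location directly, and
#' [pose_position()] to read it back.
#'
#' @param origin numeric 3-vector, meters (the `o` in `R v - o`).
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param frame label of the parent frame (`"e"`, `"l"`, `"s"`, `"h"`, `"n"`
#'   or any identifier).
#' @return an object of class `pose`.
#' @export
pose <- function(origin = c(0, 0, 0), rotation = diag(3), frame = "l") {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  assert_rotation(rotation, "pose rotation")
  structure(list(origin = origin, rotation = rotation, frame = frame),
            class = "pose")
}

#' @rdname pose
#' @param position physical location of the frame origin in the parent frame.
#' @export
pose_at <- function(position = c(0, 0, 0), rotation = diag(3), frame = "l") {
  pose(origin = -as.numeric(position), rotation = rotation, frame = frame)
}

#' @rdname pose
#' @param p a `pose`.
#' @export
pose_position <- function(p) -p$origin

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose in frame '%s'>\n", x$frame))
  cat("position (m):", format(pose_position(x), digits = 4), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Transform a point between frames
#'
#' Maps a point expressed in the pose's child frame into the parent frame as
#' `R %*% v - origin` (origin subtracted after rotation).
#'
#' @param v numeric 3-vector (point, meters) in the child frame.
#' @param p a [pose()] of the child frame in the parent frame.
#' @param frame optional label of the frame `v` is expressed in; if supplied
#'   it must match the pose's child... see Details.
#' @details When `frame` is given it is checked against the pose's `frame`
#'   attribute chain: transforming a vector labeled for a different frame is
#'   a labeled error of class `neckstick_frame_mismatch`.
#' @return numeric 3-vector in the parent frame.
#' @export
transform_point <- function(v, p, frame = NULL) {
  stopifnot(inherits(p, "pose"))
  if (!is.null(frame) && !identical(frame, p$frame))
    ns_stop("neckstick_frame_mismatch",
            "vector is labeled for frame '%s' but pose is expressed in frame '%s'",
            frame, p$frame)
  as.numeric(p$rotation %*% as.numeric(v) - p$origin)
}

#' Transform a direction between frames
#'
#' Directions carry no position, so the origin is omitted: the result is
#' `R %*% v`. Norm is preserved exactly (rotation isometry).
#'
#' @inheritParams transform_point
#' @return numeric 3-vector in the parent frame.
#' @export
transform_direction <- function(v, p) {
  stopifnot(inherits(p, "pose"))
  as.numeric(p$rotation %*% as.numeric(v))
}

#' Invert a pose
#'
#' Returns the pose of the parent frame expressed in the child frame, such
#' that transforming a point forward and then back is the identity.
#'
#' @param p a [pose()].
#' @param frame label for the new parent (the old child) frame.
#' @return a [pose()].
#' @export
invert_pose <- function(p, frame = paste0("inv_", p$frame)) {
  pose(origin = as.numeric(-crossprod(p$rotation, p$origin)),
       rotation = t(p$rotation), frame = frame)
}

#' Reference marker geometry of a tracking tripod
#'
#' Marker coordinates of a rigid tracking body expressed in its own body
#' frame. The default is an equilateral triangle of 5 cm side centered at
#' the body origin, lying in the body x-y plane.
#'
#' @param side triangle side length, meters.
#' @return a 3x3 matrix, one marker per row.
#' @export
tripod_geometry <- function(side = 0.05) {
  r <- side / sqrt(3)  # circumradius
  g <- rbind(c(0, r, 0),
             c(-side / 2, -r / 2, 0),
             c(side / 2, -r / 2, 0))
  g - matrix(colMeans(g), 3, 3, byrow = TRUE)
}

triangle_area <- function(pts) {
  a <- pts[2, ] - pts[1, ]; b <- pts[3, ] - pts[1, ]
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  0.5 * sqrt(sum(cr^2))
}

assert_noncollinear <- function(pts, what = "marker triplet", tol = 1e-8) {
  if (triangle_area(pts) <= tol)
    ns_stop("neckstick_degenerate_geometry",
            "%s is (near-)collinear: triangle area %.3g m^2 <= %.0e m^2",
            what, triangle_area(pts), tol)
  invisible(pts)
}

#' Rigid-body pose from an observed marker triplet
#'
#' Solves the orthogonal Procrustes problem (Kabsch): finds the rotation `R`
#' and translation `t` minimizing the sum of squared distances between
#' `R %*% g_i + t` and the observed markers, where `g_i` are the reference
#' geometry rows. The returned pose maps body-frame points into the
#' observation frame; its RMS fit residual is attached as attribute
#' `"rms"` (meters).
#'
#' @param markers 3x3 matrix of observed marker positions (rows), meters.
#' @param reference 3x3 matrix of body-frame marker coordinates (rows);
#'   default [tripod_geometry()].
#' @param frame parent frame label of the observations.
#' @return a [pose()] with attribute `rms`.
#' @export
pose_from_markers <- function(markers, reference = tripod_geometry(),
                              frame = "l") {
  markers <- as.matrix(markers); reference <- as.matrix(reference)
  stopifnot(all(dim(markers) == c(3L, 3L)), all(dim(reference) == c(3L, 3L)))
  assert_noncollinear(markers, "observed markers")
  assert_noncollinear(reference, "reference geometry")
  fit <- kabsch(reference, markers)
  out <- pose_at(position = fit$t, rotation = fit$R, frame = frame)
  attr(out, "rms") <- fit$rms
  out
}

# Kabsch core: R, t minimizing ||R g + t - p||^2 over rows. Kept lean; it is
# called once per body per sample when lifting marker tables to poses.
kabsch <- function(G, P) {
  gc_ <- colMeans(G); pc_ <- colMeans(P)
  Gc <- G - matrix(gc_, 3, 3, byrow = TRUE)
  Pc <- P - matrix(pc_, 3, 3, byrow = TRUE)
  H <- crossprod(Gc, Pc)                 # sum g_c p_c^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- pc_ - as.numeric(R %*% gc_)
  E <- P - (G %*% t(R) + matrix(t_, 3, 3, byrow = TRUE))
  list(R = R, t = t_, rms = sqrt(mean(rowSums(E^2))))
}
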
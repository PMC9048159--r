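#' Six-degrees-of-freedom rigid transform
#'
#' Three translations (mm) along the patient axes and three rotations
#' (degrees). Axis naming and rotation convention used throughout the
#' package (the field does not share a single convention, so reports always
#' state this one):
#'
#' * RL = world x, AP = world y, SI = world z (LPS frame);
#' * pitch = rotation about RL, yaw = rotation about AP, roll = rotation
#'   about SI;
#' * rotations compose extrinsically in the order pitch, then roll, then
#'   yaw: `R = Ry(yaw) %*% Rz(roll) %*% Rx(pitch)`;
#' * a transform maps a point as `R %*% p + t`.
#'
#' @param t_rl,t_ap,t_si translations (mm) along RL, AP, SI.
#' @param pitch,roll,yaw rotations (degrees) in (-180, 180].
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(t_rl = 0, t_ap = 0, t_si = 0,
                            pitch = 0, roll = 0, yaw = 0) {
  ang <- c(pitch = pitch, roll = roll, yaw = yaw)
  if (any(!is.finite(c(t_rl, t_ap, t_si, ang))))
    abort_qa("rigid_transform parameters must be finite")
  if (any(ang <= -180 | ang > 180))
    abort_qa("angles must lie in (-180, 180] degrees")
  structure(list(t = c(t_rl, t_ap, t_si),
                 angles = ang),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(paste0("<rigid_transform> t(RL,AP,SI) = (%.4g, %.4g, %.4g) mm; ",
                     "pitch/roll/yaw = (%.4g, %.4g, %.4g) deg\n"),
              x$t[1], x$t[2], x$t[3],
              x$angles[1], x$angles[2], x$angles[3]))
  invisible(x)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Rotation matrix of a rigid transform
#' @param tf a [rigid_transform()].
#' @return 3x3 rotation matrix (determinant +1).
#' @export
rotation_matrix <- function(tf) {
  a <- deg2rad(tf$angles)
  rot_y(a[["yaw"]]) %*% rot_z(a[["roll"]]) %*% rot_x(a[["pitch"]])
}

#' Recover pitch/roll/yaw angles (degrees) from a rotation matrix
#'
#' Inverts the package convention `R = Ry(yaw) Rz(roll) Rx(pitch)`. Valid for
#' roll in (-90, 90) degrees, which covers every QA use case.
#'
#' @param R 3x3 rotation matrix.
#' @return named numeric vector `pitch`, `roll`, `yaw` in degrees.
#' @export
euler_angles <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  roll <- asin(max(-1, min(1, R[2, 1])))
  pitch <- atan2(-R[2, 3], R[2, 2])
  yaw <- atan2(-R[3, 1], R[1, 1])
  rad2deg(c(pitch = pitch, roll = roll, yaw = yaw))
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param points length-3 vector or n x 3 matrix of world points (mm).
#' @return transformed points, same shape.
#' @export
apply_rigid <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  one <- is.null(dim(points))
  p <- if (one) matrix(as.numeric(points), 1, 3) else as.matrix(points)
  out <- p %*% t(rotation_matrix(tf))
  out <- sweep(out, 2, tf$t, `+`)
  if (one) drop(out) else out
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(tf) {
  R <- rotation_matrix(tf)
  rigid_from_matrix(t(R), -t(R) %*% tf$t)
}

# build a rigid_transform from rotation matrix + translation vector
rigid_from_matrix <- function(R, t) {
  ang <- euler_angles(R)
  rigid_transform(t[1], t[2], t[3], ang[["pitch"]], ang[["roll"]], ang[["yaw"]])
}
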
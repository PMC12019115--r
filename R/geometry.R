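#' Task layout constants
#'
#' Geometry of the reaching workspace: a start-point at the centre of a
#' circular target plane, four cardinal targets on a ring, and a cursor with a
#' homing snap radius. All lengths are in arbitrary workspace units (au); the
#' screen height spans 4 au.
#'
#' @param start_point_diameter,target_diameter,target_ring_diameter,
#'   target_plane_diameter,cursor_diameter,snap_radius Diameters / radius in au.
#' @param target_angles Target directions in degrees, counter-clockwise from
#'   the +x axis (0/90/180/270 = right/up/left/down).
#' @return A list of class `vm_layout`.
#' @export
task_layout <- function(start_point_diameter = 0.1,
                        target_diameter = 0.2,
                        target_ring_diameter = 2,
                        target_plane_diameter = 3,
                        cursor_diameter = 0.15,
                        snap_radius = 0.05,
                        target_angles = c(0, 90, 180, 270)) {
  stopifnot(
    start_point_diameter > 0, target_diameter > 0, target_ring_diameter > 0,
    target_plane_diameter > 0, cursor_diameter > 0, snap_radius > 0,
    setequal(target_angles, c(0, 90, 180, 270))
  )
  structure(
    list(
      start_point_diameter = start_point_diameter,
      target_diameter = target_diameter,
      target_ring_diameter = target_ring_diameter,
      target_plane_diameter = target_plane_diameter,
      cursor_diameter = cursor_diameter,
      snap_radius = snap_radius,
      target_angles = sort(target_angles)
    ),
    class = "vm_layout"
  )
}

#' Visual-context configuration
#'
#' Describes how raw input displacements drive the display. In the `point`
#' context the camera is static and input translates the cursor. In the `look`
#' context the cursor is fixed at screen centre and input pans/tilts a camera
#' viewing the task plane at depth `camera_distance`. `inverted_look` is `look`
#' with input gains negated on the configured axes.
#'
#' @param context One of `"point"`, `"look"`, `"inverted_look"`.
#' @param camera_distance Perspective depth of the task plane in au. The
#'   default keeps camera angles small (< 8 degrees) over the 2 au target ring
#'   so the pan/tilt mapping stays far from its 90-degree singularity.
#' @param inverted_axes `"both"` (default) or `"vertical_only"`; ignored unless
#'   `context == "inverted_look"`.
#' @return A list of class `vm_context`.
#' @export
context_config <- function(context = c("point", "look", "inverted_look"),
                           camera_distance = 8,
                           inverted_axes = c("both", "vertical_only")) {
  context <- match.arg(context)
  inverted_axes <- match.arg(inverted_axes)
  stopifnot(is.numeric(camera_distance), camera_distance > 0)
  structure(
    list(context = context, camera_distance = camera_distance,
         inverted_axes = inverted_axes),
    class = "vm_context"
  )
}

#' Visuomotor rotation descriptor
#'
#' @param magnitude Rotation magnitude in degrees (0 or 30 in the designs
#'   supported here; any non-negative value is accepted).
#' @param direction `"cw"`, `"ccw"`, or `"none"`. `magnitude == 0` iff
#'   `direction == "none"`.
#' @return A list of class `vm_rotation`.
#' @export
rotation_spec <- function(magnitude = 0, direction = c("none", "cw", "ccw")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(magnitude), magnitude >= 0)
  if ((magnitude == 0) != (direction == "none")) {
    stop("magnitude must be 0 iff direction is 'none'")
  }
  structure(list(magnitude = magnitude, direction = direction),
            class = "vm_rotation")
}

#' Signed rotation in degrees (counter-clockwise positive)
#'
#' @param rot A `vm_rotation`.
#' @return Signed degrees: +magnitude for ccw, -magnitude for cw, 0 for none.
#' @export
rotation_signed <- function(rot) {
  switch(rot$direction, none = 0, ccw = rot$magnitude, cw = -rot$magnitude)
}

#' Wrap angles into (-180, 180]
#'
#' @param a Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Apply a visuomotor rotation to displacement vectors
#'
#' Rotates 2-D displacement(s) about the origin by the configured magnitude in
#' the configured direction (ccw positive). Norm-preserving; a zero-magnitude
#' rotation returns the input unchanged.
#'
#' @param delta A length-2 numeric vector, or an n x 2 matrix of displacements.
#' @param rot A `vm_rotation` (or a signed angle in degrees).
#' @return Same shape as `delta`.
#' @export
apply_rotation <- function(delta, rot) {
  ang <- if (inherits(rot, "vm_rotation")) rotation_signed(rot) else rot
  if (ang == 0) return(delta)
  th <- ang * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (is.matrix(delta)) delta %*% t(R) else as.numeric(R %*% delta)
}

#' Snap the cursor to the start-point during homing
#'
#' If the cursor is strictly within `snap_radius` of the start-point it snaps
#' to the start-point; at or beyond the radius it is unchanged.
#'
#' @param cursor Length-2 cursor position (au).
#' @param layout A `vm_layout`.
#' @param start Start-point position (default origin).
#' @return Length-2 position.
#' @export
snap_to_start <- function(cursor, layout = task_layout(), start = c(0, 0)) {
  if (sqrt(sum((cursor - start)^2)) < layout$snap_radius) start else cursor
}

# Camera pose (yaw/pitch, degrees) that places the task-plane centre at screen
# offset `s` under a pinhole view of a plane at depth d: the plane centre
# projects at (-d tan yaw, -d tan pitch). Exact inverse of the Point cursor
# path by construction.
pose_for_offset <- function(s, camera_distance) {
  yaw <- -atan2(s[, 1], camera_distance) * 180 / pi
  pitch <- -atan2(s[, 2], camera_distance) * 180 / pi
  cbind(yaw = yaw, pitch = pitch)
}

#' Map an input path through a visual context
#'
#' Accumulates raw input displacements and produces, per sample, the on-screen
#' cursor position, the on-screen offset of the task plane (scene), and the
#' task-plane-relative cursor position. The three contexts are equated: the
#' cursor-minus-target screen vector is identical across contexts for the same
#' input stream, so `cursor_plane` (cursor relative to the task plane) is the
#' common analysis channel.
#'
#' \itemize{
#'   \item point: the scene is static (`scene_offset = 0`) and the cursor
#'     accumulates rotated input deltas.
#'   \item look: the cursor stays at screen centre; the perturbation is applied
#'     to the camera update and the scene moves opposite to the Point cursor.
#'     The camera pose is solved exactly so that every task-plane point keeps
#'     its Point-context position relative to the cursor at every sample.
#'   \item inverted_look: as look with input deltas negated on the configured
#'     axes before the camera update.
#' }
#'
#' @param deltas n x 2 matrix of per-frame raw input displacements (au).
#' @param cfg A `vm_context`.
#' @param rot A `vm_rotation`.
#' @return A list with n x 2 matrices `cursor_screen`, `scene_offset`,
#'   `cursor_plane`, `input` (cumulative raw input), and an n x 2 `pose`
#'   (yaw/pitch, degrees; all zero for point).
#' @export
forward_map <- function(deltas, cfg = context_config("point"),
                        rot = rotation_spec()) {
  deltas <- rbind(deltas)
  stopifnot(ncol(deltas) == 2, all(is.finite(deltas)))
  input <- apply(deltas, 2, cumsum)
  if (nrow(deltas) == 1) input <- rbind(c(input))
  eff <- deltas
  if (cfg$context == "inverted_look") {
    if (cfg$inverted_axes == "both") eff <- -eff else eff[, 2] <- -eff[, 2]
  }
  plane <- apply_rotation(apply(eff, 2, cumsum), rot)
  if (nrow(deltas) == 1) plane <- rbind(c(plane))
  if (cfg$context == "point") {
    cursor_screen <- plane
    scene_offset <- matrix(0, nrow(plane), 2)
    pose <- matrix(0, nrow(plane), 2, dimnames = list(NULL, c("yaw", "pitch")))
  } else {
    cursor_screen <- matrix(0, nrow(plane), 2)
    scene_offset <- -plane
    pose <- pose_for_offset(scene_offset, cfg$camera_distance)
    # the gnomonic mapping is singular at 90 degrees; refuse the
    # ill-conditioned near-singular regime as unreachable
    if (any(abs(pose) >= 85)) {
      stop("geometry-overflow: camera pose approached the 90 degree singularity")
    }
  }
  list(cursor_screen = cursor_screen, scene_offset = scene_offset,
       cursor_plane = plane, input = input, pose = pose)
}

#' Recover the input path that realizes a desired cursor path
#'
#' Inverse of [forward_map()] on the task-plane cursor channel: given the
#' desired cursor position relative to the task plane at each sample (starting
#' from the start-point), returns the raw per-frame input displacements that
#' produce it under the given context and rotation.
#'
#' @param plane_path n x 2 matrix of desired task-plane cursor positions.
#' @param cfg A `vm_context`.
#' @param rot A `vm_rotation`.
#' @return n x 2 matrix of raw input displacements (deltas).
#' @export
invert_map <- function(plane_path, cfg = context_config("point"),
                       rot = rotation_spec()) {
  plane_path <- rbind(plane_path)
  stopifnot(ncol(plane_path) == 2, all(is.finite(plane_path)))
  d <- apply(rbind(plane_path[1, ], diff(plane_path)), 2, identity)
  if (nrow(plane_path) == 1) d <- rbind(plane_path[1, ])
  ang <- if (inherits(rot, "vm_rotation")) rotation_signed(rot) else rot
  eff <- apply_rotation(d, -ang)
  if (!is.matrix(eff)) eff <- rbind(eff)
  if (cfg$context == "inverted_look") {
    if (cfg$inverted_axes == "both") eff <- -eff else eff[, 2] <- -eff[, 2]
  }
  eff
}
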
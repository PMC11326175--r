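# Retinal geometry: bearings, per-eye vertical occupancy, occlusion
# correction on a 1-degree raster, and the looming input signal.
#
# Conventions (used throughout the package):
#   * positions in cm, headings in degrees, counter-clockwise, 0 = +x axis;
#   * angles wrapped to (-180, 180];
#   * bearings are signed relative to heading: positive = left of heading;
#   * the visual field spans +/-165 deg (a 30 deg blind zone behind the fish);
#   * vertical occupancy of an object of half-extent H at distance d is
#     2 * atan(H / d), in degrees.

DEG <- 180 / pi

#' Wrap angles to (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the interval (-180, 180].
#' @examples
#' wrap_angle(c(370, -180, 180, 539))
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Signed bearing of a target point relative to a heading
#'
#' Bearing of `(tx, ty)` as seen from `(x, y)` with the observer heading
#' `heading` degrees (counter-clockwise from the +x axis). Positive bearings
#' are to the left of the heading; the result lies in (-180, 180]. Bearings
#' with magnitude above 165 degrees fall in the blind zone behind the fish.
#'
#' @param x,y observer position (cm). Vectorized.
#' @param heading observer heading (degrees CCW, 0 = +x axis).
#' @param tx,ty target position (cm).
#' @return signed bearing in degrees, positive to the left.
#' @examples
#' relative_bearing(0, 0, 0, 1, 0)   # dead ahead: 0
#' relative_bearing(0, 0, 0, 0, 1)   # left orthogonal: +90
#' relative_bearing(0, 0, 90, 1, 0)  # -90
#' @export
relative_bearing <- function(x, y, heading, tx, ty) {
  dx <- tx - x
  dy <- ty - y
  if (any(dx == 0 & dy == 0)) {
    stop("bearing undefined: target coincides with the focal position")
  }
  wrap_angle(atan2(dy, dx) * DEG - heading)
}

#' Vertical retinal occupancy of an object
#'
#' Angular extent `2 * atan(H / d)` (degrees) subtended by an object of
#' vertical half-extent `H` (fish half-height or dot radius, cm) at distance
#' `d` (cm). Strictly decreasing in distance.
#'
#' @param half_extent vertical half-extent of the object (cm), >= 0.
#' @param distance distance from the focal fish to the object center (cm), > 0.
#' @return occupancy in degrees.
#' @examples
#' vertical_occupancy(0.15, 0.42)   # ~39.3 deg
#' vertical_occupancy(0.075, 0.92)  # ~9.3 deg
#' @export
vertical_occupancy <- function(half_extent, distance) {
  if (any(distance <= 0)) stop("distance must be > 0")
  if (any(half_extent < 0)) stop("half_extent must be >= 0")
  2 * atan(half_extent / distance) * DEG
}

#' Construct a set of visual objects
#'
#' @param x,y object center positions (cm).
#' @param half_extent vertical half-extent (cm): fish half-height for agents,
#'   dot radius for projected dots.
#' @param id object identifiers (defaults to `seq_along(x)`).
#' @param kind `"agent"` or `"dot"`.
#' @return a `data.frame` of class `visual_objects`.
#' @export
visual_objects <- function(x, y, half_extent, id = seq_along(x),
                           kind = "dot") {
  if (any(half_extent <= 0)) stop("half_extent must be > 0")
  structure(
    data.frame(id = id, x = x, y = y, half_extent = half_extent,
               kind = kind, stringsAsFactors = FALSE),
    class = c("visual_objects", "data.frame")
  )
}

#' Per-eye retinal occupancy profile
#'
#' Computes the occupancy each visual object casts on the left and right eye
#' of a focal fish. In `per_object` mode each visible object contributes one
#' sample at its center bearing (occlusions ignored, as in the group
#' simulations). In `rasterized` mode the +/-165 deg field is discretized on
#' a 1 deg grid and each cell takes the occupancy of the *nearest* object
#' covering it, which corrects for neighbors occluding one another.
#'
#' Objects in the 30 deg blind zone behind the fish are excluded. Samples at
#' exactly 0 deg are assigned to the right eye (deterministic tie-break for a
#' measure-zero event); otherwise positive bearings go to the left eye.
#'
#' @param x,y,heading focal pose (cm, cm, degrees CCW).
#' @param objects a [visual_objects()] table.
#' @param mode `"per_object"` or `"rasterized"`.
#' @param half_field half-width of the visual field in degrees (165).
#' @return a `data.frame` of class `occupancy_profile` with columns `eye`
#'   (`"left"`/`"right"`), `bearing_deg`, `occupancy_deg`, `object_id`, and
#'   attribute `mode`. Empty scenes give zero rows.
#' @export
occupancy_profile <- function(x, y, heading, objects,
                              mode = c("per_object", "rasterized"),
                              half_field = 165) {
  mode <- match.arg(mode)
  empty <- structure(
    data.frame(eye = character(), bearing_deg = numeric(),
               occupancy_deg = numeric(), object_id = integer(),
               stringsAsFactors = FALSE),
    class = c("occupancy_profile", "data.frame"), mode = mode
  )
  if (is.null(objects) || nrow(objects) == 0) return(empty)
  d <- sqrt((objects$x - x)^2 + (objects$y - y)^2)
  if (any(d <= 0)) stop("all objects must be at distance > 0 from the focal")
  theta <- relative_bearing(x, y, heading, objects$x, objects$y)
  v <- vertical_occupancy(objects$half_extent, d)

  if (mode == "per_object") {
    keep <- abs(theta) <= half_field
    if (!any(keep)) return(empty)
    out <- data.frame(
      eye = ifelse(theta[keep] > 0, "left", "right"),
      bearing_deg = theta[keep],
      occupancy_deg = v[keep],
      object_id = objects$id[keep],
      stringsAsFactors = FALSE
    )
  } else {
    # horizontal angular half-width of a disc of radius H at distance d
    hw <- asin(pmin(objects$half_extent / d, 1)) * DEG
    centers <- seq(-half_field + 0.5, half_field - 0.5, by = 1)
    cell_v <- numeric(length(centers))
    cell_d <- rep(Inf, length(centers))
    cell_id <- rep(NA_integer_, length(centers))
    for (j in seq_len(nrow(objects))) {
      # covered iff angular distance from the object's center bearing < hw
      ang <- abs(wrap_angle(centers - theta[j]))
      cov <- ang <= hw[j]
      win <- cov & d[j] < cell_d
      cell_v[win] <- v[j]
      cell_d[win] <- d[j]
      cell_id[win] <- objects$id[j]
    }
    hit <- is.finite(cell_d)
    if (!any(hit)) return(empty)
    out <- data.frame(
      eye = ifelse(centers[hit] > 0, "left", "right"),
      bearing_deg = centers[hit],
      occupancy_deg = cell_v[hit],
      object_id = cell_id[hit],
      stringsAsFactors = FALSE
    )
  }
  structure(out, class = c("occupancy_profile", "data.frame"), mode = mode)
}

#' Split an occupancy profile by eye
#'
#' @param profile an [occupancy_profile()].
#' @return list with elements `left` and `right`.
#' @export
split_eyes <- function(profile) {
  list(left = profile[profile$eye == "left", , drop = FALSE],
       right = profile[profile$eye == "right", , drop = FALSE])
}

#' Looming input from two per-object occupancy profiles
#'
#' The input to the internal-state integrator at a time step: the maximal
#' increase in retinal occupancy of any single object between the previous
#' and the current profile, floored at zero. Objects present now but absent
#' before are treated as appearing with zero previous occupancy, so their
#' full occupancy counts as loom.
#'
#' For the *neighbor-induced* looming signal (the package default), the
#' previous profile must be computed with the focal pose frozen at the
#' current step, so that occupancy changes caused by the fish's own motion
#' contribute nothing; [looming_from_scene()] builds both profiles with the
#' correct convention.
#'
#' @param profile_now,profile_prev per-object [occupancy_profile()]s of the
#'   same focal agent at consecutive steps (both eyes concatenated).
#' @return list with `value` (degrees per step, >= 0) and `object_id` of the
#'   contributing object (NA when the scene is empty or nothing looms).
#' @export
looming_input <- function(profile_now, profile_prev) {
  if (nrow(profile_now) == 0) return(list(value = 0, object_id = NA_integer_))
  prev <- setNames(profile_prev$occupancy_deg, profile_prev$object_id)
  v_prev <- prev[as.character(profile_now$object_id)]
  v_prev[is.na(v_prev)] <- 0
  inc <- profile_now$occupancy_deg - v_prev
  i <- which.max(inc)
  value <- max(0, inc[i])
  if (value < 1e-9) value <- 0 # numerical dead-band
  list(value = value,
       object_id = if (value > 0) profile_now$object_id[i] else NA_integer_)
}

#' Looming input computed directly from scene history
#'
#' Convenience wrapper building the two per-object profiles entering
#' [looming_input()]. In `neighbor_induced` mode (default) the previous
#' scene is viewed from the *current* focal pose, so self-motion through a
#' static scene yields exactly zero loom; in `raw` mode the previous scene is
#' viewed from the previous pose, as actually experienced. In both modes an
#' object that was present but hidden in the blind zone emerges without
#' looming; only objects newly added to the scene count with their full
#' occupancy.
#'
#' @param pose_now,pose_prev numeric `c(x, y, heading)` at the current and
#'   previous step.
#' @param objects_now,objects_prev [visual_objects()] at the two steps
#'   (matched by `id`).
#' @param mode `"neighbor_induced"` or `"raw"`.
#' @inheritParams occupancy_profile
#' @return as [looming_input()].
#' @export
looming_from_scene <- function(pose_now, pose_prev, objects_now, objects_prev,
                               mode = c("neighbor_induced", "raw"),
                               half_field = 165) {
  mode <- match.arg(mode)
  now <- occupancy_profile(pose_now[1], pose_now[2], pose_now[3],
                           objects_now, "per_object", half_field)
  ref <- if (mode == "neighbor_induced") pose_now else pose_prev
  prev <- occupancy_profile(ref[1], ref[2], ref[3],
                            objects_prev, "per_object", half_field)
  # objects that were in the scene but invisible (blind zone) emerge
  # without looming: drop them from the current profile so only objects
  # newly added to the scene count with their full occupancy
  if (!is.null(objects_prev) && nrow(prev) < nrow(objects_prev)) {
    hidden <- setdiff(objects_prev$id, prev$object_id)
    now <- now[!(now$object_id %in% hidden), , drop = FALSE]
  }
  looming_input(now, prev)
}

#' Total occupancy per eye
#'
#' Sum of occupancy samples for each eye. For rasterized profiles each 1 deg
#' cell contributes once, so the horizontal coverage of either eye can never
#' exceed 165 cells.
#'
#' @param profile an [occupancy_profile()].
#' @return named numeric `c(left = , right = )` in degrees.
#' @export
total_occupancy <- function(profile) {
  c(left = sum(profile$occupancy_deg[profile$eye == "left"]),
    right = sum(profile$occupancy_deg[profile$eye == "right"]))
}
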
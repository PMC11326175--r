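# Occupancy-to-turn-direction policy and slope estimation.
#
# The probability to turn right given the occupancy profiles of the two eyes
# follows a weighted binocular comparison: per-object turning biases are
# weighted by relative occupancy w_i = v_i / sum(v) (the sum running over
# BOTH eyes) and summed with opposite signs for the two eyes around an
# intercept of 0.5. With a linear per-object bias a*v this collapses to
#   p(right) = 0.5 + a * [ sum_left v_i^2 / sum(v) - sum_right v_i^2 / sum(v) ]
# clamped to [0, 1].

#' Linear or tabulated occupancy-response curve
#'
#' The linear form has `p(turn away | v) = 0.5 + a * v`; the tabulated form
#' interpolates an empirical bias table `bias(v) = p(turn away | v) - 0.5`
#' (applied with a positive sign for left-eye objects and a negative sign
#' for right-eye objects). Tabulated biases must lie in `[-0.5, 0.5]`.
#'
#' @param slope probability-per-degree slope `a` of the linear response.
#' @param occupancy_deg,bias vectors defining a tabulated response; linearly
#'   interpolated (constant beyond the range).
#' @return an object of class `response_curve`.
#' @examples
#' response_curve(0.0104)
#' response_curve_tabulated(c(0, 20, 60), c(0, 0.2, 0.35))
#' @export
response_curve <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1, slope >= 0)
  structure(list(form = "linear", slope = slope), class = "response_curve")
}

#' @rdname response_curve
#' @export
response_curve_tabulated <- function(occupancy_deg, bias) {
  stopifnot(length(occupancy_deg) == length(bias), length(bias) >= 2)
  if (any(bias < -0.5 | bias > 0.5)) stop("biases must lie in [-0.5, 0.5]")
  f <- approxfun(occupancy_deg, bias, rule = 2)
  structure(list(form = "tabulated", bias_fun = f,
                 table = data.frame(occupancy_deg = occupancy_deg,
                                    bias = bias)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  if (x$form == "linear") {
    cat(sprintf("<response_curve> linear, slope a = %g per degree\n", x$slope))
  } else {
    cat(sprintf("<response_curve> tabulated, %d support points\n",
                nrow(x$table)))
  }
  invisible(x)
}

#' Probability to turn right given binocular occupancy profiles
#'
#' Evaluates the binocular comparison for a per-object occupancy profile
#' (both eyes in one table, as returned by [occupancy_profile()]). An empty
#' scene gives 0.5; mirror-symmetric scenes give exactly 0.5; the result is
#' clamped to `[0, 1]` after summation.
#'
#' @param profile a per-object [occupancy_profile()] (both eyes).
#' @param curve a [response_curve()].
#' @return probability to turn right (i.e. clockwise, away from the left eye).
#' @examples
#' obj <- visual_objects(0, 1, 0.075)  # one object 90 deg to the left
#' prof <- occupancy_profile(0, 0, 0, obj)
#' p_turn_right(prof, response_curve(0.0104))
#' @export
p_turn_right <- function(profile, curve) {
  stopifnot(inherits(curve, "response_curve"))
  v <- profile$occupancy_deg
  if (length(v) == 0 || sum(v) == 0) return(0.5)
  w <- v / sum(v)
  sgn <- ifelse(profile$eye == "left", 1, -1)
  if (curve$form == "linear") {
    p <- 0.5 + sum(sgn * w * curve$slope * v)
  } else {
    p <- 0.5 + sum(sgn * w * curve$bias_fun(v))
  }
  min(1, max(0, p))
}

#' Binocular occupancy drive
#'
#' The signed quantity multiplying the slope in the linear policy:
#' `sum_left v^2 / sum(v) - sum_right v^2 / sum(v)` (degrees). Positive when
#' the left eye is more occupied.
#'
#' @inheritParams p_turn_right
#' @return signed drive in degrees.
#' @export
occupancy_drive <- function(profile) {
  v <- profile$occupancy_deg
  if (length(v) == 0 || sum(v) == 0) return(0)
  sgn <- ifelse(profile$eye == "left", 1, -1)
  sum(sgn * v^2) / sum(v)
}

#' Estimate the response slope from binned turning events
#'
#' Reproduces the binned turning analysis: events closer than
#' `wall_exclude_bl` body lengths to the wall are discarded, the remaining
#' events are binned by the (unsigned) occupancy difference between the more
#' and the less occupied eye, the fraction of turns away from the more
#' occupied eye is computed per bin, and a weighted least-squares line
#' through the origin is fitted to `fraction - 0.5` versus bin-center
#' occupancy. Bins are weighted by their event counts (binomial-count
#' weighting), since occupancy differences are very unevenly populated.
#'
#' @param events data.frame with columns `delta_occupancy_deg` (>= 0),
#'   `turned_away` (logical) and `distance_to_wall_bl` (body lengths);
#'   [bout_events()] builds this table from a simulation bout log.
#' @param bin_width_deg bin width: 5 (low density) or 10 (high density).
#' @param wall_exclude_bl wall-proximity exclusion radius (1.25 body lengths).
#' @return list of class `response_fit`: `curve` (a linear
#'   [response_curve()]), `slope`, `se` (slope standard error), `table`
#'   (per-bin `bin_center_deg`, `n_events`, `p_turn_away`), `n_used`.
#' @export
estimate_slope <- function(events, bin_width_deg = 5, wall_exclude_bl = 1.25) {
  req <- c("delta_occupancy_deg", "turned_away", "distance_to_wall_bl")
  if (!all(req %in% names(events))) {
    stop("events must have columns: ", paste(req, collapse = ", "))
  }
  ev <- events[events$distance_to_wall_bl >= wall_exclude_bl, , drop = FALSE]
  if (nrow(ev) == 0) stop("no analyzable events")
  bin <- floor(ev$delta_occupancy_deg / bin_width_deg)
  tab <- do.call(rbind, lapply(split(ev, bin), function(b) {
    data.frame(
      bin_center_deg = (floor(b$delta_occupancy_deg[1] / bin_width_deg) + 0.5) *
        bin_width_deg,
      n_events = nrow(b),
      p_turn_away = mean(b$turned_away)
    )
  }))
  tab <- tab[order(tab$bin_center_deg), , drop = FALSE]
  rownames(tab) <- NULL
  # weighted LS through the origin: slope = sum(w x y) / sum(w x^2)
  xc <- tab$bin_center_deg
  yc <- tab$p_turn_away - 0.5
  w <- tab$n_events
  sxx <- sum(w * xc^2)
  slope <- sum(w * xc * yc) / sxx
  resid <- yc - slope * xc
  dof <- max(1, nrow(tab) - 1)
  se <- sqrt(sum(w * resid^2) / dof / sxx)
  structure(
    list(curve = response_curve(max(0, slope)), slope = slope, se = se,
         table = tab, n_used = nrow(ev)),
    class = "response_fit"
  )
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf(
    "<response_fit> slope a = %.5f +/- %.5f per degree (%d events, %d bins)\n",
    x$slope, x$se, x$n_used, nrow(x$table)))
  invisible(x)
}
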
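# shared fixture builders (all generated in code; no stored data)

# random visual scene in an annulus around the focal fish
random_scene <- function(n, d_range = c(0.5, 3), h_range = c(0.1, 0.8)) {
  d <- runif(n, d_range[1], d_range[2])
  ang <- runif(n, -pi, pi)
  visual_objects(x = d * cos(ang), y = d * sin(ang),
                 half_extent = runif(n, h_range[1], h_range[2]))
}

# straight-line trajectory table for one animal
line_traj <- function(id = 1, speed = 1, dt = 0.02, n = 100, x0 = 0, y0 = 0,
                      heading = 0) {
  t <- (seq_len(n) - 1) * dt
  data.frame(time_s = t, agent_id = id,
             x_cm = x0 + speed * t * cos(heading * pi / 180),
             y_cm = y0 + speed * t * sin(heading * pi / 180),
             heading_deg = heading, bouting = 0)
}

# stationary trajectory table for several animals at given positions
static_traj <- function(xy, dt = 0.02, n = 50) {
  do.call(rbind, lapply(seq_len(nrow(xy)), function(i) {
    data.frame(time_s = (seq_len(n) - 1) * dt, agent_id = i,
               x_cm = xy[i, 1], y_cm = xy[i, 2], heading_deg = 0,
               bouting = 0)
  }))
}

# per-eye occupancy totals by brute-force ray casting at `res` degree
# resolution: each ray takes the vertical occupancy of the first disc it
# hits (geometric first-hit, independent of the raster implementation)
raycast_totals <- function(x, y, heading, objects, res = 0.01,
                           half_field = 165) {
  angles <- seq(-half_field + res / 2, half_field - res / 2, by = res)
  phi <- (heading + angles) * pi / 180
  ux <- cos(phi); uy <- sin(phi)
  cx <- objects$x - x; cy <- objects$y - y
  d <- sqrt(cx^2 + cy^2)
  v <- 2 * atan(objects$half_extent / d) * 180 / pi
  best_t <- rep(Inf, length(angles))
  hit_v <- numeric(length(angles))
  for (j in seq_len(nrow(objects))) {
    along <- ux * cx[j] + uy * cy[j]          # forward distance to center
    perp <- abs(ux * cy[j] - uy * cx[j])      # ray-to-center distance
    hit <- along > 0 & perp <= objects$half_extent[j]
    win <- hit & along < best_t
    best_t[win] <- along[win]
    hit_v[win] <- v[j]
  }
  left <- angles > 0
  c(left = sum(hit_v[left]) * res, right = sum(hit_v[!left]) * res)
}
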
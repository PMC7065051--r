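#' Generate a synthetic gridded flow field
#'
#' Produces depth-averaged 2-D velocity fields on a regular x/y/t grid, as a
#' stand-in for hydrodynamic model output. The velocity at each node is a
#' steady residual component plus a sinusoidal tidal component:
#' `u(x,y,t) = residual_u(x,y) + amp_u * cos(2*pi*t/period + phase_u)`
#' (and likewise `v`). The default period is the M2 tidal constituent
#' (12.42 h). The residual can be uniform, a user function of (x, y), or an
#' anticlockwise gyre mimicking the residual circulation of a semi-enclosed
#' shelf sea.
#'
#' Coordinates are kilometres in an equirectangular plane (1 degree =
#' 111.19 km); times are hours.
#'
#' @param x_range,y_range Domain extents in km, length-2 numeric.
#' @param resolution_km Grid spacing in km.
#' @param t_range Time extent in hours, length-2 numeric.
#' @param resolution_h Snapshot spacing in hours.
#' @param residual Either a length-2 numeric `(u, v)` m/s for a uniform
#'   residual, a function `f(x, y)` returning `list(u =, v =)`, or the string
#'   `"gyre"` for a solid-body anticlockwise rotation about the domain centre.
#' @param gyre_speed Edge speed of the gyre in m/s (used when
#'   `residual = "gyre"`).
#' @param tide_amplitude Length-2 `(u, v)` tidal amplitudes, m/s.
#' @param tide_period Tidal period in hours (> 0); default M2 = 12.42 h.
#' @param tide_phase Length-2 `(u, v)` phases, radians.
#' @param periodic If `TRUE` (default) the field may be evaluated at any time
#'   by wrapping `t` modulo the stored time extent; the tidal signal makes
#'   this exact when the extent is a whole number of periods.
#' @return A `flow_field`: list with `x`, `y` (km), `t` (hours), and velocity
#'   arrays `u`, `v` of dimension `length(x) x length(y) x length(t)` in m/s.
#' @export
make_flow_field <- function(x_range = c(0, 100), y_range = c(0, 100),
                            resolution_km = 10,
                            t_range = c(0, 24.84), resolution_h = 1.242,
                            residual = c(0, 0), gyre_speed = 0.1,
                            tide_amplitude = c(0, 0),
                            tide_period = 12.42,
                            tide_phase = c(0, 0),
                            periodic = TRUE) {
  if (tide_period <= 0) stop("tide_period must be > 0")
  if (resolution_km <= 0 || resolution_h <= 0)
    stop("resolutions must be positive")
  x <- seq(x_range[1], x_range[2], by = resolution_km)
  y <- seq(y_range[1], y_range[2], by = resolution_km)
  t <- seq(t_range[1], t_range[2], by = resolution_h)
  nx <- length(x); ny <- length(y); nt <- length(t)
  if (nx < 2 || ny < 2 || nt < 2)
    stop("grid must have at least 2 nodes per axis")

  if (identical(residual, "gyre")) {
    xc <- mean(x_range); yc <- mean(y_range)
    rmax <- max(diff(x_range), diff(y_range)) / 2
    omega <- gyre_speed / rmax  # m/s per km of radius
    res_fun <- function(px, py) {
      list(u = -omega * (py - yc), v = omega * (px - xc))
    }
  } else if (is.function(residual)) {
    res_fun <- residual
  } else {
    stopifnot(is.numeric(residual), length(residual) == 2)
    res_fun <- function(px, py) {
      list(u = rep(residual[1], length(px)), v = rep(residual[2], length(px)))
    }
  }

  gx <- rep(x, times = ny)
  gy <- rep(y, each = nx)
  res <- res_fun(gx, gy)
  ru <- matrix(res$u, nx, ny)
  rv <- matrix(res$v, nx, ny)
  u <- array(0, c(nx, ny, nt))
  v <- array(0, c(nx, ny, nt))
  for (k in seq_len(nt)) {
    ph <- 2 * pi * t[k] / tide_period
    u[, , k] <- ru + tide_amplitude[1] * cos(ph + tide_phase[1])
    v[, , k] <- rv + tide_amplitude[2] * cos(ph + tide_phase[2])
  }
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("flow field contains non-finite velocities")
  structure(list(x = x, y = y, t = t, u = u, v = v,
                 periodic = isTRUE(periodic),
                 tide_period = tide_period),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("flow_field:", length(x$x), "x", length(x$y), "nodes,",
      length(x$t), "snapshots",
      if (x$periodic) "(time-periodic)" else "", "\n")
  cat(sprintf("  x: [%g, %g] km; y: [%g, %g] km; t: [%g, %g] h\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$t), max(x$t)))
  cat(sprintf("  |u| max %.3f m/s, |v| max %.3f m/s\n",
              max(abs(x$u)), max(abs(x$v))))
  invisible(x)
}
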
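#' Particle tracking model configuration
#'
#' Defaults follow the study design for mussel larvae in the southern North
#' Sea: releases start on day-of-year 59 (1 March), each origin releases
#' 1,489 particles every 30 minutes for 14 days, and particles are tracked
#' with 30-minute steps for 70 days. Horizontal dispersion is a random walk
#' with coefficient `dispersion_m2s` (default 10 m^2/s, a typical shelf-sea
#' magnitude). A particle "arrives" at a destination at its first entry into
#' that site's capture radius; it is counted once per destination and keeps
#' moving.
#'
#' @param release_start_day Day-of-year of first release.
#' @param particles_per_release Particles per origin per release event.
#' @param release_interval_min Minutes between release events.
#' @param release_duration_days Length of the release window, days.
#' @param tracking_duration_days Total tracked time from first release, days.
#' @param time_step_min Integration time step, minutes; must divide the
#'   release interval.
#' @param dispersion_m2s Horizontal dispersion coefficient D, m^2/s.
#' @param capture_radius_km Arrival radius around each destination, km.
#' @param boundary `"reflect"` (default; conserves particles) or `"absorb"`.
#' @return A list of class `ptm_config`.
#' @export
ptm_config <- function(release_start_day = 59,
                       particles_per_release = 1489,
                       release_interval_min = 30,
                       release_duration_days = 14,
                       tracking_duration_days = 70,
                       time_step_min = 30,
                       dispersion_m2s = 10,
                       capture_radius_km = 2,
                       boundary = c("reflect", "absorb")) {
  boundary <- match.arg(boundary)
  stopifnot(particles_per_release >= 1, release_interval_min > 0,
            release_duration_days >= 0, tracking_duration_days > 0,
            time_step_min > 0, dispersion_m2s >= 0, capture_radius_km > 0)
  if (release_interval_min %% time_step_min != 0)
    stop("time_step_min must divide release_interval_min")
  structure(list(release_start_day = release_start_day,
                 particles_per_release = particles_per_release,
                 release_interval_min = release_interval_min,
                 release_duration_days = release_duration_days,
                 tracking_duration_days = tracking_duration_days,
                 time_step_min = time_step_min,
                 dispersion_m2s = dispersion_m2s,
                 capture_radius_km = capture_radius_km,
                 boundary = boundary),
            class = "ptm_config")
}

#' Number of release events and particles per origin under a schedule
#'
#' The schedule arithmetic: one release every `release_interval_min` minutes
#' over `release_duration_days` days, starting at time zero (the start
#' instant itself is a release).
#'
#' @param config A `ptm_config`.
#' @return List with `n_releases` and `particles_per_origin`.
#' @export
release_schedule <- function(config) {
  n <- floor(config$release_duration_days * 24 * 60 /
               config$release_interval_min)
  n <- n + ifelse(config$release_duration_days * 24 * 60 %%
                    config$release_interval_min == 0, 0, 1)
  if (config$release_duration_days == 0) n <- 1
  list(n_releases = n,
       particles_per_origin = n * config$particles_per_release)
}

#' Interpolate a flow field at arbitrary positions and time
#'
#' Bilinear in space, linear in time. Positions outside the grid hull are an
#' error (the particle stepper keeps particles inside via its boundary
#' policy; interpolation never extrapolates silently). For time-periodic
#' fields the query time is wrapped into the stored extent.
#'
#' @param flow A `flow_field`.
#' @param x,y Positions, km (vectors of equal length).
#' @param time Scalar time, hours.
#' @return List with numeric vectors `u` and `v` (m/s).
#' @export
interpolate_velocity <- function(flow, x, y, time) {
  tmin <- flow$t[1]; tmax <- flow$t[length(flow$t)]
  tq <- time
  if (isTRUE(flow$periodic)) {
    tq <- tmin + (time - tmin) %% (tmax - tmin)
  } else if (time < tmin || time > tmax) {
    stop("query time ", time, " outside flow snapshot range [",
         tmin, ", ", tmax, "]")
  }
  if (any(x < flow$x[1] | x > flow$x[length(flow$x)] |
            y < flow$y[1] | y > flow$y[length(flow$y)]))
    stop("query position outside flow grid hull")

  ix <- pmin(pmax(findInterval(x, flow$x), 1), length(flow$x) - 1)
  iy <- pmin(pmax(findInterval(y, flow$y), 1), length(flow$y) - 1)
  it <- pmin(pmax(findInterval(tq, flow$t), 1), length(flow$t) - 1)
  wx <- (x - flow$x[ix]) / (flow$x[ix + 1] - flow$x[ix])
  wy <- (y - flow$y[iy]) / (flow$y[iy + 1] - flow$y[iy])
  wt <- (tq - flow$t[it]) / (flow$t[it + 1] - flow$t[it])

  bilin <- function(a, k) {
    nx <- dim(a)[1]; nxy <- nx * dim(a)[2]
    base <- (k - 1) * nxy
    v00 <- a[base + (iy - 1) * nx + ix]
    v10 <- a[base + (iy - 1) * nx + ix + 1]
    v01 <- a[base + iy * nx + ix]
    v11 <- a[base + iy * nx + ix + 1]
    (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
      (1 - wx) * wy * v01 + wx * wy * v11
  }
  u <- (1 - wt) * bilin(flow$u, it) + wt * bilin(flow$u, it + 1)
  v <- (1 - wt) * bilin(flow$v, it) + wt * bilin(flow$v, it + 1)
  list(u = u, v = v)
}

# Reflect positions into [lo, hi] (repeated folding handles large overshoots)
reflect_into <- function(p, lo, hi) {
  w <- hi - lo
  q <- (p - lo) %% (2 * w)
  lo + ifelse(q > w, 2 * w - q, q)
}

#' Advance particles one time step (advection + random-walk dispersion)
#'
#' Each particle moves by `u*dt` plus an isotropic Gaussian random-walk
#' displacement with per-axis standard deviation `sqrt(2*D*dt)`, the
#' Lagrangian equivalent of Fickian horizontal diffusion with coefficient D.
#'
#' @param x,y Positions, km.
#' @param flow A `flow_field`.
#' @param time Scalar time, hours (evaluated at the start of the step).
#' @param dt_s Time step, seconds (> 0).
#' @param D Dispersion coefficient, m^2/s (>= 0).
#' @param boundary `"reflect"` or `"absorb"`.
#' @return List with `x`, `y` (km) and logical `alive` (only `"absorb"`
#'   kills particles that step outside the domain).
#' @export
advance_particles <- function(x, y, flow, time, dt_s, D,
                              boundary = c("reflect", "absorb")) {
  boundary <- match.arg(boundary)
  stopifnot(dt_s > 0, D >= 0)
  vel <- interpolate_velocity(flow, x, y, time)
  if (anyNA(vel$u) || anyNA(vel$v)) {
    bad <- which(is.na(vel$u) | is.na(vel$v))[1]
    stop("NaN velocity for particle ", bad, " at time ", time, " h")
  }
  sig_km <- sqrt(2 * D * dt_s) / 1000
  n <- length(x)
  nx <- x + vel$u * dt_s / 1000 + sig_km * stats::rnorm(n)
  ny <- y + vel$v * dt_s / 1000 + sig_km * stats::rnorm(n)
  xlo <- flow$x[1]; xhi <- flow$x[length(flow$x)]
  ylo <- flow$y[1]; yhi <- flow$y[length(flow$y)]
  alive <- rep(TRUE, n)
  if (boundary == "reflect") {
    nx <- reflect_into(nx, xlo, xhi)
    ny <- reflect_into(ny, ylo, yhi)
  } else {
    alive <- nx >= xlo & nx <= xhi & ny >= ylo & ny <= yhi
  }
  list(x = nx, y = ny, alive = alive)
}

#' Project site coordinates onto the model's km plane
#'
#' Equirectangular projection at 111.19 km per degree, applied to raw decimal
#' degrees on both axes (the same convention as the geographic distance
#' matrix, so model geometry and genetic geometry agree).
#'
#' @param sites A `site_table`.
#' @param origin Optional `(lon, lat)` to subtract first; default the
#'   centroid of the sites.
#' @return Data frame with `site_id`, `x_km`, `y_km`.
#' @export
sites_to_km <- function(sites, origin = NULL) {
  origin <- origin %||% c(mean(sites$lon), mean(sites$lat))
  data.frame(site_id = sites$site_id,
             x_km = (sites$lon - origin[1]) * 111.19,
             y_km = (sites$lat - origin[2]) * 111.19,
             stringsAsFactors = FALSE)
}

#' Run the particle tracking model
#'
#' Each (non-outgroup) site is an origin: particles are released on the
#' configured schedule from the site position, advected and dispersed over
#' the flow field, and counted at each destination at first entry into the
#' destination's capture radius. A particle can be counted at every
#' destination at most once and is never absorbed by an arrival; the diagonal
#' of the resulting matrix is local retention. There is no mortality:
#' released particle totals are conserved throughout (with reflecting
#' boundaries).
#'
#' Site coordinates may be supplied either as a `site_table` (lat/lon,
#' projected via [sites_to_km()]) or as a data frame with `site_id`, `x_km`,
#' `y_km` already on the flow field's plane.
#'
#' @param flow A `flow_field`.
#' @param sites A `site_table` or a data frame with `site_id`, `x_km`, `y_km`.
#' @param config A `ptm_config`.
#' @param seed Integer seed for the dispersion random walk.
#' @return An `arrival_matrix`: list with integer `counts` (source rows x
#'   destination columns), `released` per-source totals, and `config_hash`.
#' @export
run_ptm <- function(flow, sites, config = ptm_config(), seed = 1) {
  if (inherits(sites, "site_table")) {
    sites <- sites[!sites$is_outgroup, , drop = FALSE]
    xy <- sites_to_km(sites)
  } else {
    stopifnot(all(c("site_id", "x_km", "y_km") %in% names(sites)))
    xy <- sites
  }
  ns <- nrow(xy)
  xlo <- flow$x[1]; xhi <- flow$x[length(flow$x)]
  ylo <- flow$y[1]; yhi <- flow$y[length(flow$y)]
  out_dom <- xy$x_km < xlo | xy$x_km > xhi | xy$y_km < ylo | xy$y_km > yhi
  if (any(out_dom))
    stop("site(s) outside flow domain: ",
         paste(xy$site_id[out_dom], collapse = ", "))

  set.seed(seed)
  sch <- release_schedule(config)
  dt_h <- config$time_step_min / 60
  dt_s <- config$time_step_min * 60
  n_steps <- ceiling(config$tracking_duration_days * 24 / dt_h)
  steps_per_release <- config$release_interval_min / config$time_step_min
  t0 <- (config$release_start_day - 1) * 24  # hours since Jan 1, day 59 = 1 Mar

  counts <- matrix(0L, ns, ns, dimnames = list(xy$site_id, xy$site_id))
  released <- rep(0L, ns); names(released) <- xy$site_id

  # particle state, grown at each release event
  px <- numeric(0); py <- numeric(0)
  porig <- integer(0)
  arrived <- matrix(FALSE, 0, ns)
  r2 <- config$capture_radius_km^2

  for (step in seq_len(n_steps)) {
    tnow <- t0 + (step - 1) * dt_h
    rel_idx <- (step - 1) / steps_per_release
    if (rel_idx == floor(rel_idx) && rel_idx < sch$n_releases) {
      npr <- config$particles_per_release
      px <- c(px, rep(xy$x_km, each = npr))
      py <- c(py, rep(xy$y_km, each = npr))
      porig <- c(porig, rep(seq_len(ns), each = npr))
      released <- released + npr
      arrived <- rbind(arrived, matrix(FALSE, npr * ns, ns))
      # release-instant arrivals (local retention at t = 0, and any
      # destination within the capture radius of the origin)
      newi <- (length(px) - npr * ns + 1):length(px)
      for (d in seq_len(ns)) {
        hit <- (px[newi] - xy$x_km[d])^2 + (py[newi] - xy$y_km[d])^2 <= r2
        if (any(hit)) {
          arrived[newi[hit], d] <- TRUE
          counts[, d] <- counts[, d] +
            tabulate(porig[newi][hit], nbins = ns)
        }
      }
    }
    if (!length(px)) next
    st <- advance_particles(px, py, flow, tnow, dt_s,
                            config$dispersion_m2s, config$boundary)
    px <- st$x; py <- st$y
    if (config$boundary == "absorb" && !all(st$alive)) {
      keep <- st$alive
      px <- px[keep]; py <- py[keep]
      porig <- porig[keep]
      arrived <- arrived[keep, , drop = FALSE]
      if (!length(px)) next
    }
    for (d in seq_len(ns)) {
      hit <- !arrived[, d] &
        (px - xy$x_km[d])^2 + (py - xy$y_km[d])^2 <= r2
      if (any(hit)) {
        arrived[hit, d] <- TRUE
        counts[, d] <- counts[, d] + tabulate(porig[hit], nbins = ns)
      }
    }
  }

  structure(list(counts = counts, released = released,
                 config_hash = config_hash(config), n_particles = length(px)),
            class = "arrival_matrix")
}

#' @export
print.arrival_matrix <- function(x, ...) {
  ns <- nrow(x$counts)
  cat("arrival_matrix:", ns, "sites,", sum(x$released), "particles released\n")
  nz <- sum(x$counts == 0)
  cat("  zero cells:", nz, "of", ns * ns,
      "(diagonal = local retention)\n")
  invisible(x)
}

#' Normalise arrival counts to per-origin proportions
#'
#' @param arrivals An `arrival_matrix` (or a bare counts matrix plus
#'   `released`).
#' @param include_retention Keep the diagonal (default `TRUE`); otherwise the
#'   diagonal is zeroed before normalisation.
#' @return A row-stochastic-at-most matrix of arrival proportions
#'   `counts[s, d] / released[s]`, with attribute `zero_rows` naming origins
#'   that reached no destination at all.
#' @export
arrivals_to_proportions <- function(arrivals, include_retention = TRUE) {
  counts <- arrivals$counts
  released <- arrivals$released
  if (!include_retention) diag(counts) <- 0L
  stopifnot(all(released > 0))
  p <- sweep(counts + 0, 1, released, "/")
  zr <- rownames(p)[rowSums(p) == 0]
  attr(p, "zero_rows") <- zr
  p
}
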
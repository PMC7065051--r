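flow_uniform <- function(u = 0.1, v = 0, ext = 200)
  make_flow_field(c(-ext, ext), c(-ext, ext), ext / 4, residual = c(u, v))

test_that("velocity interpolation is exact at nodes and bilinear between", {
  f <- make_flow_field(c(0, 20), c(0, 20), 10, residual = c(0, 0))
  # overwrite one time slice with a known corner pattern
  f$u[, , 1] <- 0
  f$u[2, 2, 1] <- 4    # node (10, 10)
  expect_equal(interpolate_velocity(f, 10, 10, 0)$u, 4)
  expect_equal(interpolate_velocity(f, 0, 0, 0)$u, 0)
  # cell centre of (0,0)-(10,10) cell with corner values (0, 0, 0, 4)
  expect_equal(interpolate_velocity(f, 5, 5, 0)$u, 1.0)
})

test_that("time interpolation blends snapshots linearly", {
  f <- make_flow_field(c(0, 20), c(0, 20), 10, t_range = c(0, 2),
                       resolution_h = 1, residual = c(0, 0), periodic = FALSE)
  f$u[, , 1] <- 1; f$u[, , 2] <- 3; f$u[, , 3] <- 5
  expect_equal(interpolate_velocity(f, 10, 10, 0.5)$u, 2)
  expect_error(interpolate_velocity(f, 10, 10, 9), "outside flow snapshot")
})

test_that("pure advection moves every particle exactly u*dt", {
  f <- flow_uniform(0.1, 0)
  n <- 200
  set.seed(4)
  x0 <- runif(n, -50, 50); y0 <- runif(n, -50, 50)
  st <- advance_particles(x0, y0, f, time = 0, dt_s = 1800, D = 0)
  # 0.1 m/s * 1800 s = 180 m east, for every particle, wherever it starts
  expect_equal(st$x - x0, rep(0.18, n))
  expect_equal(st$y, y0)
})

test_that("random-walk displacement variance follows the diffusion law", {
  f <- flow_uniform(0, 0)
  set.seed(99)
  n <- 10000; D <- 10
  x <- rep(0, n); y <- rep(0, n)
  nsteps <- 50
  for (k in seq_len(nsteps)) {
    s <- advance_particles(x, y, f, 0, 1800, D)
    x <- s$x; y <- s$y
  }
  Tsec <- nsteps * 1800
  expect_lt(abs(var(x * 1000) / (2 * D * Tsec) - 1), 0.05)
  expect_lt(abs(var(y * 1000) / (2 * D * Tsec) - 1), 0.05)
})

test_that("reflecting boundaries keep particles inside, preserving overshoot", {
  f <- make_flow_field(c(0, 10), c(0, 10), 5, residual = c(10, 0))
  # 10 m/s * 1800 s = 18 km: from x=1 overshoots the 10 km wall by 9 -> 1
  st <- advance_particles(1, 5, f, 0, 1800, 0, boundary = "reflect")
  expect_equal(st$x, 1)
  st2 <- advance_particles(1, 5, f, 0, 1800, 0, boundary = "absorb")
  expect_false(st2$alive)
})

test_that("zero flow with no dispersion yields a purely diagonal matrix", {
  f <- flow_uniform(0, 0)
  sites <- data.frame(site_id = c("A", "B", "C"),
                      x_km = c(-40, 0, 40), y_km = 0)
  cfg <- ptm_config(particles_per_release = 30, release_duration_days = 0,
                    tracking_duration_days = 2, dispersion_m2s = 0)
  am <- run_ptm(f, sites, cfg, seed = 1)
  expect_equal(diag(am$counts), am$released, ignore_attr = TRUE)
  expect_equal(sum(am$counts) - sum(diag(am$counts)), 0)
})

test_that("a steady current carries all particles over a downstream site", {
  # 0.2 m/s = 17.28 km/day; A at x=-40 crosses B at x=0 within 3 days
  f <- flow_uniform(0.2, 0)
  sites <- data.frame(site_id = c("A", "B"), x_km = c(-40, 0), y_km = 0)
  cfg <- ptm_config(particles_per_release = 25, release_duration_days = 0,
                    tracking_duration_days = 4, dispersion_m2s = 0,
                    capture_radius_km = 2)
  am <- run_ptm(f, sites, cfg, seed = 1)
  expect_equal(am$counts["A", "B"], am$released["A"], ignore_attr = TRUE)
  expect_equal(am$counts["B", "A"], 0L, ignore_attr = TRUE)  # asymmetric
})

test_that("the default schedule reproduces the study release arithmetic", {
  sch <- release_schedule(ptm_config())
  expect_equal(sch$n_releases, 672)            # 14 d x 48 releases/d
  expect_equal(sch$particles_per_origin, 1489 * 672)
})

test_that("arrival counts are monotone in capture radius at fixed seed", {
  f <- flow_uniform(0.1, 0.02)
  sites <- data.frame(site_id = c("A", "B", "C"),
                      x_km = c(-40, 0, 30), y_km = c(0, 5, -5))
  base <- sapply(c(2, 6, 12), function(r) {
    cfg <- ptm_config(particles_per_release = 60, release_duration_days = 0,
                      tracking_duration_days = 5, dispersion_m2s = 20,
                      capture_radius_km = r)
    sum(run_ptm(f, sites, cfg, seed = 7)$counts)
  })
  expect_true(all(diff(base) >= 0))
})

test_that("particle conservation holds and sites outside the domain error", {
  f <- flow_uniform(0.1, 0)
  sites <- data.frame(site_id = c("A", "B"), x_km = c(-40, 500), y_km = 0)
  cfg <- ptm_config(particles_per_release = 10, release_duration_days = 0,
                    tracking_duration_days = 1)
  expect_error(run_ptm(f, sites, cfg), "outside flow domain: B")
  sites$x_km[2] <- 40
  am <- run_ptm(f, sites, cfg, seed = 1)
  expect_equal(am$n_particles, sum(am$released))
  expect_true(all(am$counts <= matrix(am$released, 2, 2)))
})

test_that("proportions are scale-invariant with flagged zero rows", {
  am <- structure(list(
    counts = matrix(c(5L, 0L, 0L, 0L), 2, 2,
                    dimnames = list(c("A", "B"), c("A", "B"))),
    released = c(A = 10L, B = 10L)), class = "arrival_matrix")
  p <- arrivals_to_proportions(am)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(attr(p, "zero_rows"), "B")
  am2 <- am; am2$counts <- am$counts * 10L; am2$released <- am$released * 10L
  expect_equal(arrivals_to_proportions(am2), p)
})
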
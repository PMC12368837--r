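test_that("Cunningham slip correction matches closed-form values", {
  expect_identical(cunningham_correction(0), 1)
  expect_equal(cunningham_correction(1), 1 + 1.257 + 0.4 * exp(-1.1),
               tolerance = 1e-12)
  expect_equal(cunningham_correction(100),
               1 + 100 * (1.257 + 0.4 * exp(-1.1 / 100)), tolerance = 1e-12)
  expect_equal(round(cunningham_correction(100), 2), 166.26)
  expect_error(cunningham_correction(-0.1), "non-negative")
})

test_that("relaxation time follows the slip-corrected Stokes formula", {
  # continuum state (zero mean free path) so Cc = 1
  st <- tibble::tibble(mean_free_path = 0, viscosity = 1.8e-5)
  p1 <- particles(diameter = 1e-6, density = 1000)
  expect_equal(relaxation_time(p1, st), 1000 * 1e-12 / (18 * 1.8e-5),
               tolerance = 1e-12)
  p0 <- particles(diameter = 0, density = 1000, mass = 1e-18)
  expect_identical(relaxation_time(p0, st), 0)
  p2 <- particles(diameter = 2e-6, density = 1000)
  expect_equal(relaxation_time(p2, st) / relaxation_time(p1, st), 4,
               tolerance = 1e-12)
})

test_that("drag relaxation matches the analytic exponential solution", {
  u <- 50
  field <- uniform_flow_field(velocity_z = u)
  p <- particles(diameter = 1e-6, density = 1000, z = 0.1)
  tau <- relaxation_time(p, field$uniform)
  res <- simulate_trajectory(p, field, rng_seed = 1, dt = tau / 200,
                             t_max = tau, brownian = FALSE)
  v_analytic <- u * (1 - exp(-1))
  expect_equal(res$fate, "timed_out")
  expect_lt(abs(res$state$vz - v_analytic) / v_analytic, 0.005)
})

test_that("velocity converges as the step is refined", {
  u <- 50
  field <- uniform_flow_field(velocity_z = u)
  p <- particles(diameter = 1e-6, density = 1000, z = 0.1)
  tau <- relaxation_time(p, field$uniform)
  v_at <- function(dt) simulate_trajectory(p, field, dt = dt, t_max = tau,
                                           brownian = FALSE)$state$vz
  v1 <- v_at(tau / 200)
  v2 <- v_at(tau / 400)
  expect_lt(abs(v2 - v1) / abs(v2), 0.001)
})

test_that("a particle in still gas stays put and times out", {
  field <- uniform_flow_field(velocity_z = 0)
  p <- particles(diameter = 1e-6, density = 1000, z = 0.1)
  res <- simulate_trajectory(p, field, dt = 1e-6, t_max = 1e-4,
                             brownian = FALSE)
  expect_equal(res$fate, "timed_out")
  expect_equal(res$state$z, 0.1)
  expect_equal(res$state$vz, 0)
})

test_that("an axial particle impacts a sphere at its near pole", {
  field <- uniform_flow_field(velocity_z = 100)
  surf <- collision_surface("sphere", z_s = 5e-3, radius = 1e-3)
  p <- particles(diameter = 1e-6, density = 1000, z = 0, vz = 100)
  res <- simulate_trajectory(p, field, surf, dt = 1e-7, t_max = 1e-3,
                             brownian = FALSE)
  expect_equal(res$fate, "impacted_surface")
  expect_equal(unname(res$impact_point["z"]), 5e-3, tolerance = 1e-9)
  expect_equal(unname(res$impact_point["x"]), 0)
  expect_gt(res$impact_speed, 99)
})

test_that("particles outside the domain are rejected", {
  field <- build_flow_field(default_source())
  p <- particles(diameter = 1e-6, density = 1000, z = 1)  # beyond z_max
  expect_error(simulate_trajectory(p, field), "outside the flow domain")
})

test_that("seeded Brownian runs are reproducible and decorrelated by index", {
  field <- uniform_flow_field(velocity_z = 10, pressure = 100)
  p <- particles(diameter = 2.2e-9, density = 900, z = 0.1)
  r1 <- simulate_trajectory(p, field, rng_seed = 7, dt = 1e-7, t_max = 2e-5)
  r2 <- simulate_trajectory(p, field, rng_seed = 7, dt = 1e-7, t_max = 2e-5)
  r3 <- simulate_trajectory(p, field, rng_seed = 8, dt = 1e-7, t_max = 2e-5)
  expect_identical(r1$state, r2$state)
  expect_false(isTRUE(all.equal(r1$state, r3$state)))
})

test_that("micron droplets punch through the Mach disk with retained speed", {
  src <- default_source()
  field <- build_flow_field(src)
  xm <- mach_disk_position(src)
  p <- particles(diameter = 1e-6, density = 1000, z = 0, vz = 1)
  speed_at <- function(zs) {
    surf <- collision_surface("plane", z_s = zs)
    simulate_trajectory(p, field, surf, dt = 1e-7, t_max = 3e-4,
                        brownian = FALSE)$impact_speed
  }
  planes <- c(0.6, 0.8, 1.0, 1.2) * xm
  speeds <- vapply(planes, speed_at, numeric(1))
  peak <- max(speeds)
  # droplet inertia: just behind the disk the droplet keeps >80% of its
  # peak speed while the post-shock gas has dropped below 50% of it
  expect_gt(speed_at(xm * 1.001), 0.8 * peak)
  post_gas <- centerline_state(xm * 1.05, src)$velocity_z
  expect_lt(post_gas, 0.5 * peak)
})
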
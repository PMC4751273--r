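test_that("stable_dt combines the Courant and diffusive bounds", {
  p <- default_parameters()
  # pure diffusion at 20 um: diffusive cap 0.9 * dx^2 / (4 D)
  g <- make_calibration_domain(2e-3, 2e-3, 20e-6)
  f <- region_fields(g, p, build_case("A1"))
  expect_equal(stable_dt(g, f, p), 0.9 * (20e-6)^2 / (4 * 8.7e-11),
    tolerance = 1e-12
  )
  # advection-dominated: no diffusion, drainage at u_b on a fine grid
  g2 <- make_calibration_domain(1e-4, 1e-4, 2.36e-6)
  p2 <- default_parameters(D_star = 0)
  f2 <- region_fields(g2, p2, build_case("C1"))
  expect_equal(stable_dt(g2, f2, p2), 0.5 * 2.36e-6 / 8.33e-6,
    tolerance = 1e-9
  )
  # doubling dx doubles the advective bound
  g3 <- make_calibration_domain(1e-4, 1e-4, 4.72e-6)
  f3 <- region_fields(g3, p2, build_case("C1"))
  expect_equal(stable_dt(g3, f3, p2), 2 * stable_dt(g2, f2, p2))
  # nothing constrains the step -> Inf (caller caps at the output cadence)
  p0 <- default_parameters(D_star = 0, u_white = 0, u_b = 0)
  f0 <- region_fields(g, p0, build_case("A1"))
  expect_identical(stable_dt(g, f0, p0), Inf)
  # the run never exceeds the configured Courant number
  gc <- coarse_coronal()
  fc <- region_fields(gc, p, build_case("C1"))
  vmax <- max(sqrt(fc$ubx^2 + fc$uby^2), sqrt(fc$ux^2 + fc$uy^2))
  expect_lte(stable_dt(gc, fc, p) * vmax / gc$dx, p$C_max + 1e-12)
})

test_that("pure exchange reproduces the two-box closed form to dt order", {
  g <- make_calibration_domain(1e-3, 1e-3, 1e-4)
  p <- default_parameters(D_star = 0, u_white = 0, u_b = 0)
  init <- field_state(matrix(p$c0, g$nx, g$ny))
  sim <- run_simulation("C1", g, p,
    cadence = 10, injection = FALSE,
    initial_state = init
  )
  TT <- p$t_total
  cf <- sim$final_state$c[1, 1]
  cbf <- sim$final_state$cb[1, 1]
  # forward Euler with dt = 10 s: relative error ~ k_b * dt / 2 ~ 1e-3
  expect_equal(cf, p$c0 * exp(-p$k_b * TT), tolerance = 2e-3)
  expect_equal(cbf, p$c0 * (1 - exp(-p$k_b * TT)), tolerance = 4e-3)
  # the exchange itself is exactly conservative
  expect_equal(cf + cbf, p$c0, tolerance = 1e-12)
  # uniform fields stay uniform
  expect_equal(max(sim$final_state$c) - min(sim$final_state$c), 0)
})

test_that("null dynamics leave the state unchanged and no source means zero fields", {
  g <- make_calibration_domain(1e-3, 1e-3, 1e-4)
  p <- default_parameters(
    D_star = 0, u_white = 0, u_b = 0, k_b = 0,
    t_inject = 0, t_total = 100
  )
  set.seed(42)
  init <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  sim <- run_simulation("C1", g, p,
    cadence = 50, injection = FALSE,
    initial_state = field_state(init)
  )
  expect_equal(sim$final_state$c, init, tolerance = 1e-15)
  expect_true(all(sim$final_state$cb == 0))

  # zero-duration injection: everything stays zero
  p2 <- default_parameters(t_inject = 0, t_total = 100)
  g2 <- make_calibration_domain(1e-3, 1e-3, 1e-4, source = "point")
  sim2 <- run_simulation("A1", g2, p2, cadence = 50)
  expect_true(all(sim2$final_state$c == 0))
  expect_true(all(distance_timeseries(sim2)$distance == 0))
})

test_that("a released pulse follows the 2D heat kernel on the calibration domain", {
  g <- make_calibration_domain(8e-3, 8e-3, 25e-6)
  p <- default_parameters(t_total = 1200)
  init <- matrix(0, g$nx, g$ny)
  ij <- locate_cell(g, c(4e-3, 4e-3))
  init[ij[1], ij[2]] <- 1
  M <- 1 * g$dx^2
  sim <- run_simulation("A1", g, p,
    cadence = 1200, injection = FALSE,
    initial_state = field_state(init)
  )
  cc <- cell_centers(g)
  r2 <- outer((cc$x - cc$x[ij[1]])^2, (cc$y - cc$y[ij[2]])^2, "+")
  exact <- M / (4 * pi * p$D_star * 1200) * exp(-r2 / (4 * p$D_star * 1200))
  l2 <- sqrt(sum((sim$final_state$c - exact)^2) / sum(exact^2))
  expect_lt(l2, 0.02)
})

test_that("a rotated anisotropic tensor reproduces the rotated Gaussian", {
  g <- make_calibration_domain(4e-3, 4e-3, 20e-6)
  p <- default_parameters(t_total = 600)
  dpar <- 2e-10
  dperp <- 5e-11
  th <- pi / 4
  f <- region_fields(g, p, build_case("A1"))
  f$Dxx[] <- dpar * cos(th)^2 + dperp * sin(th)^2
  f$Dyy[] <- dpar * sin(th)^2 + dperp * cos(th)^2
  f$Dxy[] <- (dpar - dperp) * cos(th) * sin(th)
  init <- matrix(0, g$nx, g$ny)
  ij <- locate_cell(g, c(2e-3, 2e-3))
  init[ij[1], ij[2]] <- 1
  sim <- run_simulation("A1", g, p,
    cadence = 600, injection = FALSE,
    initial_state = field_state(init), fields = f
  )
  cc <- cell_centers(g)
  X <- outer(cc$x - cc$x[ij[1]], rep(1, g$ny))
  Y <- outer(rep(1, g$nx), cc$y - cc$y[ij[2]])
  XI <- cos(th) * X + sin(th) * Y
  ETA <- -sin(th) * X + cos(th) * Y
  M <- g$dx^2
  exact <- M / (4 * pi * sqrt(dpar * dperp) * 600) *
    exp(-XI^2 / (4 * dpar * 600) - ETA^2 / (4 * dperp * 600))
  l2 <- sqrt(sum((sim$final_state$c - exact)^2) / sum(exact^2))
  expect_lt(l2, 0.02)
})

test_that("a narrow membrane pulse advects at u_b with an exact centroid", {
  g <- make_calibration_domain(10e-3, 0.5e-3, 50e-6)
  p <- default_parameters(D_star = 0, u_white = 0, k_b = 0, t_total = 600)
  ic <- locate_cell(g, c(2e-3, 2.5e-4))[1]
  cb0 <- matrix(0, g$nx, g$ny)
  cb0[ic, ] <- 1
  sim <- run_simulation("C1", g, p,
    cadence = 60, injection = FALSE,
    initial_state = field_state(matrix(0, g$nx, g$ny), cb0)
  )
  xc <- cell_centers(g)$x
  w <- rowSums(sim$final_state$cb)
  centroid <- sum(xc * w) / sum(w)
  expect_lt(abs(centroid - (xc[ic] + p$u_b * 600)), g$dx)
  # upwind advection keeps the field non-negative and conserves mass
  expect_gte(min(sim$final_state$cb), 0)
  m <- sim$mass$moles_membrane
  expect_lt(max(abs(m - m[1])) / m[1], 1e-12)
})

test_that("total moles are conserved without injection in no-flux mode", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 300)
  blob <- matrix(0, g$nx, g$ny)
  ij <- locate_cell(g, c(5.0e-3, 2.5e-3))
  blob[ij[1] + (-3:3), ij[2] + (-3:3)] <- p$c0
  blob[g$label == 0L | g$label == 3L] <- 0
  sim <- run_simulation("C1", g, p,
    cadence = 10, injection = FALSE,
    initial_state = field_state(blob), post_injection = "no_flux"
  )
  mtot <- sim$mass$moles_ecs + sim$mass$moles_membrane
  # <= 1e-10 relative drift per step, and ~30 steps per output interval
  expect_lt(max(abs(diff(mtot))) / mtot[1], 30 * 1e-10)
  expect_lt((max(mtot) - min(mtot)) / mtot[1], 1e-10 * p$t_total)
  expect_true(all(sim$mass$moles_lost == 0))
})

test_that("fields remain non-negative and bounded during injection runs", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 600)
  for (id in c("A1", "C1")) {
    sim <- run_simulation(id, g, p, cadence = 100)
    expect_gte(min(sim$final_state$c), -1e-12 * p$c0)
    expect_gte(min(sim$final_state$cb), -1e-12 * p$c0)
    expect_lte(max(sim$final_state$c), p$c0 * (1 + 1e-9))
  }
})

test_that("the injection schedule drives the inflow cells as configured", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 300)
  sim <- run_simulation("A1", g, p,
    cadence = 60,
    snapshot_times = c(60, 300)
  )
  s60 <- sim$snapshots[["t60"]]
  expect_true(all(abs(s60$c[g$inflow] - p$c0) < 1e-12))
  s300 <- sim$snapshots[["t300"]]
  expect_true(all(s300$c[g$inflow] == 0)) # dirichlet_zero after t_inject
  expect_true(all(s300$cb[g$inflow] == 0)) # membrane never prescribed / needle wall

  sim2 <- run_simulation("A1", g, p,
    cadence = 60,
    snapshot_times = 300, post_injection = "no_flux"
  )
  expect_gt(max(sim2$snapshots[["t300"]]$c[g$inflow]), 0)
})

test_that("membrane moles are non-decreasing in drainage cases", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 600)
  sim <- run_simulation("C1", g, p, cadence = 30)
  expect_true(all(diff(sim$mass$moles_membrane) >= -1e-15))
})

test_that("detection distance at fixed time is non-decreasing in the drainage speed", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 420)
  d <- vapply(c("A1", "C2", "C1"), function(id) {
    tail(distance_timeseries(run_simulation(id, g, p, cadence = 420))$distance, 1)
  }, numeric(1)) # drainage speeds 0, u_b/2, u_b
  expect_true(all(diff(d) >= 0))
  expect_gt(d[3], d[1]) # full drainage demonstrably outruns diffusion
})

test_that("identical inputs give identical simulations", {
  g <- coarse_coronal()
  p <- default_parameters(t_total = 300)
  s1 <- run_simulation("C1", g, p, cadence = 30)
  s2 <- run_simulation("C1", g, p, cadence = 30)
  expect_identical(s1$distance, s2$distance)
  expect_identical(s1$final_state$c, s2$final_state$c)
})

test_that("instability is detected and reported with a time stamp", {
  g <- make_calibration_domain(1e-3, 1e-3, 25e-6)
  p <- default_parameters()
  f <- region_fields(g, p, build_case("A1"))
  init <- matrix(0, g$nx, g$ny)
  init[20, 20] <- p$c0
  st <- field_state(init)
  expect_error(
    {
      for (i in 1:50) st <- step(st, g, f, p, dt = 500, injection = FALSE)
    },
    "diverged at t"
  )
})

test_that("single explicit steps match the documented update semantics", {
  # one uptake-only step: c loses k dt c, cb gains exactly that
  g <- make_calibration_domain(1e-3, 1e-3, 1e-4)
  p <- default_parameters(D_star = 0, u_white = 0, u_b = 0)
  f <- region_fields(g, p, build_case("C1"))
  st <- field_state(matrix(p$c0, g$nx, g$ny))
  st1 <- step(st, g, f, p, dt = 2, injection = FALSE)
  expect_equal(st1$t, 2)
  expect_equal(st1$c[1, 1], p$c0 * (1 - p$k_b * 2), tolerance = 1e-12)
  expect_equal(st1$cb[1, 1], p$c0 * p$k_b * 2, tolerance = 1e-12)
})
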
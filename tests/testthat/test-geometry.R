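test_that("coronal-like rasterization has the documented shape anchors", {
  g <- make_slice(slice_spec("coronal_like", dx = 20e-6))
  # 8.2 mm x 5.5 mm raster domain (padded right of the 8 mm brain box to
  # hold the 2.46 mm drainage arc)
  expect_equal(g$ny, 275)
  expect_equal(g$nx, round(g$width / 20e-6))
  expect_gte(g$width, 5.7e-3 + 2.46e-3)
  expect_equal(g$needle_tip, c(5.7e-3, 2.8e-3))
  expect_equal(g$drainage_direction, c(1, 0))

  # every cell has exactly one label and the partition covers the grid
  expect_true(all(g$label %in% 0:3))
  expect_equal(length(g$label), g$nx * g$ny)

  # needle: a connected 50 um (+/- 1 cell) column reaching the top boundary
  ncols <- which(apply(g$label == 3L, 1, any))
  expect_lte(diff(range(ncols)) + 1, 3)
  wid_m <- (diff(range(ncols)) + 1) * g$dx
  expect_lte(abs(wid_m - 50e-6), g$dx + 1e-12)
  expect_true(all(g$label[ncols, g$ny] == 3L))
  for (i in ncols) {
    rows <- which(g$label[i, ] == 3L)
    expect_equal(rows, seq(min(rows), g$ny)) # contiguous to the top
  }

  # inflow cells sit at the tip, adjacent to gray matter
  cc <- cell_centers(g)
  for (idx in g$inflow) {
    i <- (idx - 1) %% g$nx + 1
    j <- (idx - 1) %/% g$nx + 1
    d <- sqrt((cc$x[i] - 5.7e-3)^2 + (cc$y[j] - 2.8e-3)^2)
    expect_lte(d, g$dx * 0.75)
    expect_equal(g$label[i, j - 1], 1L)
  }
})

test_that("the brain interior extends 2.46 mm from the tip along +x and no further", {
  g <- make_slice(slice_spec("coronal_like", dx = 25e-6))
  cc <- cell_centers(g)
  tip <- g$needle_tip
  interior <- g$label == 1L | g$label == 2L
  X <- matrix(cc$x, g$nx, g$ny)
  Y <- matrix(cc$y, g$nx, g$ny, byrow = TRUE)
  right <- interior & X > tip[1]
  dmax <- max(sqrt((X[right] - tip[1])^2 + (Y[right] - tip[2])^2))
  expect_lte(dmax, 2.46e-3)
  expect_gte(dmax, 2.46e-3 - 2 * g$dx)
  # and in particular straight along +x at the tip row
  jrow <- locate_cell(g, tip)[2]
  reach <- max(X[interior[, jrow], jrow]) - tip[1]
  expect_lt(abs(reach - 2.46e-3), 2 * g$dx)
})

test_that("rasterization is resolution-convergent and degenerate specs work", {
  a50 <- make_slice(slice_spec("coronal_like", dx = 50e-6))
  a25 <- make_slice(slice_spec("coronal_like", dx = 25e-6))
  for (lbl in c(1L, 2L)) {
    area50 <- sum(a50$label == lbl) * (50e-6)^2
    area25 <- sum(a25$label == lbl) * (25e-6)^2
    expect_lt(abs(area50 - area25) / area25, 0.02)
  }

  # no white regions -> all interior gray
  g0 <- make_slice(slice_spec("coronal_like", dx = 50e-6, white_regions = list()))
  expect_false(any(g0$label == 2L))
  expect_gt(sum(g0$label == 1L), 0)

  # needle narrower than a cell and out-of-domain tips are errors
  expect_error(
    make_slice(slice_spec("coronal_like", dx = 200e-6)),
    "needle"
  )
  expect_error(
    make_slice(slice_spec("coronal_like", needle_tip = c(9e-3, 9e-3))),
    "outside"
  )
})

test_that("calibration domains are homogeneous and deterministic", {
  g <- make_calibration_domain(10e-3, 10e-3, 50e-6, source = "point")
  expect_equal(c(g$nx, g$ny), c(200, 200))
  expect_true(all(g$label == 1L))
  expect_length(g$inflow, 1)
  ij <- locate_cell(g, g$injection_point)
  expect_equal(g$inflow, ij[1] + (ij[2] - 1) * g$nx)

  g2 <- make_calibration_domain(1e-3, 1e-3, 0.5e-3)
  expect_equal(c(g2$nx, g2$ny), c(2, 2))
  expect_length(g2$inflow, 0)

  ga <- make_calibration_domain(3e-3, 2e-3, 0.1e-3, source = "point")
  gb <- make_calibration_domain(3e-3, 2e-3, 0.1e-3, source = "point")
  expect_identical(ga, gb)

  expect_error(make_calibration_domain(-1, 1, 0.1), "> 0")
})

test_that("region_fields assigns the documented transport coefficients", {
  p <- default_parameters()
  g <- coarse_coronal()
  f <- region_fields(g, p, build_case("A1"))
  gray <- g$label == 1L
  white <- g$label == 2L
  expect_true(all(f$Dxx[gray] == 8.7e-11))
  expect_true(all(f$Dyy[gray] == 8.7e-11))
  expect_true(all(f$Dxy[gray] == 0))
  expect_true(all(f$ux == 0) && all(f$uy == 0))
  expect_true(all(f$kup == 0) && all(f$ubx == 0))

  # white-matter tensor from D_free = D* lambda_gray^2 over the fiber lambdas
  expect_equal(unique(f$Dxx[white]), 8.7e-11 * 1.6^2 / 1.47^2, tolerance = 1e-12)
  expect_equal(unique(f$Dyy[white]), 8.7e-11 * 1.6^2 / 1.68^2, tolerance = 1e-12)
  expect_equal(unique(f$Dxx[white]), 1.03e-10, tolerance = 0.005)
  expect_equal(unique(f$Dyy[white]), 7.89e-11, tolerance = 0.005)

  # B2: bulk flow at 5x along the fiber axis (+x), white matter only
  fb <- region_fields(g, p, build_case("B2"))
  expect_equal(unique(fb$ux[white]), 5 * 1.75e-7)
  expect_true(all(fb$ux[!white] == 0))

  # C2: half drainage speed everywhere in the interior, full uptake
  fc <- region_fields(g, p, build_case("C2"))
  expect_equal(unique(fc$ubx[gray | white]), 0.5 * 8.33e-6)
  expect_true(all(fc$uby == 0))
  expect_equal(unique(fc$kup[gray | white]), 2.5e-4)
  expect_true(all(fc$kup[!(gray | white)] == 0))

  # rotated fiber axis fills the symmetric tensor
  sp <- slice_spec("coronal_like",
    dx = 50e-6,
    white_regions = list(list(
      type = "band", x0 = 1e-3, x1 = 7e-3, y0 = 4.4e-3, y1 = 4.8e-3,
      fiber = c(1, 1) / sqrt(2)
    ))
  )
  fr <- region_fields(make_slice(sp), p, build_case("A1"))
  wsel <- make_slice(sp)$label == 2L
  dpar <- 8.7e-11 * 1.6^2 / 1.47^2
  dperp <- 8.7e-11 * 1.6^2 / 1.68^2
  expect_equal(unique(fr$Dxx[wsel]), (dpar + dperp) / 2, tolerance = 1e-12)
  expect_equal(unique(fr$Dxy[wsel]), (dpar - dperp) / 2, tolerance = 1e-12)

  # unnormalized fiber axis is rejected at spec time
  expect_error(
    make_slice(slice_spec("coronal_like",
      dx = 50e-6,
      white_regions = list(list(
        type = "band", x0 = 1e-3, x1 = 7e-3, y0 = 4.4e-3, y1 = 4.8e-3,
        fiber = c(2, 0)
      ))
    )),
    "unit"
  )
})

test_that("sagittal-like defaults place the tip and drainage direction", {
  g <- make_slice(slice_spec("sagittal_like", dx = 50e-6))
  expect_equal(g$needle_tip, c(6.1e-3, 3.9e-3))
  expect_equal(g$drainage_direction, c(0, 1))
  expect_equal(round(g$width * 1e3, 1), 13.7)
  expect_equal(round(g$height * 1e3, 1), 5.5)
})
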
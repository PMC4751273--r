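#' Specification of a synthetic brain-slice geometry
#'
#' Describes a rasterized 2D stand-in for a homogenized mouse brain slice:
#' one gray-matter interior, zero or more white-matter regions with a fiber
#' axis, an injection-needle rectangle (50 um wide) entering from the top
#' (brain surface) down to the needle tip, and a constant perivascular
#' drainage direction.
#'
#' Defaults:
#' * `coronal_like`: brain 8.0 mm wide x 5.5 mm high, needle tip at
#'   (5.7, 2.8) mm, drainage along +x. Right of the needle tip the interior
#'   boundary is a circular arc of radius `boundary_reach` = 2.46 mm centred
#'   on the tip, so the drainage front meets the brain boundary at 2.46 mm
#'   from the injection site; the raster domain is padded to 8.2 mm to
#'   contain the arc.
#' * `sagittal_like`: brain 13.7 mm x 5.5 mm, needle tip at (6.1, 3.9) mm,
#'   drainage along +y (toward the upper brain surface).
#' * `calibration`: plain homogeneous rectangle (see
#'   [make_calibration_domain()]).
#'
#' White-matter regions are axis-aligned bands or ellipses, each with a unit
#' fiber-axis vector; the defaults place one corpus-callosum-like band above
#' (coronal) or below (sagittal) the injection site, far enough from it that
#' detectable tracer reaches it only in the elevated-diffusion cases.
#'
#' @param kind `"coronal_like"` or `"sagittal_like"`.
#' @param dx grid spacing in m (square cells); default 25 um.
#' @param needle_tip length-2 numeric, m; defaults per `kind`.
#' @param white_regions list of regions, each a list with `type` (`"band"`
#'   or `"ellipse"`), geometry fields (`x0`,`x1`,`y0`,`y1` for bands;
#'   `center`, `a`, `b`, `angle` for ellipses) and a unit `fiber` vector.
#'   `NULL` gives the per-kind default; `list()` gives none.
#' @param drainage_direction unit 2-vector for the membrane drainage
#'   velocity; defaults per `kind`.
#' @param boundary_reach distance in m from the needle tip to the brain
#'   boundary along the drainage direction (coronal default 2.46 mm;
#'   `NA` for no arc clipping, the sagittal default).
#' @return An object of class `slice_spec`.
#' @examples
#' sp <- slice_spec("coronal_like")
#' g <- make_slice(slice_spec("coronal_like", dx = 100e-6, needle_tip = NULL))
#' @export
slice_spec <- function(kind = c("coronal_like", "sagittal_like"),
                       dx = 25e-6,
                       needle_tip = NULL,
                       white_regions = NULL,
                       drainage_direction = NULL,
                       boundary_reach = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (kind == "coronal_like") {
    width <- 8.0e-3
    height <- 5.5e-3
    if (is.null(needle_tip)) needle_tip <- c(5.7e-3, 2.8e-3)
    if (is.null(drainage_direction)) drainage_direction <- c(1, 0)
    if (is.null(boundary_reach)) boundary_reach <- 2.46e-3
    if (is.null(white_regions)) {
      white_regions <- list(list(
        type = "band", x0 = 1.0e-3, x1 = 7.0e-3, y0 = 4.4e-3, y1 = 4.8e-3,
        fiber = c(1, 0)
      ))
    }
  } else {
    width <- 13.7e-3
    height <- 5.5e-3
    if (is.null(needle_tip)) needle_tip <- c(6.1e-3, 3.9e-3)
    if (is.null(drainage_direction)) drainage_direction <- c(0, 1)
    if (is.null(boundary_reach)) boundary_reach <- NA_real_
    if (is.null(white_regions)) {
      white_regions <- list(list(
        type = "band", x0 = 2.0e-3, x1 = 11.7e-3, y0 = 2.3e-3, y1 = 2.7e-3,
        fiber = c(1, 0)
      ))
    }
  }
  structure(
    list(
      kind = kind, width = width, height = height, dx = dx,
      needle_tip = needle_tip, needle_halfwidth = 25e-6,
      white_regions = white_regions,
      drainage_direction = drainage_direction / sqrt(sum(drainage_direction^2)),
      boundary_reach = boundary_reach,
      corner_radius = 1.0e-3
    ),
    class = "slice_spec"
  )
}

# region label codes used in the label matrix
.LBL <- c(exterior = 0L, gray = 1L, white = 2L, needle = 3L)

inside_roundrect <- function(x, y, x0, x1, y0, y1, r) {
  ddx <- pmax(pmax(x0 + r - x, x - (x1 - r)), 0)
  ddy <- pmax(pmax(y0 + r - y, y - (y1 - r)), 0)
  (x >= x0 & x <= x1 & y >= y0 & y <= y1) & (ddx^2 + ddy^2 <= r^2)
}

region_contains <- function(reg, x, y) {
  if (reg$type == "band") {
    x >= reg$x0 & x <= reg$x1 & y >= reg$y0 & y <= reg$y1
  } else if (reg$type == "ellipse") {
    ang <- if (is.null(reg$angle)) 0 else reg$angle
    xr <- cos(ang) * (x - reg$center[1]) + sin(ang) * (y - reg$center[2])
    yr <- -sin(ang) * (x - reg$center[1]) + cos(ang) * (y - reg$center[2])
    (xr / reg$a)^2 + (yr / reg$b)^2 <= 1
  } else {
    stop("unknown white-region type: ", reg$type, call. = FALSE)
  }
}

#' Rasterize a slice specification onto a uniform grid
#'
#' Builds the cell-labelled geometry used by the solver. Cells are square
#' with spacing `dx`; physical coordinates are in meters with the origin at
#' the lower-left domain corner and cell centers at `(i - 0.5, j - 0.5) * dx`.
#' The needle is rasterized as a 50 um wide column from the top boundary
#' down to the needle tip; the needle cells adjacent to the tip are the
#' inflow cells where the injected concentration is prescribed.
#'
#' @param spec a [slice_spec()].
#' @return An object of class `geometry_grid` with fields `dx`, `nx`, `ny`,
#'   `origin`, `width`, `height`, `label` (integer matrix, codes 0 exterior,
#'   1 gray, 2 white, 3 needle), `white_id` (integer matrix of white-region
#'   indices), `fibers` (list of unit vectors), `needle_tip`, `inflow`
#'   (linear cell indices), `injection_point`, `drainage_direction`, `kind`.
#' @export
make_slice <- function(spec) {
  stopifnot(inherits(spec, "slice_spec"))
  dx <- spec$dx
  tip <- spec$needle_tip
  pad <- if (is.finite(spec$boundary_reach)) {
    max(0, tip[1] + spec$boundary_reach + 2 * dx - spec$width)
  } else {
    0
  }
  dom_w <- spec$width + pad
  nx <- max(2L, as.integer(round(dom_w / dx)))
  ny <- max(2L, as.integer(round(spec$height / dx)))
  if (tip[1] <= 0 || tip[1] >= dom_w || tip[2] <= 0 || tip[2] >= spec$height) {
    stop("needle tip lies outside the domain", call. = FALSE)
  }
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  interior <- inside_roundrect(
    X, Y, 0, spec$width, 0, spec$height, spec$corner_radius
  )
  if (is.finite(spec$boundary_reach)) {
    # right of the tip the boundary is an arc of radius boundary_reach
    # centred on the tip (drainage front pins there at a fixed distance)
    right <- X > tip[1]
    within <- (X - tip[1])^2 + (Y - tip[2])^2 <= spec$boundary_reach^2
    interior <- (interior & !right) | (right & within)
  }

  label <- matrix(.LBL[["exterior"]], nx, ny)
  label[interior] <- .LBL[["gray"]]

  white_id <- matrix(0L, nx, ny)
  fibers <- list()
  for (w in seq_along(spec$white_regions)) {
    reg <- spec$white_regions[[w]]
    fib <- as.numeric(reg$fiber)
    if (length(fib) != 2 || abs(sqrt(sum(fib^2)) - 1) > 1e-6) {
      stop("white-region fiber axis must be a unit 2-vector", call. = FALSE)
    }
    inw <- interior & region_contains(reg, X, Y)
    label[inw] <- .LBL[["white"]]
    white_id[inw] <- w
    fibers[[w]] <- fib
  }

  if (dx > 2 * spec$needle_halfwidth + 1e-12) {
    stop("grid spacing too coarse: needle narrower than one cell", call. = FALSE)
  }
  needle_col <- abs(xc - tip[1]) <= spec$needle_halfwidth
  if (!any(needle_col)) {
    stop("grid spacing too coarse: needle narrower than one cell", call. = FALSE)
  }
  needle_row <- yc > tip[2]
  needle <- outer(needle_col, needle_row, "&")
  label[needle] <- .LBL[["needle"]]
  white_id[needle] <- 0L
  jtip <- which(needle_row)[1]
  inflow <- which(needle_col) + (jtip - 1L) * nx

  g <- structure(
    list(
      dx = dx, nx = nx, ny = ny, origin = c(0, 0),
      width = dom_w, height = spec$height,
      label = label, white_id = white_id, fibers = fibers,
      needle_tip = tip, inflow = inflow, injection_point = tip,
      drainage_direction = spec$drainage_direction,
      kind = spec$kind
    ),
    class = "geometry_grid"
  )
  validate_grid(g)
}

#' Homogeneous calibration domain
#'
#' A rectangle of uniform gray matter with no needle, used as an oracle
#' fixture: released pulses evolve as the free-space heat kernel until they
#' feel the no-flux boundaries.
#'
#' @param width,height domain extent in m, > 0.
#' @param dx grid spacing in m, > 0.
#' @param source `"none"`, or `"point"` to mark the central cell as an
#'   inflow (Dirichlet injection) cell.
#' @return A `geometry_grid`; `injection_point` is the source-cell center
#'   (or the domain center when `source = "none"`).
#' @examples
#' g <- make_calibration_domain(1e-3, 1e-3, 0.5e-3)
#' c(g$nx, g$ny)
#' @export
make_calibration_domain <- function(width, height, dx,
                                    source = c("none", "point")) {
  source <- match.arg(source)
  if (!is.numeric(width) || width <= 0 || !is.numeric(height) || height <= 0 ||
      !is.numeric(dx) || dx <= 0) {
    stop("width, height and dx must be > 0", call. = FALSE)
  }
  nx <- max(1L, as.integer(round(width / dx)))
  ny <- max(1L, as.integer(round(height / dx)))
  label <- matrix(.LBL[["gray"]], nx, ny)
  ic <- as.integer(ceiling(nx / 2))
  jc <- as.integer(ceiling(ny / 2))
  center <- c((ic - 0.5) * dx, (jc - 0.5) * dx)
  inflow <- if (source == "point") ic + (jc - 1L) * nx else integer(0)
  structure(
    list(
      dx = dx, nx = nx, ny = ny, origin = c(0, 0),
      width = nx * dx, height = ny * dx,
      label = label, white_id = matrix(0L, nx, ny), fibers = list(),
      needle_tip = NULL, inflow = inflow, injection_point = center,
      drainage_direction = c(1, 0),
      kind = "calibration"
    ),
    class = "geometry_grid"
  )
}

validate_grid <- function(g) {
  stopifnot(all(dim(g$label) == c(g$nx, g$ny)))
  if (length(g$inflow)) {
    # each inflow cell must touch at least one gray cell
    lbl <- g$label
    for (idx in g$inflow) {
      i <- ((idx - 1L) %% g$nx) + 1L
      j <- ((idx - 1L) %/% g$nx) + 1L
      nb <- c(
        if (i > 1) lbl[i - 1, j], if (i < g$nx) lbl[i + 1, j],
        if (j > 1) lbl[i, j - 1], if (j < g$ny) lbl[i, j + 1]
      )
      if (!any(nb == .LBL[["gray"]])) {
        stop("inflow cell not adjacent to gray matter; check needle placement",
          call. = FALSE
        )
      }
    }
  }
  g
}

#' @export
print.geometry_grid <- function(x, ...) {
  counts <- table(factor(x$label,
    levels = .LBL,
    labels = names(.LBL)
  ))
  cat(sprintf(
    "Geometry grid (%s): %d x %d cells, dx = %g um, %.2f x %.2f mm\n",
    x$kind, x$nx, x$ny, x$dx * 1e6, x$width * 1e3, x$height * 1e3
  ))
  cat("  cells:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$needle_tip)) {
    cat(sprintf(
      "  needle tip at (%.2f, %.2f) mm; %d inflow cell(s)\n",
      x$needle_tip[1] * 1e3, x$needle_tip[2] * 1e3, length(x$inflow)
    ))
  }
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid a `geometry_grid`.
#' @return list with vectors `x` (length nx) and `y` (length ny) in m.
#' @export
cell_centers <- function(grid) {
  list(
    x = (seq_len(grid$nx) - 0.5) * grid$dx + grid$origin[1],
    y = (seq_len(grid$ny) - 0.5) * grid$dx + grid$origin[2]
  )
}

#' Locate the cell containing a physical point
#' @param grid a `geometry_grid`.
#' @param point length-2 numeric, m.
#' @return integer vector `c(i, j)` of cell indices.
#' @export
locate_cell <- function(grid, point) {
  i <- min(grid$nx, max(1L, as.integer(floor((point[1] - grid$origin[1]) / grid$dx)) + 1L))
  j <- min(grid$ny, max(1L, as.integer(floor((point[2] - grid$origin[2]) / grid$dx)) + 1L))
  c(i, j)
}

#' Per-cell transport coefficient fields
#'
#' Maps a geometry, the physical parameters, and a simulation case to the
#' per-cell coefficient fields used by the solver:
#'
#' * gray cells: isotropic ECS diffusion `diffusion_multiplier * D_star`,
#'   zero ECS velocity;
#' * white cells: anisotropic tensor built from the free-medium coefficient
#'   `D_free = D_star * lambda_gray^2` divided by `lambda_par^2` /
#'   `lambda_perp^2`, rotated to the region's fiber axis, and ECS bulk-flow
#'   velocity `bulkflow_multiplier * u_white` along the fiber axis;
#' * all interior (gray + white) cells: take-up rate
#'   `uptake_multiplier * k_b` and membrane drainage velocity
#'   `drainage_multiplier * u_b` along the grid's drainage direction;
#' * needle and exterior cells: zeros.
#'
#' @param grid a `geometry_grid`.
#' @param params a [default_parameters()] object.
#' @param case a [build_case()] object.
#' @return An object of class `region_fields`: list of `nx x ny` matrices
#'   `Dxx`, `Dyy`, `Dxy` (m^2 s^-1), `ux`, `uy`, `ubx`, `uby` (m s^-1),
#'   `kup` (s^-1).
#' @export
region_fields <- function(grid, params, case) {
  stopifnot(
    inherits(grid, "geometry_grid"), inherits(params, "clearance_params"),
    inherits(case, "case_spec")
  )
  nx <- grid$nx
  ny <- grid$ny
  z <- matrix(0, nx, ny)
  f <- list(
    Dxx = z, Dyy = z, Dxy = z, ux = z, uy = z,
    ubx = z, uby = z, kup = z
  )
  gray <- grid$label == .LBL[["gray"]]
  white <- grid$label == .LBL[["white"]]
  interior <- gray | white

  Dg <- case$diffusion_multiplier * params$D_star
  f$Dxx[gray] <- Dg
  f$Dyy[gray] <- Dg

  if (any(white)) {
    D_free <- params$D_star * params$lambda_gray^2
    dpar <- case$diffusion_multiplier * D_free / params$lambda_white_par^2
    dperp <- case$diffusion_multiplier * D_free / params$lambda_white_perp^2
    for (w in seq_along(grid$fibers)) {
      a <- grid$fibers[[w]]
      if (abs(sqrt(sum(a^2)) - 1) > 1e-6) {
        stop("fiber axis of white region ", w, " is not a unit vector",
          call. = FALSE
        )
      }
      sel <- grid$white_id == w & white
      f$Dxx[sel] <- dpar * a[1]^2 + dperp * a[2]^2
      f$Dyy[sel] <- dpar * a[2]^2 + dperp * a[1]^2
      f$Dxy[sel] <- (dpar - dperp) * a[1] * a[2]
      spd <- case$bulkflow_multiplier * params$u_white
      f$ux[sel] <- spd * a[1]
      f$uy[sel] <- spd * a[2]
    }
  }

  f$kup[interior] <- case$uptake_multiplier * params$k_b
  ubs <- case$drainage_multiplier * params$u_b
  f$ubx[interior] <- ubs * grid$drainage_direction[1]
  f$uby[interior] <- ubs * grid$drainage_direction[2]

  structure(f, class = "region_fields", case_id = case$case_id)
}

#' Export a geometry grid as a long data frame
#'
#' One row per cell with physical center coordinates and the region label;
#' convenient for plotting or for writing a portable text representation.
#'
#' @param x a `geometry_grid`.
#' @param ... unused.
#' @return data.frame with columns `x`, `y` (m), `label` (factor), `white_id`.
#' @export
as.data.frame.geometry_grid <- function(x, ...) {
  cc <- cell_centers(x)
  data.frame(
    x = rep(cc$x, times = x$ny),
    y = rep(cc$y, each = x$nx),
    label = factor(as.vector(x$label),
      levels = .LBL,
      labels = names(.LBL)
    ),
    white_id = as.vector(x$white_id)
  )
}
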
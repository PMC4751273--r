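#' Two-compartment field state
#'
#' Bundles the ECS concentration field `c`, the basement-membrane field
#' `cb` (both `nx x ny` matrices in mol m^-3) and the simulation time.
#'
#' @param c,cb numeric matrices of identical dimensions.
#' @param t simulation time in s.
#' @return An object of class `field_state`.
#' @export
field_state <- function(c, cb = NULL, t = 0) {
  c <- as.matrix(c)
  if (is.null(cb)) cb <- matrix(0, nrow(c), ncol(c))
  cb <- as.matrix(cb)
  stopifnot(all(dim(c) == dim(cb)), is.numeric(t), length(t) == 1L)
  structure(list(c = c, cb = cb, t = t), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "Field state at t = %.1f s: max c = %.3g, max c_b = %.3g mol m^-3\n",
    x$t, max(x$c), max(x$cb)
  ))
  invisible(x)
}

# Solver-ready discretization: activity masks, diffusion face coefficients
# (harmonic means; zero faces are no-flux walls), and kernel flags.
prep_solver <- function(grid, params, case, fields,
                        injection_flow = FALSE) {
  nx <- grid$nx
  ny <- grid$ny
  lbl <- grid$label
  mem_act <- lbl == 1L | lbl == 2L
  ecs_act <- mem_act
  ecs_act[grid$inflow] <- TRUE

  # effective per-cell D for face construction; inflow cells couple with the
  # gray-matter coefficient so the Dirichlet value diffuses into the tissue
  Dg <- case$diffusion_multiplier * params$D_star
  Dxx <- fields$Dxx
  Dyy <- fields$Dyy
  Dxx[grid$inflow] <- Dg
  Dyy[grid$inflow] <- Dg
  Dxx[!ecs_act] <- 0
  Dyy[!ecs_act] <- 0

  hmean <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  fe <- matrix(0, nx, ny)
  fn <- matrix(0, nx, ny)
  if (nx > 1) {
    both <- ecs_act[-nx, , drop = FALSE] & ecs_act[-1, , drop = FALSE]
    fe[-nx, ] <- both * hmean(Dxx[-nx, , drop = FALSE], Dxx[-1, , drop = FALSE])
  }
  if (ny > 1) {
    both <- ecs_act[, -ny, drop = FALSE] & ecs_act[, -1, drop = FALSE]
    fn[, -ny] <- both * hmean(Dyy[, -ny, drop = FALSE], Dyy[, -1, drop = FALSE])
  }

  ux <- fields$ux
  uy <- fields$uy
  if (injection_flow && params$injection_velocity > 0 &&
      !is.null(grid$injection_point)) {
    # exploratory radial source flow at the needle tip during injection
    cc <- cell_centers(grid)
    X <- matrix(cc$x, nx, ny) - grid$injection_point[1]
    Y <- matrix(cc$y, nx, ny, byrow = TRUE) - grid$injection_point[2]
    r <- sqrt(X^2 + Y^2)
    r0 <- 50e-6
    mag <- params$injection_velocity * pmin(1, r0 / pmax(r, grid$dx / 2))
    ux <- ux + ifelse(mem_act & r > 0, mag * X / pmax(r, grid$dx / 2), 0)
    uy <- uy + ifelse(mem_act & r > 0, mag * Y / pmax(r, grid$dx / 2), 0)
  }

  list(
    fe = fe, fn = fn, dxy = fields$Dxy,
    ux = ux, uy = uy, ubx = fields$ubx, uby = fields$uby,
    kup = fields$kup, ecs_act = ecs_act, mem_act = mem_act,
    use_cross = any(fields$Dxy != 0),
    use_ecs_adv = any(ux != 0) || any(uy != 0),
    use_mem_adv = any(fields$ubx != 0) || any(fields$uby != 0)
  )
}

#' Largest stable explicit time step
#'
#' Combines the advective Courant bound (using the fastest cell speed in
#' either compartment and the configured Courant number `C_max`) with the
#' standard explicit-diffusion cap `0.9 * dx^2 / (4 * max eigenvalue of the
#' diffusion tensor)`. Returns `Inf` when neither mechanism constrains the
#' step (the caller then caps the step at the output cadence).
#'
#' @param grid a `geometry_grid`.
#' @param fields a [region_fields()] object.
#' @param params a [default_parameters()] object.
#' @return Time step in s (possibly `Inf`).
#' @export
stable_dt <- function(grid, fields, params) {
  if (grid$dx <= 0) stop("grid spacing must be > 0", call. = FALSE)
  vmax <- max(
    sqrt(fields$ux^2 + fields$uy^2),
    sqrt(fields$ubx^2 + fields$uby^2),
    if (params$injection_velocity > 0) params$injection_velocity else 0
  )
  dt_adv <- courant_timestep(grid$dx, vmax, params$C_max)
  # largest eigenvalue of the symmetric 2x2 tensor per cell
  emax <- max((fields$Dxx + fields$Dyy) / 2 +
    sqrt(((fields$Dxx - fields$Dyy) / 2)^2 + fields$Dxy^2))
  dt_diff <- if (emax > 0) 0.9 * grid$dx^2 / (4 * emax) else Inf
  min(dt_adv, dt_diff)
}

#' Advance the coupled fields by one explicit step
#'
#' Low-level single-step update, mostly useful for testing; simulations are
#' run with [run_simulation()]. The step must satisfy the [stable_dt()]
#' bound; instability (non-finite values or concentrations exceeding ten
#' times the injected concentration) raises an error naming the time.
#'
#' @param state a [field_state()].
#' @param grid a `geometry_grid`.
#' @param fields a [region_fields()] object.
#' @param params a [default_parameters()] object.
#' @param dt time step in s.
#' @param post_injection inflow-cell condition after the injection ends:
#'   `"dirichlet_zero"` (hold at 0, the literal injection schedule) or
#'   `"no_flux"` (let the cells evolve freely).
#' @param injection logical; prescribe `c0` on the inflow cells while
#'   `t <= t_inject`.
#' @return The advanced `field_state`.
#' @export
step <- function(state, grid, fields, params, dt,
                 post_injection = c("dirichlet_zero", "no_flux"),
                 injection = TRUE) {
  post_injection <- match.arg(post_injection)
  stopifnot(inherits(state, "field_state"))
  case <- attr(fields, "case_id")
  case <- if (is.null(case)) build_case("C1") else build_case(case)
  prep <- prep_solver(grid, params, case, fields)
  blow <- 10 * max(params$c0, max(abs(state$c)), max(abs(state$cb)), 1e-30)
  res <- advance_fields_cpp(
    state$c, state$cb, prep$fe, prep$fn, prep$dxy,
    prep$ux, prep$uy, prep$ubx, prep$uby, prep$kup,
    prep$ecs_act, prep$mem_act,
    if (injection) as.integer(grid$inflow) else integer(0),
    params$c0, params$t_inject,
    if (post_injection == "dirichlet_zero") 0L else 1L,
    grid$dx, dt, 1L, state$t, blow,
    prep$use_cross, prep$use_ecs_adv, prep$use_mem_adv
  )
  if (res$status != 0) {
    stop(sprintf("solver diverged at t = %.4g s", res$t_fail), call. = FALSE)
  }
  field_state(res$c, res$cb, res$t)
}

#' Run a full clearance simulation
#'
#' Integrates the coupled ECS / basement-membrane model from `t = 0` to
#' `params$t_total` with a CFL-stable explicit step: the injected
#' concentration `c0` is prescribed on the inflow cells during the first
#' `t_inject` seconds, after which the fields evolve freely (with the
#' inflow cells held at zero under the default `"dirichlet_zero"` mode).
#' Detection distances (per compartment) and the compartment mass ledger
#' are recorded at every output time; full field snapshots are kept at
#' `snapshot_times`. The run is a pure function of its inputs: identical
#' inputs give identical outputs.
#'
#' @param case a [build_case()] object or case id string.
#' @param grid a `geometry_grid`.
#' @param params a [default_parameters()] object.
#' @param cadence output cadence in s (default 10).
#' @param snapshot_times times (s) at which to keep full field snapshots;
#'   default: end of injection, 5 min after injection, end of run.
#' @param post_injection see [step()].
#' @param injection logical; `FALSE` disables the injection entirely (used
#'   with `initial_state` for pulse-release experiments).
#' @param initial_state optional [field_state()] providing initial fields.
#' @param fields optional [region_fields()]-shaped coefficient override;
#'   by default the coefficients are derived from `grid`, `params`, `case`.
#' @return An object of class `clearance_sim` with elements `case_id`,
#'   `params`, `grid`, `threshold` (detection concentration, mol m^-3),
#'   `distance` (data.frame: time, ecs, membrane, combined, in m), `mass`
#'   (data.frame: time, moles_ecs, moles_membrane, moles_lost), `snapshots`
#'   (list of `field_state`), `final_state`.
#' @examples
#' \donttest{
#' g <- make_calibration_domain(2e-3, 2e-3, 50e-6, source = "point")
#' p <- default_parameters(t_total = 240)
#' sim <- run_simulation("A1", g, p, cadence = 60)
#' sim$distance
#' }
#' @export
run_simulation <- function(case, grid, params = default_parameters(),
                           cadence = 10,
                           snapshot_times = NULL,
                           post_injection = c("dirichlet_zero", "no_flux"),
                           injection = TRUE,
                           initial_state = NULL,
                           fields = NULL) {
  post_injection <- match.arg(post_injection)
  if (is.character(case)) case <- build_case(case)
  stopifnot(
    inherits(case, "case_spec"), inherits(grid, "geometry_grid"),
    inherits(params, "clearance_params"), cadence > 0
  )
  if (is.null(fields)) fields <- region_fields(grid, params, case)
  prep <- prep_solver(grid, params, case, fields)
  prep_inj <- if (injection && params$injection_velocity > 0) {
    prep_solver(grid, params, case, fields, injection_flow = TRUE)
  } else {
    prep
  }
  dt_max <- stable_dt(grid, fields, params)

  t_total <- params$t_total
  if (is.null(snapshot_times)) {
    snapshot_times <- unique(c(
      params$t_inject, min(params$t_inject + 300, t_total), t_total
    ))
  }
  tout <- sort(unique(c(
    seq(0, t_total, by = cadence), params$t_inject, t_total,
    snapshot_times
  )))
  tout <- tout[tout >= 0 & tout <= t_total]

  cw <- matrix(0, grid$nx, grid$ny)
  cbw <- cw
  if (!is.null(initial_state)) {
    stopifnot(inherits(initial_state, "field_state"))
    stopifnot(all(dim(initial_state$c) == c(grid$nx, grid$ny)))
    cw <- initial_state$c + 0
    cbw <- initial_state$cb + 0
  }
  do_inject <- injection && length(grid$inflow) > 0 && params$t_inject > 0
  if (do_inject) cw[grid$inflow] <- params$c0
  blow <- 10 * max(params$c0, max(abs(cw)), max(abs(cbw)), 1e-30)
  post_mode <- if (post_injection == "dirichlet_zero") 0L else 1L
  inflow <- if (do_inject) as.integer(grid$inflow) else integer(0)

  threshold <- params$detection_fraction * params$c0
  cc <- cell_centers(grid)
  rmat <- sqrt(
    outer(
      (cc$x - grid$injection_point[1])^2,
      (cc$y - grid$injection_point[2])^2, "+"
    )
  )
  cell_vol <- grid$dx^2 # unit out-of-plane depth (1 m), as in 2D convention

  nt <- length(tout)
  d_ecs <- d_mem <- m_ecs <- m_mem <- numeric(nt)
  snaps <- list()
  record <- function(k) {
    d_ecs[k] <<- if (any(cw >= threshold)) max(rmat[cw >= threshold]) else 0
    d_mem[k] <<- if (any(cbw >= threshold)) max(rmat[cbw >= threshold]) else 0
    m_ecs[k] <<- sum(cw[prep$ecs_act]) * cell_vol
    m_mem[k] <<- sum(cbw[prep$mem_act]) * cell_vol
    if (any(abs(tout[k] - snapshot_times) < 1e-9)) {
      snaps[[sprintf("t%g", tout[k])]] <<-
        field_state(cw + 0, cbw + 0, tout[k])
    }
  }
  record(1L)

  for (k in seq_len(nt)[-1]) {
    t0 <- tout[k - 1]
    t1 <- tout[k]
    pr <- if (t0 < params$t_inject) prep_inj else prep
    dt_cap <- if (pr$use_ecs_adv && params$injection_velocity > 0 &&
      t0 < params$t_inject) {
      min(dt_max, courant_timestep(
        grid$dx,
        max(sqrt(pr$ux^2 + pr$uy^2)), params$C_max
      ))
    } else {
      dt_max
    }
    dt_target <- min(dt_cap, t1 - t0)
    nsub <- as.integer(ceiling((t1 - t0) / dt_target - 1e-12))
    dt <- (t1 - t0) / nsub
    res <- advance_fields_cpp(
      cw, cbw, pr$fe, pr$fn, pr$dxy, pr$ux, pr$uy, pr$ubx, pr$uby, pr$kup,
      pr$ecs_act, pr$mem_act, inflow, params$c0, params$t_inject, post_mode,
      grid$dx, dt, nsub, t0, blow,
      pr$use_cross, pr$use_ecs_adv, pr$use_mem_adv
    )
    if (res$status != 0) {
      stop(sprintf(
        "solver diverged at t = %.4g s in case %s",
        res$t_fail, case$case_id
      ), call. = FALSE)
    }
    cw <- res$c
    cbw <- res$cb
    record(k)
  }

  dist <- data.frame(
    time = tout, ecs = d_ecs, membrane = d_mem,
    combined = pmax(d_ecs, d_mem)
  )
  mtot <- m_ecs + m_mem
  kref <- which.min(abs(tout - params$t_inject))
  lost <- ifelse(tout > params$t_inject, pmax(0, mtot[kref] - mtot), 0)
  mass <- data.frame(
    time = tout, moles_ecs = m_ecs, moles_membrane = m_mem,
    moles_lost = lost
  )

  structure(
    list(
      case_id = case$case_id, case = case, params = params, grid = grid,
      threshold = threshold, distance = dist, mass = mass,
      snapshots = snaps,
      final_state = field_state(cw, cbw, tout[nt]),
      post_injection = post_injection, cadence = cadence
    ),
    class = "clearance_sim"
  )
}

#' @export
print.clearance_sim <- function(x, ...) {
  cat(sprintf(
    "Clearance simulation, case %s on %s grid (%d x %d, dx = %g um)\n",
    x$case_id, x$grid$kind, x$grid$nx, x$grid$ny, x$grid$dx * 1e6
  ))
  n <- nrow(x$distance)
  cat(sprintf(
    "  t = %.0f s: max detection distance %.2f mm (ECS %.2f, membrane %.2f)\n",
    x$distance$time[n], x$distance$combined[n] * 1e3,
    x$distance$ecs[n] * 1e3, x$distance$membrane[n] * 1e3
  ))
  invisible(x)
}
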
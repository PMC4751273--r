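#' Default physical parameters of the clearance model
#'
#' Returns the parameter set used throughout the simulations. All values are
#' SI (m, s, mol m^-3; note 1 mM = 1 mol m^-3) and default to the published
#' measurements for 3 kDa dextran in mouse/rat brain tissue:
#'
#' * `D_star` = 8.7e-11 m^2 s^-1 -- effective diffusion coefficient in gray
#'   matter (already tortuosity-scaled, temperature-corrected to 37 C),
#' * `lambda_gray` = 1.60, `lambda_white_par` = 1.47,
#'   `lambda_white_perp` = 1.68 -- tortuosities; the free-medium coefficient
#'   implied by gray matter, `D_free = D_star * lambda_gray^2`, is divided by
#'   the white-matter lambdas squared to build the anisotropic tensor,
#' * `u_white` = 1.75e-7 m s^-1 -- bulk flow speed along white-matter fibers,
#' * `u_b` = 8.33e-6 m s^-1 -- apparent perivascular drainage speed
#'   (2.5 mm in 5 min),
#' * `k_b` = 2.5e-4 s^-1 -- first-order take-up rate from the ECS into the
#'   basement-membrane compartment; `k_d` = 0 (no degradation for dextran),
#' * `c0` = 0.33 mol m^-3 -- injected concentration (1 ug/ul of 3 kDa
#'   dextran), injected over `t_inject` = 120 s of a `t_total` = 1920 s run,
#' * `detection_fraction` = 1e-3 -- detection threshold as a fraction of
#'   `c0`,
#' * `C_max` = 0.5 -- Courant number bound for the explicit time step,
#' * `injection_velocity` = 0 m s^-1 -- optional radial convective flow at
#'   the needle tip during injection (exploratory; off by default).
#'
#' @param ... named overrides for any of the fields above.
#' @return An object of class `clearance_params` (a validated named list).
#' @examples
#' p <- default_parameters()
#' p$u_b
#' default_parameters(k_b = 0)$k_b
#' @export
default_parameters <- function(...) {
  p <- list(
    D_star = 8.7e-11,
    lambda_gray = 1.60,
    lambda_white_par = 1.47,
    lambda_white_perp = 1.68,
    u_white = 1.75e-7,
    u_b = 8.33e-6,
    k_b = 2.5e-4,
    k_d = 0,
    c0 = 0.33,
    t_inject = 120,
    t_total = 1920,
    detection_fraction = 1e-3,
    C_max = 0.5,
    injection_velocity = 0
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_parameters(p)
}

validate_parameters <- function(p) {
  num_fields <- c(
    "D_star", "lambda_gray", "lambda_white_par", "lambda_white_perp",
    "u_white", "u_b", "k_b", "k_d", "c0", "t_inject", "t_total",
    "detection_fraction", "C_max", "injection_velocity"
  )
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (p$detection_fraction <= 0 || p$detection_fraction >= 1) {
    stop("detection_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (p$C_max <= 0 || p$C_max > 1) {
    stop("C_max must lie in (0, 1]", call. = FALSE)
  }
  if (p$t_total < p$t_inject) {
    stop("t_total must be >= t_inject", call. = FALSE)
  }
  structure(p, class = "clearance_params")
}

#' @export
print.clearance_params <- function(x, ...) {
  cat("Clearance model parameters (SI units):\n")
  for (f in names(x)) cat(sprintf("  %-20s %g\n", f, x[[f]]))
  invisible(x)
}

# Simulation case table: multipliers on (D*, u_white, u_b, k_b).
.case_table <- data.frame(
  case_id = c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3", "C4"),
  diffusion_multiplier = c(1, 5, 10, 1, 1, 1, 1, 1, 1, 5),
  bulkflow_multiplier = c(0, 0, 0, 1, 5, 10, 1, 1, 1, 1),
  drainage_multiplier = c(0, 0, 0, 0, 0, 0, 1, 0.5, 0.5, 0.5),
  uptake_multiplier = c(0, 0, 0, 0, 0, 0, 1, 1, 0.1, 0.1),
  stringsAsFactors = FALSE
)

#' Simulation case definitions
#'
#' The ten simulation cases probe whether diffusion alone can explain the
#' observed tracer spread: A-cases are diffusion only (at 1x, 5x, 10x the
#' measured coefficient), B-cases add white-matter bulk flow (1x, 5x, 10x),
#' and C-cases add perivascular drainage and take-up at full or reduced
#' strength. Each case is a tuple of dimensionless multipliers applied to
#' `(D_star, u_white, u_b, k_b)`.
#'
#' @param case_id one of `"A1"`, `"A2"`, `"A3"`, `"B1"`, `"B2"`, `"B3"`,
#'   `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @return An object of class `case_spec` with fields `case_id`,
#'   `diffusion_multiplier`, `bulkflow_multiplier`, `drainage_multiplier`,
#'   `uptake_multiplier`.
#' @examples
#' build_case("A1")
#' build_case("C4")
#' @export
build_case <- function(case_id) {
  if (!is.character(case_id) || length(case_id) != 1L ||
      !case_id %in% .case_table$case_id) {
    stop(
      "unknown case id ", deparse(case_id), "; valid ids: ",
      paste(.case_table$case_id, collapse = ", "),
      call. = FALSE
    )
  }
  row <- .case_table[.case_table$case_id == case_id, ]
  structure(as.list(row), class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf(
    "Case %s: D* x %g, u x %g, u_b x %g, k_b x %g\n",
    x$case_id, x$diffusion_multiplier, x$bulkflow_multiplier,
    x$drainage_multiplier, x$uptake_multiplier
  ))
  invisible(x)
}

#' All simulation case ids
#' @return Character vector of the ten case ids.
#' @export
case_ids <- function() .case_table$case_id

#' Convert a mass concentration to molarity
#'
#' Converts a tracer mass concentration (as prepared for injection, in
#' micrograms per microliter, i.e. g/L) into a molar concentration in
#' mol m^-3 (numerically equal to mM), given the molecular weight.
#'
#' @param mass_concentration mass concentration in ug/ul (= g/L), >= 0.
#' @param molecular_weight molecular weight in Da (= g/mol), > 0.
#' @return Molar concentration in mol m^-3.
#' @examples
#' mass_to_molar(1, 3000) # 3 kDa dextran at 1 ug/ul -> 0.33 mM
#' @export
mass_to_molar <- function(mass_concentration, molecular_weight) {
  if (!is.numeric(mass_concentration) || any(mass_concentration < 0)) {
    stop("mass_concentration must be >= 0", call. = FALSE)
  }
  if (!is.numeric(molecular_weight) || any(molecular_weight <= 0)) {
    stop("molecular_weight must be > 0", call. = FALSE)
  }
  # g/L divided by g/mol -> mol/L; 1 mol/L = 1000 mol/m^3
  mass_concentration / molecular_weight * 1000
}

#' Temperature-correct a diffusion coefficient
#'
#' Applies the Stokes-Einstein scaling `D ~ T / mu` to translate a diffusion
#' coefficient measured at one temperature to another, using the dynamic
#' viscosities of the medium (water) at the two temperatures.
#'
#' @param D_ref diffusion coefficient at the reference temperature, m^2 s^-1.
#' @param T_ref,T_target absolute temperatures in K, > 0.
#' @param mu_ref,mu_target dynamic viscosities in Pa s, > 0.
#' @return `D_ref * (T_target / T_ref) * (mu_ref / mu_target)`.
#' @examples
#' temperature_correct_diffusion(1e-10, 293.15, 310.15, 1.002e-3, 0.6913e-3)
#' @export
temperature_correct_diffusion <- function(D_ref, T_ref, T_target,
                                          mu_ref, mu_target) {
  vals <- c(D_ref, T_ref, T_target, mu_ref, mu_target)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all arguments must be positive finite numbers", call. = FALSE)
  }
  D_ref * (T_target / T_ref) * (mu_ref / mu_target)
}

#' CFL-limited time step
#'
#' Largest explicit time step keeping the Courant number `C = u * dt / dx`
#' at or below the given bound. With zero speed the advective constraint is
#' vacuous and `Inf` is returned so callers fall back to the diffusive
#' stability cap (see [stable_dt()]).
#'
#' @param dx grid spacing, m, > 0.
#' @param speed advection speed, m s^-1, >= 0.
#' @param C Courant number bound, dimensionless, > 0.
#' @return Time step in s; `Inf` when `speed == 0`.
#' @examples
#' courant_timestep(2.36e-6, 8.33e-6, 0.5) # ~0.14 s
#' @export
courant_timestep <- function(dx, speed, C) {
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.numeric(speed) || speed < 0) stop("speed must be >= 0", call. = FALSE)
  if (speed == 0) return(Inf)
  C * dx / speed
}

#' Peclet number
#'
#' Dimensionless ratio of convective to diffusive transport,
#' `Pe = L * U / D`. The simulations use the height of the mouse brain
#' (5.5 mm) as the length scale.
#'
#' @param L length scale, m, > 0.
#' @param U velocity, m s^-1, >= 0.
#' @param D diffusion coefficient, m^2 s^-1, > 0.
#' @return `L * U / D`.
#' @examples
#' peclet(5.5e-3, 8.33e-6, 8.7e-11) # drainage-dominated: Pe ~ 527
#' @export
peclet <- function(L, U, D) {
  if (!is.numeric(L) || L <= 0) stop("L must be > 0", call. = FALSE)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  if (!is.numeric(U) || U < 0) stop("U must be >= 0", call. = FALSE)
  L * U / D
}

#' Peclet numbers of the simulation cases
#'
#' Evaluates the Peclet number of each case with the convention used in the
#' case table: B-cases use the (scaled) white-matter bulk flow speed,
#' C-cases the (scaled) perivascular drainage speed, and the diffusion
#' coefficient is the case's scaled `D_star`. A-cases have no flow (Pe = 0).
#'
#' @param params a [default_parameters()] object.
#' @param L length scale in m; defaults to the 5.5 mm brain height.
#' @return data.frame with columns `case_id`, `velocity` (the speed used),
#'   and `Pe`.
#' @export
case_peclet <- function(params = default_parameters(), L = 5.5e-3) {
  tab <- .case_table
  U <- ifelse(
    tab$drainage_multiplier > 0,
    tab$drainage_multiplier * params$u_b,
    tab$bulkflow_multiplier * params$u_white
  )
  D <- tab$diffusion_multiplier * params$D_star
  data.frame(
    case_id = tab$case_id,
    velocity = U,
    Pe = mapply(function(u, d) peclet(L, u, d), U, D),
    stringsAsFactors = FALSE
  )
}
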
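#' Porewater solute state
#'
#' Holds a per-cell porewater concentration profile for one solute, together
#' with the overlying-water concentration that drives diffusive and nonlocal
#' exchange.  Concentrations are per volume of porewater (mM or uM, kept
#' consistent within a profile).
#'
#' @param solute_name label, e.g. `"DIC"` or `"SO4"`.
#' @param concentration numeric vector, one value per grid cell, finite and
#'   non-negative.
#' @param overlying_water_conc scalar concentration of the overlying water.
#' @param time days since experiment start.
#' @return An object of class `"solute_state"`.
#' @export
solute_state <- function(solute_name, concentration, overlying_water_conc,
                         time = 0) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop_invalid("`concentration` must be finite and non-negative")
  if (!is.finite(overlying_water_conc) || overlying_water_conc < 0)
    stop_invalid("`overlying_water_conc` must be finite and non-negative")
  structure(list(solute_name = as.character(solute_name),
                 concentration = as.double(concentration),
                 overlying_water_conc = as.double(overlying_water_conc),
                 time = as.double(time)),
            class = "solute_state")
}

#' Solid-phase pigment tracer state
#'
#' Chlorophyll a and pheopigment concentrations per g wet sediment, one value
#' per grid cell.
#'
#' @param chl_a,pheopigment numeric vectors, finite and non-negative.
#' @param time days since experiment start.
#' @return An object of class `"tracer_state"`.
#' @export
tracer_state <- function(chl_a, pheopigment, time = 0) {
  if (length(chl_a) != length(pheopigment))
    stop_invalid("`chl_a` and `pheopigment` must have the same length")
  if (any(!is.finite(chl_a)) || any(chl_a < 0) ||
      any(!is.finite(pheopigment)) || any(pheopigment < 0))
    stop_invalid("tracer concentrations must be finite and non-negative")
  structure(list(chl_a = as.double(chl_a), pheopigment = as.double(pheopigment),
                 time = as.double(time)),
            class = "tracer_state")
}

#' Nonlocal exchange field
#'
#' Depth-dependent nonlocal exchange frequencies (1/day): `alpha_physical`
#' is tide-driven porewater flushing, `alpha_biological` is lugworm
#' bioirrigation.  Each is a per-cell vector on the model grid.
#'
#' @param grid a [build_grid()] object.
#' @param alpha_physical,alpha_biological non-negative vectors of length
#'   `grid$n_cells` (scalars are recycled).
#' @return An object of class `"exchange_field"`.
#' @export
exchange_field <- function(grid, alpha_physical = 0, alpha_biological = 0) {
  validate_grid(grid)
  n <- grid$n_cells
  ap <- rep_len(as.double(alpha_physical), n)
  ab <- rep_len(as.double(alpha_biological), n)
  if (any(!is.finite(ap)) || any(ap < 0) || any(!is.finite(ab)) || any(ab < 0))
    stop_invalid("exchange frequencies must be finite and non-negative")
  structure(list(alpha_physical = ap, alpha_biological = ab),
            class = "exchange_field")
}

#' Depth profiles for mixing parameters
#'
#' `profile_exponential()` gives `amplitude * exp(-x / length_scale)`, the
#' shape used for physically driven mixing that is strongest at the
#' sediment--water interface.  `profile_window()` gives a constant
#' `amplitude` on `[z1, z2]` with half-cosine ramps of width `ramp` cm on
#' either side, the shape used for faunal activity confined to a living
#' depth.
#'
#' @param grid a [build_grid()] object.
#' @param amplitude peak value (units of the target quantity).
#' @param length_scale e-folding depth in cm (`> 0`).
#' @param z1,z2 window edges in cm, `z1 < z2`.
#' @param ramp half-cosine edge width in cm (`>= 0`).
#' @return Numeric vector over `grid$cell_centers`.
#' @export
profile_exponential <- function(grid, amplitude, length_scale) {
  validate_grid(grid)
  if (amplitude < 0 || length_scale <= 0)
    stop_invalid("`amplitude` must be >= 0 and `length_scale` > 0")
  amplitude * exp(-grid$cell_centers / length_scale)
}

#' @rdname profile_exponential
#' @export
profile_window <- function(grid, amplitude, z1, z2, ramp = 2) {
  validate_grid(grid)
  if (amplitude < 0 || ramp < 0 || z1 >= z2)
    stop_invalid("need `amplitude` >= 0, `ramp` >= 0 and `z1` < `z2`")
  x <- grid$cell_centers
  out <- numeric(length(x))
  core <- x >= z1 & x <= z2
  out[core] <- 1
  if (ramp > 0) {
    up <- x > z1 - ramp & x < z1
    out[up] <- 0.5 * (1 + cos(pi * (z1 - x[up]) / ramp))
    dn <- x > z2 & x < z2 + ramp
    out[dn] <- 0.5 * (1 + cos(pi * (x[dn] - z2) / ramp))
  }
  amplitude * out
}

#' Transport parameters
#'
#' Physical constants of the forward models.  Solute diffusion uses the
#' free-solution diffusivity `molecular_diffusivity` corrected for
#' tortuosity; solid-phase mixing uses the depth-dependent biodiffusion
#' fields `biodiffusion_physical` (`D_P(x)`) and `biodiffusion_biological`
#' (`D_B(x)`).  Chlorophyll a decays at `chl_decay` (1/day) and converts to
#' pheopigment with fractional yield `chl_to_pheo_yield`; pheopigment decays
#' at `pheo_decay`.  `surface_chl_flux` is the chl-a deposition flux at the
#' interface, expressed per unit bulk sediment (concentration x cm / day).
#' `reaction_decay` and `reaction_production` are optional first-order sink
#' and constant source hooks for solutes (both default to zero).
#'
#' @param molecular_diffusivity free-solution diffusivity D0 (cm^2/day).
#' @param tortuosity `"boudreau"` for `D_s = D0 / (1 - 2 ln phi)` (the
#'   standard sand correction) or `"none"` for `D_s = D0`.
#' @param biodiffusion_physical,biodiffusion_biological per-cell vectors
#'   (cm^2/day) or scalars; see [profile_exponential()] / [profile_window()].
#' @param chl_decay,pheo_decay first-order decay constants (1/day).
#' @param chl_to_pheo_yield fraction in `[0, 1]`.
#' @param surface_chl_flux chl-a deposition flux at `x = 0`.
#' @param reaction_decay,reaction_production solute reaction hooks (1/day,
#'   concentration/day).
#' @return An object of class `"transport_params"`.
#' @export
transport_params <- function(molecular_diffusivity = 0,
                             tortuosity = c("boudreau", "none"),
                             biodiffusion_physical = 0,
                             biodiffusion_biological = 0,
                             chl_decay = 0, pheo_decay = 0,
                             chl_to_pheo_yield = 1,
                             surface_chl_flux = 0,
                             reaction_decay = 0,
                             reaction_production = 0) {
  tortuosity <- match.arg(tortuosity)
  vals <- c(molecular_diffusivity, biodiffusion_physical,
            biodiffusion_biological, chl_decay, pheo_decay, surface_chl_flux,
            reaction_decay, reaction_production)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_invalid("rates, diffusivities and fluxes must be finite and >= 0")
  if (!is.finite(chl_to_pheo_yield) || chl_to_pheo_yield < 0 ||
      chl_to_pheo_yield > 1)
    stop_invalid("`chl_to_pheo_yield` must lie in [0, 1]")
  structure(list(molecular_diffusivity = molecular_diffusivity,
                 tortuosity = tortuosity,
                 biodiffusion_physical = biodiffusion_physical,
                 biodiffusion_biological = biodiffusion_biological,
                 chl_decay = chl_decay, pheo_decay = pheo_decay,
                 chl_to_pheo_yield = chl_to_pheo_yield,
                 surface_chl_flux = surface_chl_flux,
                 reaction_decay = reaction_decay,
                 reaction_production = reaction_production),
            class = "transport_params")
}

effective_diffusivity <- function(params, porosity) {
  d0 <- params$molecular_diffusivity
  if (params$tortuosity == "boudreau") d0 / (1 - 2 * log(porosity)) else
    rep_len(d0, length(porosity))
}

# Assemble the tridiagonal spatial operator A and constant source b so that
# dC/dt = A C + b for the finite-volume discretization.  `diffusivity` is the
# cell-wise effective diffusivity of the transported quantity; `weight` is
# the capacity factor (porosity for solutes, 1 for solids); `decay` and
# `source` are cell-wise linear reaction terms.  Boundaries:
#   top:    list(type = "dirichlet", value=) | "no_flux" | list(type="flux", value=)
#   bottom: "no_flux" | list(type = "dirichlet", value=)
# Dirichlet faces use a second-order one-sided gradient so the scheme stays
# second-order accurate up to the wall.
assemble_operator <- function(grid, diffusivity, weight, decay, source,
                              top, bottom) {
  n <- grid$n_cells
  h <- grid$cell_widths[1]
  pd <- weight * diffusivity                  # conductivity phi * D_s
  face <- 2 * pd[-n] * pd[-1] / (pd[-n] + pd[-1])
  face[!is.finite(face)] <- 0                 # both sides zero conductivity
  w <- face / h^2
  lower <- w / weight[-1]
  upper <- w / weight[-n]
  diag <- numeric(n)
  diag[1] <- -w[1] / weight[1]
  if (n > 2) diag[2:(n - 1)] <- -(w[-(n - 1)] + w[-1]) / weight[2:(n - 1)]
  diag[n] <- -w[n - 1] / weight[n]
  b <- rep_len(as.double(source), n)
  diag <- diag - rep_len(as.double(decay), n)

  bc <- function(side) if (is.character(side)) list(type = side) else side
  top <- bc(top); bottom <- bc(bottom)
  if (top$type == "dirichlet") {
    g <- pd[1] / (weight[1] * h^2)
    diag[1] <- diag[1] - 3 * g
    upper[1] <- upper[1] + g / 3
    b[1] <- b[1] + (8 / 3) * g * top$value
  } else if (top$type == "flux") {
    b[1] <- b[1] + top$value / (weight[1] * h)
  } else if (top$type != "no_flux") stop_invalid("unknown top boundary type")
  if (bottom$type == "dirichlet") {
    g <- pd[n] / (weight[n] * h^2)
    diag[n] <- diag[n] - 3 * g
    lower[n - 1] <- lower[n - 1] + g / 3
    b[n] <- b[n] + (8 / 3) * g * bottom$value
  } else if (bottom$type != "no_flux") stop_invalid("unknown bottom boundary type")
  list(lower = lower, diag = diag, upper = upper, b = b)
}

# March dC/dt = A C + b with backward Euler over the requested output times.
march_operator <- function(op, c0, output_times, dt_target) {
  out <- matrix(NA_real_, length(c0), length(output_times))
  t_prev <- 0
  state <- c0
  for (j in seq_along(output_times)) {
    delta <- output_times[j] - t_prev
    if (delta <= 0) { out[, j] <- state; next }
    n_sub <- max(1L, ceiling(delta / dt_target))
    dt <- delta / n_sub
    res <- tridiag_march_cpp(-dt * op$lower, 1 - dt * op$diag, -dt * op$upper,
                             dt * op$b, state, n_sub, n_sub)
    state <- res[, 1]
    if (any(!is.finite(state)))
      stop(sprintf("solver diverged at t = %g days", output_times[j]),
           call. = FALSE)
    out[, j] <- state
    t_prev <- output_times[j]
  }
  out
}

check_output_times <- function(output_times, duration) {
  if (!is.numeric(duration) || duration <= 0)
    stop_invalid("`duration` must be positive")
  if (any(!is.finite(output_times)) || is.unsorted(output_times, strictly = TRUE) ||
      any(output_times < 0) || any(output_times > duration + 1e-12))
    stop_invalid("`output_times` must be strictly increasing within [0, duration]")
  output_times
}

#' Solve the nonlocal-exchange porewater solute model
#'
#' Integrates
#' \deqn{\partial(\phi C)/\partial t = \partial_x(\phi D_s \partial_x C)
#'   + \phi\,[\alpha_P(x) + \alpha_B(x)]\,(C_{ow} - C)
#'   + \phi\,(P - k C)}
#' on the sediment grid with (by default) a fixed concentration
#' \eqn{C = C_{ow}} at the interface and zero gradient at depth.  Time
#' stepping is backward Euler (unconditionally stable); the step length is
#' chosen so that `rate * dt <= 0.1` for the fastest linear rate.
#'
#' @param grid a [build_grid()] object.
#' @param params a [transport_params()] object (uses `molecular_diffusivity`,
#'   `tortuosity` and the reaction hooks).
#' @param exchange an [exchange_field()].
#' @param initial a [solute_state()]; its `overlying_water_conc` sets the
#'   boundary/exchange concentration.
#' @param duration total simulated time (days).
#' @param output_times strictly increasing times in `[0, duration]` at which
#'   states are returned; defaults to `duration`.
#' @param top_boundary `"dirichlet"` (fixed at `C_ow`, the default) or
#'   `"no_flux"`.
#' @param bottom_boundary `"no_flux"` (default) or `"dirichlet"` with
#'   `bottom_value`.
#' @param bottom_value bottom concentration when `bottom_boundary =
#'   "dirichlet"`.
#' @param dt optional time-step override (days).
#' @return A list of [solute_state()] objects, one per output time.
#' @export
solve_solute <- function(grid, params, exchange, initial, duration,
                         output_times = duration,
                         top_boundary = c("dirichlet", "no_flux"),
                         bottom_boundary = c("no_flux", "dirichlet"),
                         bottom_value = NULL, dt = NULL) {
  validate_grid(grid)
  stopifnot(inherits(params, "transport_params"),
            inherits(exchange, "exchange_field"),
            inherits(initial, "solute_state"))
  top_boundary <- match.arg(top_boundary)
  bottom_boundary <- match.arg(bottom_boundary)
  n <- grid$n_cells
  if (length(initial$concentration) != n)
    stop_invalid("initial concentration length must equal the grid cell count")
  if (any(!is.finite(initial$concentration)))
    stop_invalid("initial concentration contains non-finite values")
  output_times <- check_output_times(output_times, duration)

  alpha <- exchange$alpha_physical + exchange$alpha_biological
  if (length(alpha) != n) stop_invalid("exchange field length mismatch")
  ds <- effective_diffusivity(params, grid$porosity)
  c_ow <- initial$overlying_water_conc
  op <- assemble_operator(
    grid, diffusivity = ds, weight = grid$porosity,
    decay = alpha + params$reaction_decay,
    source = alpha * c_ow + params$reaction_production,
    top = if (top_boundary == "dirichlet")
      list(type = "dirichlet", value = c_ow) else "no_flux",
    bottom = if (bottom_boundary == "dirichlet")
      list(type = "dirichlet", value = bottom_value) else "no_flux")
  max_rate <- max(alpha + params$reaction_decay, 0)
  dt_target <- if (!is.null(dt)) dt else
    min(0.1, if (max_rate > 0) 0.1 / max_rate else Inf)
  states <- march_operator(op, initial$concentration, output_times, dt_target)
  lapply(seq_along(output_times), function(j)
    solute_state(initial$solute_name, pmax(states[, j], 0), c_ow,
                 time = initial$time + output_times[j]))
}

#' Steady state of the porewater solute model
#'
#' Solves the stationary form of the equation in [solve_solute()] directly
#' (one tridiagonal solve, no time stepping).
#'
#' @inheritParams solve_solute
#' @param c_ow overlying-water concentration.
#' @param solute_name label for the returned state.
#' @return A [solute_state()] at `time = Inf`.
#' @export
solve_solute_steady <- function(grid, params, exchange, c_ow,
                                solute_name = "solute",
                                top_boundary = c("dirichlet", "no_flux"),
                                bottom_boundary = c("no_flux", "dirichlet"),
                                bottom_value = NULL) {
  validate_grid(grid)
  top_boundary <- match.arg(top_boundary)
  bottom_boundary <- match.arg(bottom_boundary)
  alpha <- exchange$alpha_physical + exchange$alpha_biological
  ds <- effective_diffusivity(params, grid$porosity)
  op <- assemble_operator(
    grid, diffusivity = ds, weight = grid$porosity,
    decay = alpha + params$reaction_decay,
    source = alpha * c_ow + params$reaction_production,
    top = if (top_boundary == "dirichlet")
      list(type = "dirichlet", value = c_ow) else "no_flux",
    bottom = if (bottom_boundary == "dirichlet")
      list(type = "dirichlet", value = bottom_value) else "no_flux")
  conc <- tridiag_solve_cpp(-op$lower, -op$diag, -op$upper, op$b)
  solute_state(solute_name, pmax(conc, 0), c_ow, time = Inf)
}

#' Solve the solid-phase pigment tracer model
#'
#' Integrates the coupled pair
#' \deqn{\partial Chl/\partial t = \partial_x([D_P + D_B]\partial_x Chl) - k_{chl} Chl}
#' \deqn{\partial Pheo/\partial t = \partial_x([D_P + D_B]\partial_x Pheo)
#'   + y\,k_{chl}\,Chl - k_{pheo} Pheo}
#' with a prescribed chl-a deposition flux at the interface and zero-gradient
#' bottom.  Chl a is advanced implicitly; pheopigment is then advanced
#' implicitly using the freshly updated chl-a field as its source.
#'
#' @inheritParams solve_solute
#' @param initial a [tracer_state()].
#' @param top_boundary `"flux"` (deposition flux `surface_chl_flux`, default)
#'   or `"no_flux"` (closed column, used for conservation audits).
#' @return A list of [tracer_state()] objects, one per output time.
#' @export
solve_pigments <- function(grid, params, initial, duration,
                           output_times = duration,
                           top_boundary = c("flux", "no_flux"), dt = NULL) {
  validate_grid(grid)
  stopifnot(inherits(params, "transport_params"),
            inherits(initial, "tracer_state"))
  top_boundary <- match.arg(top_boundary)
  n <- grid$n_cells
  if (length(initial$chl_a) != n)
    stop_invalid("initial tracer length must equal the grid cell count")
  output_times <- check_output_times(output_times, duration)
  d_mix <- rep_len(params$biodiffusion_physical, n) +
    rep_len(params$biodiffusion_biological, n)
  ones <- rep(1, n)
  top <- if (top_boundary == "flux")
    list(type = "flux", value = params$surface_chl_flux) else "no_flux"
  op_c <- assemble_operator(grid, d_mix, ones, params$chl_decay, 0,
                            top = top, bottom = "no_flux")
  op_p <- assemble_operator(grid, d_mix, ones, params$pheo_decay, 0,
                            top = "no_flux", bottom = "no_flux")
  max_rate <- max(params$chl_decay, params$pheo_decay)
  dt_target <- if (!is.null(dt)) dt else
    min(0.1, if (max_rate > 0) 0.1 / max_rate else Inf)

  out <- vector("list", length(output_times))
  chl <- initial$chl_a; pheo <- initial$pheopigment
  t_prev <- 0
  for (j in seq_along(output_times)) {
    delta <- output_times[j] - t_prev
    if (delta > 0) {
      n_sub <- max(1L, ceiling(delta / dt_target))
      dts <- delta / n_sub
      res <- pigment_march_cpp(
        -dts * op_c$lower, 1 - dts * op_c$diag, -dts * op_c$upper, dts * op_c$b,
        -dts * op_p$lower, 1 - dts * op_p$diag, -dts * op_p$upper, dts * op_p$b,
        rep(dts * params$chl_to_pheo_yield * params$chl_decay, n),
        chl, pheo, n_sub, n_sub)
      chl <- res$chl[, 1]; pheo <- res$pheo[, 1]
      if (any(!is.finite(chl)) || any(!is.finite(pheo)))
        stop(sprintf("solver diverged at t = %g days", output_times[j]),
             call. = FALSE)
      t_prev <- output_times[j]
    }
    out[[j]] <- tracer_state(pmax(chl, 0), pmax(pheo, 0),
                             time = initial$time + output_times[j])
  }
  out
}

#' Steady state of the pigment tracer model
#'
#' Direct stationary solve of the equations in [solve_pigments()] with the
#' deposition-flux top boundary.
#'
#' @inheritParams solve_pigments
#' @return A [tracer_state()] at `time = Inf`.
#' @export
solve_pigments_steady <- function(grid, params) {
  validate_grid(grid)
  n <- grid$n_cells
  if (params$chl_decay <= 0 || params$pheo_decay <= 0)
    stop_invalid("steady pigment profiles need positive decay constants")
  d_mix <- rep_len(params$biodiffusion_physical, n) +
    rep_len(params$biodiffusion_biological, n)
  ones <- rep(1, n)
  op_c <- assemble_operator(grid, d_mix, ones, params$chl_decay, 0,
                            top = list(type = "flux",
                                       value = params$surface_chl_flux),
                            bottom = "no_flux")
  chl <- pmax(tridiag_solve_cpp(-op_c$lower, -op_c$diag, -op_c$upper, op_c$b), 0)
  op_p <- assemble_operator(grid, d_mix, ones, params$pheo_decay,
                            params$chl_to_pheo_yield * params$chl_decay * chl,
                            top = "no_flux", bottom = "no_flux")
  pheo <- pmax(tridiag_solve_cpp(-op_p$lower, -op_p$diag, -op_p$upper, op_p$b), 0)
  tracer_state(chl, pheo, time = Inf)
}

#' Nonlocal exchange mass budget
#'
#' Depth-integrated flux contributed by the nonlocal exchange term,
#' \eqn{\sum_i \phi_i (\alpha_{P,i} + \alpha_{B,i}) (C_{ow} - C_i) w_i},
#' positive into the sediment (amount per unit area per day).
#'
#' @inheritParams solve_solute
#' @param state a [solute_state()] on the same grid.
#' @return A single number.
#' @export
exchange_budget <- function(grid, state, exchange) {
  validate_grid(grid)
  stopifnot(inherits(state, "solute_state"), inherits(exchange, "exchange_field"))
  n <- grid$n_cells
  if (length(state$concentration) != n ||
      length(exchange$alpha_physical) != n)
    stop_invalid("state/exchange lengths must match the grid")
  sum(grid$porosity * (exchange$alpha_physical + exchange$alpha_biological) *
        (state$overlying_water_conc - state$concentration) * grid$cell_widths)
}

#' Depth-integrated inventory of a profile
#'
#' @param grid a [build_grid()] object.
#' @param values per-cell concentrations.
#' @param porosity_weighted multiply by porosity (porewater solutes) or not
#'   (solid tracers).
#' @return Amount per unit area.
#' @export
depth_integral <- function(grid, values, porosity_weighted = FALSE) {
  validate_grid(grid)
  if (length(values) != grid$n_cells) stop_invalid("length mismatch with grid")
  w <- grid$cell_widths
  if (porosity_weighted) w <- w * grid$porosity
  sum(values * w)
}
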
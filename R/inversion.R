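#' Configuration for mixing-parameter inversion
#'
#' Bundles the grid, per-analyte transport constants, pigment constants and
#' optimizer settings used by the fitting routines.  Defaults mirror the
#' synthetic study scenario (see [scenario_config()]): DIC and sulfate in a
#' 40 cm sand column, porewater calibration on the first two time points of
#' a four-week manipulation experiment, pigment calibration against steady
#' profiles.
#'
#' @param grid a [build_grid()] object.
#' @param analytes named list; per analyte a list with `d0` (free-solution
#'   diffusivity, cm^2/day), `c_ow` (overlying water) and `c_init` (uniform
#'   initial concentration after sieving/homogenization).
#' @param pigments list with `k_chl`, `k_pheo`, `yield`, `flux` used by the
#'   particle-mixing fit (held fixed; only mixing coefficients are fitted).
#' @param ramp half-cosine edge width (cm) of the bioirrigation and
#'   biodiffusion windows.
#' @param bounds named list of length-2 numeric bounds for each fitted
#'   parameter (`a_P`, `L_P`, `a_B`, `z1`, `width`, `d_P`, `L_DP`, `d_B`,
#'   `w1`, `wwidth`).
#' @param n_starts number of Latin-hypercube multistarts.
#' @param seed integer seed controlling the multistart design.
#' @param dt optional solver time-step override (days).
#' @return A list of class `"inversion_config"`.
#' @export
inversion_config <- function(grid = build_grid(40, 80, 0.4),
                             analytes = list(
                               DIC = list(d0 = 0.8, c_ow = 2.1, c_init = 7),
                               SO4 = list(d0 = 0.75, c_ow = 28, c_init = 22)),
                             pigments = list(k_chl = 0.02, k_pheo = 0.002,
                                             yield = 1, flux = 1.5),
                             ramp = 2,
                             bounds = list(a_P = c(0, 5), L_P = c(0.5, 15),
                                           a_B = c(0, 5), z1 = c(0, 30),
                                           width = c(1, 30),
                                           d_P = c(0, 10), L_DP = c(0.5, 15),
                                           d_B = c(0, 5), w1 = c(0, 30),
                                           wwidth = c(1, 30)),
                             n_starts = 8, seed = 1, dt = NULL) {
  validate_grid(grid)
  structure(list(grid = grid, analytes = analytes, pigments = pigments,
                 ramp = ramp, bounds = bounds, n_starts = n_starts,
                 seed = seed, dt = dt),
            class = "inversion_config")
}

fit_result <- function(parameters, loss, converged, n_evaluations, residuals,
                       bounds, seed, flags = character()) {
  structure(list(parameters = parameters, loss = loss, converged = converged,
                 n_evaluations = n_evaluations, residuals = residuals,
                 bounds = bounds, seed = seed, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:",
      paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
            collapse = ", "),
      sprintf("\n  loss = %.6g, converged = %s, evaluations = %d\n",
              x$loss, x$converged, x$n_evaluations))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Bounded derivative-free minimization: Nelder-Mead on logit-transformed
# coordinates from `n_starts` seeded Latin-hypercube starts, best loss wins,
# ties broken by lexicographically smallest parameter vector, followed by
# one polish restart from the winner.
multistart_minimize <- function(loss_fn, lower, upper, n_starts, seed,
                                maxit = 600) {
  k <- length(lower)
  n_eval <- 0L
  to_x <- function(z) lower + (upper - lower) * plogis(z)
  wrapped <- function(z) {
    n_eval <<- n_eval + 1L
    val <- loss_fn(to_x(z))
    if (!is.finite(val)) 1e300 else val
  }
  design <- with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- qlogis(0.02 + 0.96 * design)
  lex_smaller <- function(a, b) {
    for (i in seq_along(a)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    FALSE
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- optim(starts[s, ], wrapped, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = maxit))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         lex_smaller(to_x(fit$par), to_x(best$par)))) best <- fit
  }
  polish <- optim(best$par, wrapped, method = "Nelder-Mead",
                  control = list(reltol = 1e-12, maxit = maxit))
  if (polish$value <= best$value) best <- polish
  list(par = to_x(best$par), value = best$value,
       converged = polish$convergence == 0, n_evaluations = n_eval)
}

check_profile_obs <- function(observations,
                              required = c("analyte", "treatment", "day",
                                           "depth_cm", "value")) {
  missing <- setdiff(required, names(observations))
  if (length(missing))
    stop_invalid("observations lack columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(observations$value)) || any(observations$value < 0))
    stop_invalid("observation values must be finite and non-negative")
  observations
}

# Per-observation inverse-variance weights under the multiplicative
# (log-normal) error model: the error sd of each measurement scales with its
# value, so var_i is proportional to value_i^2.  A floor at 1% of the analyte
# mean keeps near-zero observations from dominating.
error_weights <- function(values, all_values) {
  floor_ <- 0.01 * mean(abs(all_values))
  if (!is.finite(floor_) || floor_ <= 0) return(rep(1, length(values)))
  1 / pmax(abs(values), floor_)^2
}

# Linear-interpolation weights from cell centers to observation depths
# (constant extrapolation beyond the end cells).
interp_weights <- function(centers, xout) {
  n <- length(centers)
  lo <- pmin(pmax(findInterval(xout, centers), 1L), n - 1L)
  frac <- (xout - centers[lo]) / (centers[lo + 1L] - centers[lo])
  frac <- pmin(pmax(frac, 0), 1)
  list(lo = lo, frac = frac)
}

# Objective factory for porewater fits.  Precomputes, per analyte, the
# diffusion part of the operator, the observation layout and the variance
# weights, so each evaluation only adds the exchange terms and marches.
# Numerically identical to running solve_solute() with default settings.
make_porewater_objective <- function(observations, config) {
  grid <- config$grid
  n <- grid$n_cells
  per_analyte <- lapply(unique(observations$analyte), function(an) {
    obs <- observations[observations$analyte == an, ]
    spec <- config$analytes[[an]]
    if (is.null(spec)) stop_invalid("no analyte configuration for ", an)
    days <- sort(unique(obs$day))
    by_day <- lapply(days, function(dd) {
      sel <- obs$day == dd
      c(list(value = obs$value[sel],
             weight = error_weights(obs$value[sel], obs$value)),
        interp_weights(grid$cell_centers, obs$depth_cm[sel]))
    })
    ds <- effective_diffusivity(
      transport_params(molecular_diffusivity = spec$d0), grid$porosity)
    list(ds = ds, c_ow = spec$c_ow, c_init = rep(spec$c_init, n),
         days = days, by_day = by_day)
  })
  function(alpha_p, alpha_b) {
    alpha <- alpha_p + alpha_b
    max_rate <- max(alpha, 0)
    dt_target <- if (!is.null(config$dt)) config$dt else
      min(0.1, if (max_rate > 0) 0.1 / max_rate else Inf)
    total <- 0
    resid_all <- numeric(0)
    for (pa in per_analyte) {
      op <- assemble_operator(grid, pa$ds, grid$porosity, alpha,
                              alpha * pa$c_ow,
                              top = list(type = "dirichlet", value = pa$c_ow),
                              bottom = "no_flux")
      state <- pa$c_init
      t_prev <- 0
      for (j in seq_along(pa$days)) {
        delta <- pa$days[j] - t_prev
        if (delta > 0) {
          n_sub <- max(1L, ceiling(delta / dt_target))
          dt <- delta / n_sub
          state <- tridiag_march_cpp(-dt * op$lower, 1 - dt * op$diag,
                                     -dt * op$upper, dt * op$b, state,
                                     n_sub, n_sub)[, 1]
          t_prev <- pa$days[j]
        }
        conc <- pmax(state, 0)
        bd <- pa$by_day[[j]]
        pred <- conc[bd$lo] * (1 - bd$frac) + conc[bd$lo + 1L] * bd$frac
        r <- pred - bd$value
        total <- total + sum(bd$weight * r^2)
        resid_all <- c(resid_all, r)
      }
    }
    list(loss = total, residuals = resid_all)
  }
}

#' Fit physical porewater mixing from the defaunated treatment
#'
#' Estimates the amplitude `a_P` and e-folding depth `L_P` of the physical
#' nonlocal exchange profile `alpha_P(x) = a_P exp(-x / L_P)` by weighted
#' least squares against defaunated porewater profiles, with bioirrigation
#' forced to zero.  The transient forward model starts from a uniform
#' concentration (sieved, homogenized sediment).
#'
#' @param observations data frame with columns `analyte`, `treatment`,
#'   `day` (days since start), `depth_cm`, `value` (plus optional
#'   `time_point`, `replicate`); only rows from the defaunated treatment are
#'   used.
#' @param config an [inversion_config()].
#' @return A `fit_result` with parameters `a_P`, `L_P`.
#' @export
fit_physical_porewater <- function(observations, config = inversion_config()) {
  observations <- check_profile_obs(observations)
  obs <- observations[observations$treatment %in%
                        c("defaunated", "nonbioturbated"), , drop = FALSE]
  if (!nrow(obs)) stop_invalid("no defaunated observations supplied")
  n_times <- length(unique(obs$day))
  n_depths <- length(unique(obs$depth_cm))
  if (n_times < 2 && n_depths < 6)
    stop_invalid("need >= 2 time points or >= 6 depth levels")
  if (nrow(obs) < 2) stop_invalid("underdetermined: fewer observations than parameters")
  lower <- c(config$bounds$a_P[1], config$bounds$L_P[1])
  upper <- c(config$bounds$a_P[2], config$bounds$L_P[2])
  objective <- make_porewater_objective(obs, config)
  if (sd(obs$value) == 0) {
    res <- objective(rep(0, config$grid$n_cells), 0)
    warning("observations carry no depth/time signal; a_P unidentifiable",
            call. = FALSE)
    return(fit_result(c(a_P = lower[1], L_P = mean(config$bounds$L_P)),
                      res$loss, FALSE, 1L, res$residuals,
                      list(lower = lower, upper = upper), config$seed,
                      flags = "no_signal"))
  }
  loss_fn <- function(theta) {
    ap <- profile_exponential(config$grid, theta[1], theta[2])
    objective(ap, 0)$loss
  }
  best <- multistart_minimize(loss_fn, lower, upper, config$n_starts,
                              config$seed)
  ap <- profile_exponential(config$grid, best$par[1], best$par[2])
  res <- objective(ap, 0)
  fit_result(c(a_P = best$par[1], L_P = best$par[2]), best$value,
             best$converged, best$n_evaluations, res$residuals,
             list(lower = lower, upper = upper), config$seed)
}

#' Fit lugworm bioirrigation from the refaunated treatment
#'
#' With the physical exchange `alpha_P(x)` held fixed at the defaunated
#' estimate, fits the bioirrigation window `alpha_B(x) = a_B` on
#' `[z1, z2]` (half-cosine edges) to refaunated porewater profiles.
#'
#' @inheritParams fit_physical_porewater
#' @param physical_fit the converged `fit_result` from
#'   [fit_physical_porewater()].
#' @return A `fit_result` with parameters `a_B`, `z1`, `z2`.
#' @export
fit_bioirrigation <- function(observations, physical_fit,
                              config = inversion_config()) {
  observations <- check_profile_obs(observations)
  stopifnot(inherits(physical_fit, "fit_result"))
  if (!physical_fit$converged && !("no_signal" %in% physical_fit$flags))
    stop_invalid("physical fit did not converge")
  obs <- observations[observations$treatment %in%
                        c("refaunated", "bioturbated"), , drop = FALSE]
  if (!nrow(obs)) stop_invalid("no refaunated observations supplied")
  if (nrow(obs) < 3) stop_invalid("underdetermined: fewer observations than parameters")
  alpha_p <- profile_exponential(config$grid, physical_fit$parameters["a_P"],
                                 physical_fit$parameters["L_P"])
  lower <- c(config$bounds$a_B[1], config$bounds$z1[1], config$bounds$width[1])
  upper <- c(config$bounds$a_B[2], config$bounds$z1[2], config$bounds$width[2])
  objective <- make_porewater_objective(obs, config)
  loss_fn <- function(theta) {
    ab <- profile_window(config$grid, theta[1], theta[2],
                         min(theta[2] + theta[3], config$grid$depth_max),
                         ramp = config$ramp)
    objective(alpha_p, ab)$loss
  }
  best <- multistart_minimize(loss_fn, lower, upper, config$n_starts,
                              child_seed(config$seed, 2))
  z2 <- min(best$par[2] + best$par[3], config$grid$depth_max)
  ab <- profile_window(config$grid, best$par[1], best$par[2], z2,
                       ramp = config$ramp)
  res <- objective(alpha_p, ab)
  fit_result(c(a_B = best$par[1], z1 = best$par[2], z2 = z2), best$value,
             best$converged, best$n_evaluations, res$residuals,
             list(lower = lower, upper = upper), config$seed)
}

pigment_loss <- function(observations, config, d_phys, d_bio) {
  grid <- config$grid
  pg <- config$pigments
  params <- transport_params(biodiffusion_physical = d_phys,
                             biodiffusion_biological = d_bio,
                             chl_decay = pg$k_chl, pheo_decay = pg$k_pheo,
                             chl_to_pheo_yield = pg$yield,
                             surface_chl_flux = pg$flux)
  st <- solve_pigments_steady(grid, params)
  model <- list(chl_a = st$chl_a, pheopigment = st$pheopigment)
  total <- 0
  resid_all <- numeric(0)
  for (an in c("chl_a", "pheopigment")) {
    obs <- observations[observations$analyte == an, ]
    if (!nrow(obs)) next
    w <- error_weights(obs$value, obs$value)
    pred <- approx(grid$cell_centers, model[[an]], xout = obs$depth_cm,
                   rule = 2)$y
    r <- pred - obs$value
    total <- total + sum(w * r^2)
    resid_all <- c(resid_all, r)
  }
  list(loss = total, residuals = resid_all)
}

#' Fit physical and biological particle mixing from pigment profiles
#'
#' Two-stage calibration of the biodiffusion model against steady chl-a and
#' pheopigment profiles: stage 1 fits the physical mixing profile
#' `D_P(x) = d_P exp(-x / L_DP)` to the nonbioturbated treatment; stage 2
#' holds it fixed and fits the biological window `D_B(x) = d_B` on
#' `[w1, w2]` to the bioturbated treatment.
#'
#' @param observations data frame with columns `analyte` (`"chl_a"` or
#'   `"pheopigment"`), `treatment` (`"nonbioturbated"` / `"bioturbated"`),
#'   `depth_cm`, `value`.
#' @param config an [inversion_config()].
#' @return A `fit_result` with parameters `d_P`, `L_DP`, `d_B`, `w1`, `w2`;
#'   the per-stage results are attached as `$stages`.
#' @export
fit_particle_mixing <- function(observations, config = inversion_config()) {
  observations <- check_profile_obs(
    observations, required = c("analyte", "treatment", "depth_cm", "value"))
  ctrl <- observations[observations$treatment == "nonbioturbated", ]
  bio <- observations[observations$treatment == "bioturbated", ]
  if (!nrow(ctrl) || !nrow(bio))
    stop_invalid("need both nonbioturbated and bioturbated pigment profiles")
  if (nrow(ctrl) < 2 || nrow(bio) < 3)
    stop_invalid("underdetermined: fewer observations than parameters")

  lower1 <- c(config$bounds$d_P[1], config$bounds$L_DP[1])
  upper1 <- c(config$bounds$d_P[2], config$bounds$L_DP[2])
  loss1 <- function(theta) {
    dp <- profile_exponential(config$grid, theta[1], theta[2])
    pigment_loss(ctrl, config, dp, 0)$loss
  }
  s1 <- multistart_minimize(loss1, lower1, upper1, config$n_starts,
                            child_seed(config$seed, 3))
  dp <- profile_exponential(config$grid, s1$par[1], s1$par[2])
  res1 <- pigment_loss(ctrl, config, dp, 0)
  stage1 <- fit_result(c(d_P = s1$par[1], L_DP = s1$par[2]), s1$value,
                       s1$converged, s1$n_evaluations, res1$residuals,
                       list(lower = lower1, upper = upper1), config$seed)

  lower2 <- c(config$bounds$d_B[1], config$bounds$w1[1], config$bounds$wwidth[1])
  upper2 <- c(config$bounds$d_B[2], config$bounds$w1[2], config$bounds$wwidth[2])
  loss2 <- function(theta) {
    db <- profile_window(config$grid, theta[1], theta[2],
                         min(theta[2] + theta[3], config$grid$depth_max),
                         ramp = config$ramp)
    pigment_loss(bio, config, dp, db)$loss
  }
  s2 <- multistart_minimize(loss2, lower2, upper2, config$n_starts,
                            child_seed(config$seed, 4))
  w2 <- min(s2$par[2] + s2$par[3], config$grid$depth_max)
  db <- profile_window(config$grid, s2$par[1], s2$par[2], w2, ramp = config$ramp)
  res2 <- pigment_loss(bio, config, dp, db)
  stage2 <- fit_result(c(d_B = s2$par[1], w1 = s2$par[2], w2 = w2), s2$value,
                       s2$converged, s2$n_evaluations, res2$residuals,
                       list(lower = lower2, upper = upper2), config$seed)

  out <- fit_result(c(stage1$parameters, stage2$parameters), stage2$loss,
                    stage1$converged && stage2$converged,
                    stage1$n_evaluations + stage2$n_evaluations,
                    c(res1$residuals, res2$residuals),
                    list(stage1 = stage1$bounds, stage2 = stage2$bounds),
                    config$seed)
  out$stages <- list(physical = stage1, biological = stage2)
  out
}

#' Lugworm feeding intensity from sand fractions
#'
#' Per-depth difference in sand volume fraction between bioturbated and
#' nonbioturbated (control) sediment, `F_B(x) = f_sand(x) - f'_sand(x)`; a
#' proxy for selective ingestion of fine particles (positive where coarse
#' sand is enriched by worm feeding).  The control profile is linearly
#' interpolated to the bioturbated depths first.
#'
#' @param sand_bioturbated,sand_control data frames with columns `depth_cm`
#'   and `fraction` (volume fractions in `[0, 1]`).
#' @return Data frame with `depth_cm` and `F_B` (in `[-1, 1]`).
#' @export
feeding_intensity <- function(sand_bioturbated, sand_control) {
  for (d in list(sand_bioturbated, sand_control)) {
    if (!all(c("depth_cm", "fraction") %in% names(d)))
      stop_invalid("sand profiles need `depth_cm` and `fraction` columns")
    if (any(!is.finite(d$fraction)) || any(d$fraction < 0) ||
        any(d$fraction > 1))
      stop_invalid("sand fractions must lie in [0, 1]")
  }
  ctrl <- if (nrow(sand_control) == 1) rep(sand_control$fraction,
                                           nrow(sand_bioturbated))
  else approx(sand_control$depth_cm, sand_control$fraction,
              xout = sand_bioturbated$depth_cm, rule = 2, ties = mean)$y
  data.frame(depth_cm = sand_bioturbated$depth_cm,
             F_B = sand_bioturbated$fraction - ctrl)
}
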
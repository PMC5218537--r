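# Synthetic data generators: Gompertz-mortality lifespan cohorts matching a
# whole-life dietary trial design, and noisy Hill concentration-response
# datasets. All generators are pure functions of (configuration, seed).

#' Gompertz mortality parameters
#'
#' Hazard `h(t) = a * exp(b * t)` per day; survival
#' `S(t) = exp(-(a/b) (exp(b t) - 1))`. Treatment effects act as proportional
#' multipliers on the hazard.
#'
#' @param a Baseline hazard per day (`> 0`).
#' @param b Hazard growth rate per day (`> 0`).
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("Gompertz parameters must be positive")
  }
  structure(list(a = a, b = b), class = "gompertz_params")
}

#' Analytic mean lifespan under Gompertz mortality
#'
#' Integrates `S(t) = exp(-(k a / b)(exp(b t) - 1))` over `t >= 0` by adaptive
#' quadrature; `multiplier` scales the hazard proportionally.
#'
#' @param params A [gompertz_params].
#' @param multiplier Proportional hazard multiplier (`> 0`, 1 = baseline).
#' @return Mean lifespan in days.
#' @export
gompertz_mean <- function(params, multiplier = 1) {
  stopifnot(inherits(params, "gompertz_params"), multiplier > 0)
  a <- params$a * multiplier; b <- params$b
  surv <- function(t) exp(-(a / b) * expm1(b * t))
  # S(t) decays doubly exponentially; integrate to where it is below 1e-18
  t_max <- log1p(41.5 * b / a) / b
  stats::integrate(surv, 0, t_max, rel.tol = 1e-10, subdivisions = 500L)$value
}

#' Calibrate the baseline hazard to a target mean lifespan
#'
#' Solves for `a` such that the analytic Gompertz mean equals `target_mean`
#' within 0.5 day, with `b` held fixed. The root is bracketed on a log10(a)
#' grid and refined numerically.
#'
#' @param target_mean Target mean lifespan in days (`> 0`).
#' @param b Hazard growth rate per day.
#' @return A [gompertz_params] with the calibrated `a`.
#' @examples
#' p <- calibrate_gompertz(886, b = 0.006)
#' gompertz_mean(p)  # ~886
#' @export
calibrate_gompertz <- function(target_mean, b = 0.006) {
  if (target_mean <= 0 || b <= 0) stop("target_mean and b must be positive")
  f <- function(log10_a) gompertz_mean(gompertz_params(10^log10_a, b)) - target_mean
  lo <- -14; hi <- 2
  if (f(lo) < 0 || f(hi) > 0) stop("no bracketing interval for the hazard solve")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  out <- gompertz_params(10^root, b)
  if (abs(gompertz_mean(out) - target_mean) > 0.5) stop("hazard calibration did not converge")
  out
}

#' Hazard multiplier achieving a target mean lifespan
#'
#' Given baseline Gompertz parameters, solves for the proportional-hazard
#' multiplier whose analytic mean equals `target_mean` (larger multipliers
#' shorten life).
#'
#' @param target_mean Target group mean lifespan in days.
#' @param params Baseline [gompertz_params].
#' @return The multiplier (`> 0`).
#' @export
multiplier_for_mean <- function(target_mean, params) {
  stopifnot(inherits(params, "gompertz_params"), target_mean > 0)
  f <- function(logk) gompertz_mean(params, exp(logk)) - target_mean
  if (f(-12) < 0 || f(12) > 0) stop("target mean outside attainable range")
  exp(stats::uniroot(f, c(-12, 12), tol = 1e-10)$root)
}

#' Sample integer-day lifespans from a Gompertz law
#'
#' Inverse-CDF sampling: with hazard multiplier `k`,
#' `T = (1/b) log(1 - (b / (k a)) log U)`, `U ~ Uniform(0, 1)`; values are
#' rounded to the nearest day and floored at 1 to match the inference grid.
#'
#' @param params A [gompertz_params].
#' @param n Number of animals (`>= 1`).
#' @param multiplier Proportional hazard multiplier (`> 0`).
#' @param seed Integer seed; required.
#' @return Integer vector of `n` lifespans in days.
#' @export
sample_gompertz <- function(params, n, multiplier = 1, seed) {
  stopifnot(inherits(params, "gompertz_params"))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n < 1) stop("n must be >= 1")
  if (multiplier <= 0) stop("multiplier must be positive")
  set.seed(seed)
  u <- stats::runif(n)
  a <- params$a * multiplier; b <- params$b
  t <- log1p(-(b / a) * log(u)) / b
  pmax(1L, as.integer(round(t)))
}

# deterministic per-group/per-stream seed split from one master seed
split_seed <- function(seed, index) {
  as.integer((as.double(seed) * 131071 + 7919 * index) %% 2147483647)
}

#' Trial configuration for a synthetic whole-life cohort study
#'
#' @param gompertz Baseline [gompertz_params] (control mortality).
#' @param groups Data frame with columns `label`, `n`, `multiplier` (unique
#'   labels, `n >= 1`, multipliers `> 0`).
#' @param seed Master integer seed (mandatory; split deterministically per
#'   group).
#' @param censor_horizon_days Optional administrative censoring horizon.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(gompertz, groups, seed, censor_horizon_days = NULL) {
  stopifnot(inherits(gompertz, "gompertz_params"), is.data.frame(groups),
            all(c("label", "n", "multiplier") %in% names(groups)))
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (anyDuplicated(groups$label)) stop("group labels must be unique")
  if (any(groups$n < 1) || any(groups$multiplier <= 0)) stop("invalid group spec")
  structure(
    list(gompertz = gompertz, groups = groups, seed = as.integer(seed),
         censor_horizon_days = censor_horizon_days),
    class = "trial_config"
  )
}

#' Default whole-life trial design
#'
#' Mirrors the study design the package targets: a large control cohort
#' (n = 335, mean lifespan 886 days), dietary restriction (n = 60, mean 125%
#' of control), three Mg-supplemented groups (n = 15 each, mean 110% of
#' control), and a CaCl2 group (n = 15, no effect). Hazard multipliers are
#' solved from the analytic Gompertz mean rather than set ad hoc.
#'
#' @param seed Master integer seed.
#' @param control_mean Control mean lifespan in days (default 886).
#' @param b Gompertz rate per day (default 0.006).
#' @return A [trial_config].
#' @export
default_trial_config <- function(seed, control_mean = 886, b = 0.006) {
  gp <- calibrate_gompertz(control_mean, b = b)
  mult_dr <- multiplier_for_mean(1.25 * control_mean, gp)
  mult_mg <- multiplier_for_mean(1.10 * control_mean, gp)
  groups <- data.frame(
    label = c("Control", "DR", "MgAc", "MgOH", "MgCl2", "CaCl2"),
    n = c(335L, 60L, 15L, 15L, 15L, 15L),
    multiplier = c(1, mult_dr, mult_mg, mult_mg, mult_mg, 1),
    stringsAsFactors = FALSE
  )
  trial_config(gp, groups, seed = seed)
}

#' Simulate a whole-life trial
#'
#' Draws one Gompertz cohort per group (seed split deterministically per
#' group), optionally right-censoring at the administrative horizon.
#'
#' @param config A [trial_config].
#' @return A [cohort_table] with one row per animal.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  g <- config$groups
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    times <- sample_gompertz(config$gompertz, g$n[i], g$multiplier[i],
                             seed = split_seed(config$seed, i))
    event <- rep(1L, g$n[i])
    if (!is.null(config$censor_horizon_days)) {
      cens <- times > config$censor_horizon_days
      times[cens] <- config$censor_horizon_days
      event[cens] <- 0L
    }
    rows[[i]] <- data.frame(
      subject_id = sprintf("%s_%03d", g$label[i], seq_len(g$n[i])),
      group = g$label[i], time = times, event = event,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  cohort_table(tab$subject_id, tab$group, tab$time, tab$event)
}

#' Simulate a noisy Hill concentration-response dataset
#'
#' Each of `n_cells` cells is measured at every concentration; responses are
#' the Hill curve plus i.i.d. Gaussian noise (homoscedastic, a stand-in for
#' unreported patch-clamp variability).
#'
#' @param params Generating [hill_params].
#' @param concentrations Concentrations in mM (non-empty, `>= 0`).
#' @param n_cells Number of cells (`>= 1`).
#' @param noise_sd Gaussian noise SD in response units; default 3% of
#'   `emax - emin`.
#' @param seed Integer seed; required.
#' @param group Group label for the output table.
#' @return Data frame with columns `group`, `cell_id`, `concentration_mM`,
#'   `response_pApF`.
#' @export
simulate_dose_response <- function(params, concentrations, n_cells,
                                   noise_sd = 0.03 * (params$emax - params$emin),
                                   seed, group = "group1") {
  stopifnot(inherits(params, "hill_params"))
  if (length(concentrations) == 0L) stop("concentration list must be non-empty")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  grid <- expand.grid(cell = seq_len(n_cells), conc = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  resp <- hill_response(params, grid$conc) + stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(
    group = group,
    cell_id = sprintf("cell_%02d", grid$cell),
    concentration_mM = grid$conc,
    response_pApF = resp,
    stringsAsFactors = FALSE
  )
}

#' Reference Hill parameter presets for TS-cell current block
#'
#' Four presets for TRPM6/M7-like current inhibition by intracellular MgATP
#' and free Mg2+ in wild-type and Trpm6-deficient cells. IC50 (mM) and Hill
#' slope follow the reported concentration-response fits
#' (MgATP: 3.17 mM / -1.81 wild type, 1.45 mM / -1.95 mutant;
#' free Mg2+: 0.60 mM / -1.14 wild type, 0.72 mM / -1.18 mutant).
#' Emin/Emax (pA/pF at +80 mV) are synthetic: raw per-cell current densities
#' are not published, so Emin is set to 0 (complete block) and Emax to
#' plausible magnitudes with the mutant currents smaller than wild type.
#' Each preset carries a default concentration panel spanning its transition.
#'
#' @return Named list (`wt_mgatp`, `mut_mgatp`, `wt_free_mg`, `mut_free_mg`);
#'   each element has `$params` ([hill_params]) and `$concentrations` (mM).
#' @export
hill_presets <- function() {
  conc_mgatp <- c(0, 0.5, 1, 2, 3, 4, 6, 10)
  conc_mg <- c(0, 0.1, 0.2, 0.4, 0.8, 1.5, 3, 6)
  list(
    wt_mgatp = list(params = hill_params(0, 45, ic50 = 3.17, h = -1.81),
                    concentrations = conc_mgatp),
    mut_mgatp = list(params = hill_params(0, 18, ic50 = 1.45, h = -1.95),
                     concentrations = conc_mgatp),
    wt_free_mg = list(params = hill_params(0, 45, ic50 = 0.60, h = -1.14),
                      concentrations = conc_mg),
    mut_free_mg = list(params = hill_params(0, 18, ic50 = 0.72, h = -1.18),
                       concentrations = conc_mg)
  )
}
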
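# Hill-equation concentration-response analysis for whole-cell current block
# by intracellular Mg2+ / MgATP, and nested-model curve comparison by the
# extra sum-of-squares F test.
#
# The response model is the four-parameter Hill curve with the concentration
# entering the base-10 exponent on the linear mM scale:
#
#   E(C) = Emin + (Emax - Emin) / (1 + 10^((IC50 - C) * h))
#
# For inhibition data h < 0, so E falls from ~Emax at low inhibitor toward
# Emin at high inhibitor, with E(IC50) = (Emin + Emax) / 2 exactly.

#' Hill curve parameters
#'
#' @param emin Minimal effect/current (response units, e.g. pA/pF).
#' @param emax Maximally achievable effect; `emax >= emin` as oriented here.
#' @param ic50 Half-maximal concentration in mM (`> 0`).
#' @param h Hill slope factor (dimensionless; negative for inhibition).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(emin, emax, ic50, h) {
  stopifnot(is.finite(emin), is.finite(emax), is.finite(ic50), is.finite(h))
  if (ic50 <= 0) stop("ic50 must be positive")
  if (emax < emin) stop("emax must be >= emin")
  structure(list(emin = emin, emax = emax, ic50 = ic50, h = h),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: Emin = %.4g, Emax = %.4g, IC50 = %.4g mM, h = %.4g\n",
              x$emin, x$emax, x$ic50, x$h))
  invisible(x)
}

#' Evaluate the Hill inhibition curve
#'
#' @param params A [hill_params] object.
#' @param conc Concentration(s) in mM (`>= 0`); the formula is finite at 0.
#' @return Response at each concentration. The base-10 exponent is clamped to
#'   +/-300 to guard overflow at extreme concentrations.
#' @examples
#' p <- hill_params(0, 100, ic50 = 1, h = -1)
#' hill_response(p, c(0, 1, 2))  # 90.909..., 50, 9.0909...
#' @export
hill_response <- function(params, conc) {
  stopifnot(inherits(params, "hill_params"), all(conc >= 0))
  # evaluated from IC50 directly (no log10 round trip) so E(IC50) is the
  # exact midpoint
  expo <- pmin(pmax((params$ic50 - conc) * params$h, -300), 300)
  params$emin + (params$emax - params$emin) / (1 + 10^expo)
}

# internal evaluation on the optimizer scale: theta = (emin, emax, lic50, h)
hill_eval <- function(theta, conc) {
  expo <- (10^theta[3] - conc) * theta[4]
  expo <- pmin(pmax(expo, -300), 300)
  theta[1] + (theta[2] - theta[1]) / (1 + 10^expo)
}

# one nls.lm run from a given start; returns NULL on failure
hill_lm_once <- function(start_free, free, fixed_theta, conc, resp) {
  resid_fn <- function(par) {
    th <- fixed_theta
    th[free] <- par
    resp - hill_eval(th, conc)
  }
  fit <- tryCatch(
    quiet_lm(
      par = start_free, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-13, gtol = 0, maxiter = 500, maxfev = 5000
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(par = fit$par, rss = sum(resid_fn(fit$par)^2), fit = fit)
}

# nls.lm, with the routine iteration-cap warning muffled: a restart that stops
# at the cap still yields a candidate whose residual SS competes with the
# other starts
quiet_lm <- function(...) {
  withCallingHandlers(
    minpack.lm::nls.lm(...),
    warning = function(w) {
      if (grepl("maxiter|iterations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Fit the Hill curve by nonlinear least squares
#'
#' Minimizes the residual sum of squares of [hill_response] over the four
#' parameters (or any free subset). IC50 is optimized as log10(IC50) to
#' enforce positivity and condition the problem; results are reported on the
#' mM scale. A data-driven start (Emax = max response, Emin = min response,
#' IC50 = concentration nearest the half-maximal response, h = -1) is used
#' together with two perturbed restarts (IC50 x3 and /3); the best residual
#' sum of squares wins.
#'
#' @param conc Concentrations in mM; at least 5 points spanning a >= 3-fold
#'   range of positive concentrations.
#' @param response Observed responses (same length as `conc`).
#' @param fixed Optional named list fixing a subset of `emin`, `emax`, `ic50`,
#'   `h` at given values.
#' @return A `hill_fit` object: `params` ([hill_params]), `se` (asymptotic
#'   standard errors, NA for fixed parameters), `rss`, `df`
#'   (`n - n_free`), `n`, `fitted`.
#' @export
fit_hill <- function(conc, response, fixed = list()) {
  stopifnot(length(conc) == length(response), all(is.finite(conc)),
            all(is.finite(response)), all(conc >= 0))
  if (length(conc) < 5L) stop("underdetermined: need at least 5 points")
  pos <- conc[conc > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 3) {
    stop("insufficient concentration range (need >= 3-fold span)")
  }
  par_names <- c("emin", "emax", "ic50", "h")
  if (length(fixed) && !all(names(fixed) %in% par_names)) stop("unknown fixed parameter")
  free_names <- setdiff(par_names, names(fixed))
  if (length(free_names) == 0L) stop("no free parameters")
  if (length(conc) < length(free_names) + 1L) stop("underdetermined")

  # theta scale: (emin, emax, log10 ic50, h)
  fixed_theta <- rep(NA_real_, 4L)
  for (nm in names(fixed)) {
    v <- fixed[[nm]]
    fixed_theta[match(nm, par_names)] <- if (nm == "ic50") log10(v) else v
  }
  free <- which(is.na(fixed_theta))

  emax0 <- max(response); emin0 <- min(response)
  mid <- (emax0 + emin0) / 2
  cand <- conc[conc > 0]
  ic50_0 <- cand[which.min(abs(response[conc > 0] - mid))]
  if (!length(ic50_0) || ic50_0 <= 0) ic50_0 <- stats::median(pos)
  starts <- lapply(c(1, 3, 1 / 3), function(f) {
    c(emin0, emax0, log10(ic50_0 * f), -1)[free]
  })

  best <- NULL
  for (st in starts) {
    res <- hill_lm_once(st, free, fixed_theta, conc, response)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  if (is.null(best)) stop("fit failed")

  theta <- fixed_theta
  theta[free] <- best$par
  n <- length(conc)
  df <- n - length(free)
  # asymptotic SEs from the Jacobian at the optimum, delta method for IC50
  se_theta <- rep(NA_real_, 4L)
  if (df >= 1 && best$rss > 0) {
    jac <- tryCatch({
      h_ <- 1e-6
      sapply(seq_along(free), function(j) {
        tp <- theta; tm <- theta
        step <- h_ * max(1, abs(theta[free[j]]))
        tp[free[j]] <- tp[free[j]] + step
        tm[free[j]] <- tm[free[j]] - step
        (hill_eval(tp, conc) - hill_eval(tm, conc)) / (2 * step)
      })
    }, error = function(e) NULL)
    if (!is.null(jac)) {
      xtx <- crossprod(jac)
      cov_free <- tryCatch(solve(xtx) * best$rss / df, error = function(e) NULL)
      if (!is.null(cov_free)) se_theta[free] <- sqrt(pmax(diag(cov_free), 0))
    }
  }
  ic50 <- 10^theta[3]
  se <- c(
    emin = se_theta[1], emax = se_theta[2],
    ic50 = if (is.na(se_theta[3])) NA_real_ else log(10) * ic50 * se_theta[3],
    h = se_theta[4]
  )
  params <- hill_params(min(theta[1], theta[2]), max(theta[1], theta[2]),
                        ic50, theta[4])
  structure(
    list(params = params, se = se, rss = best$rss, df = df, n = n,
         fitted = hill_eval(theta, conc), free = par_names[free]),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill nonlinear least-squares fit\n")
  cat(sprintf("  IC50 = %.4g mM (SE %.3g), h = %.4g (SE %.3g)\n",
              x$params$ic50, x$se[["ic50"]], x$params$h, x$se[["h"]]))
  cat(sprintf("  Emin = %.4g, Emax = %.4g\n", x$params$emin, x$params$emax))
  cat(sprintf("  residual SS = %.6g on %d df (n = %d)\n", x$rss, x$df, x$n))
  invisible(x)
}

#' Compare two concentration-response datasets by the extra sum-of-squares F test
#'
#' The full model fits each dataset with its own four Hill parameters
#' (8 parameters; `SS_full = SS_A + SS_B`). The null model constrains them:
#' `"all-shared"` fits one four-parameter curve to the pooled data, while
#' `"ic50-and-slope-shared"` shares IC50 and the Hill slope but keeps separate
#' Emin/Emax per dataset (6 parameters). The F statistic
#' `((SS_null - SS_full) / (df_null - df_full)) / (SS_full / df_full)`
#' is referred to the F distribution; small p rejects a common curve.
#'
#' @param concA,responseA First dataset.
#' @param concB,responseB Second dataset.
#' @param mode `"all-shared"` (default) or `"ic50-and-slope-shared"`.
#' @return A `curve_comparison` object: `F`, `df_num`, `df_den`, `p_value`,
#'   `mode`, `ss_null`, `ss_full`, the per-group fits, and `degenerate`
#'   (TRUE when `SS_full` is exactly 0 so p is reported at the machine floor).
#' @export
compare_curves <- function(concA, responseA, concB, responseB,
                           mode = c("all-shared", "ic50-and-slope-shared")) {
  mode <- match.arg(mode)
  fitA <- fit_hill(concA, responseA)
  fitB <- fit_hill(concB, responseB)
  nA <- length(concA); nB <- length(concB)
  ss_full <- fitA$rss + fitB$rss
  df_full <- nA + nB - 8L

  if (mode == "all-shared") {
    fit0 <- fit_hill(c(concA, concB), c(responseA, responseB))
    ss_null <- fit0$rss
    df_null <- nA + nB - 4L
  } else {
    fit0 <- fit_shared_ic50_h(concA, responseA, concB, responseB, fitA, fitB)
    ss_null <- fit0$rss
    df_null <- nA + nB - 6L
  }

  if (ss_null < ss_full * (1 - 1e-9) - 1e-12) {
    stop("nested-model misfit: SS_null < SS_full signals an optimizer failure")
  }
  degenerate <- FALSE
  if (ss_full <= 0) {
    if (ss_null > 0) {
      degenerate <- TRUE
      f_stat <- Inf
      p <- .Machine$double.xmin
    } else {
      f_stat <- 0; p <- 1
    }
  } else {
    f_stat <- max(0, (ss_null - ss_full) / (df_null - df_full)) / (ss_full / df_full)
    p <- stats::pf(f_stat, df_null - df_full, df_full, lower.tail = FALSE)
  }
  structure(
    list(F = f_stat, df_num = df_null - df_full, df_den = df_full,
         p_value = p, mode = mode, ss_null = ss_null, ss_full = ss_full,
         fitA = fitA, fitB = fitB, fit_null = fit0, degenerate = degenerate),
    class = "curve_comparison"
  )
}

# Null model with shared log10(IC50) and h, separate Emin/Emax per dataset.
# theta = (eminA, emaxA, eminB, emaxB, lic50, h); started from per-group fits.
fit_shared_ic50_h <- function(concA, responseA, concB, responseB, fitA, fitB) {
  resid_fn <- function(par) {
    rA <- responseA - hill_eval(c(par[1], par[2], par[5], par[6]), concA)
    rB <- responseB - hill_eval(c(par[3], par[4], par[5], par[6]), concB)
    c(rA, rB)
  }
  lic50_0 <- log10(sqrt(fitA$params$ic50 * fitB$params$ic50))
  h0 <- (fitA$params$h + fitB$params$h) / 2
  start <- c(fitA$params$emin, fitA$params$emax,
             fitB$params$emin, fitB$params$emax, lic50_0, h0)
  best <- NULL
  for (f in c(1, 3, 1 / 3)) {
    st <- start; st[5] <- st[5] + log10(f)
    fit <- tryCatch(
      quiet_lm(
        par = st, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-15, ptol = 1e-13, gtol = 0, maxiter = 500, maxfev = 5000
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("fit failed")
  best
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("Extra sum-of-squares F test (%s null)\n", x$mode))
  cat(sprintf("  F(%d, %d) = %.4f, p = %.4g%s\n", x$df_num, x$df_den, x$F,
              x$p_value, if (x$degenerate) " [degenerate: SS_full = 0]" else ""))
  cat(sprintf("  SS_null = %.6g, SS_full = %.6g\n", x$ss_null, x$ss_full))
  cat(sprintf("  IC50: %.4g vs %.4g mM; h: %.4g vs %.4g\n",
              x$fitA$params$ic50, x$fitB$params$ic50,
              x$fitA$params$h, x$fitB$params$h))
  invisible(x)
}
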
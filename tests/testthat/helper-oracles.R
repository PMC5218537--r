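# Independent oracles used across the suite. These deliberately avoid the
# code paths they validate: sums of i.i.d. draws are enumerated over all
# ordered with-replacement tuples, and Hill fits are cross-checked against a
# dense grid search with analytic linear sub-fits.

# pmf of the sum of n i.i.d. draws from the empirical distribution of
# `values`, by full enumeration over all length(values)^n ordered tuples.
enum_sum_pmf <- function(values, n) {
  tuples <- expand.grid(rep(list(values), n), KEEP.OUT.ATTRS = FALSE)
  sums <- rowSums(tuples)
  tab <- table(sums)
  list(sum = as.numeric(names(tab)), prob = as.numeric(tab) / length(sums))
}

# exact directional mean-test p-value by enumeration
enum_mean_test_p <- function(control, treated_mean, n) {
  mu <- mean(control)
  if (treated_mean == mu) return(1)
  o <- enum_sum_pmf(control, n)
  total <- treated_mean * n
  if (treated_mean > mu) sum(o$prob[o$sum >= total - 1e-9])
  else sum(o$prob[o$sum <= total + 1e-9])
}

# dense grid search over (log10 IC50, h) with Emin/Emax solved analytically
# by linear least squares at each node; returns the best node
grid_hill_fit <- function(conc, resp, lic50_range, h_range, n_grid = 121) {
  lic50s <- seq(lic50_range[1], lic50_range[2], length.out = n_grid)
  hs <- seq(h_range[1], h_range[2], length.out = n_grid)
  best <- list(rss = Inf)
  for (l in lic50s) {
    for (h in hs) {
      w <- 1 / (1 + 10^pmin(pmax((10^l - conc) * h, -300), 300))
      # E = emin + (emax - emin) * w  ==  alpha + beta * w
      fit <- stats::lm.fit(cbind(1, w), resp)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(rss = rss, ic50 = 10^l, h = h,
                     emin = fit$coefficients[1],
                     emax = fit$coefficients[1] + fit$coefficients[2])
      }
    }
  }
  best
}

# concentration panel guaranteed informative for (ic50, h): points across the
# transition (width ~ 1/|h| mM for this linear-concentration Hill form) plus
# anchors near zero and deep saturation so the >= 3-fold span always holds
informative_conc <- function(ic50, h) {
  sort(unique(c(0, ic50 / 10, 4 * ic50,
                pmax(0, ic50 + (1 / abs(h)) * c(-4, -2, -1, -0.5, 0, 0.5, 1, 2, 4)))))
}

# small random pmf on an integer grid, for property-style loops
random_ddist <- function(n_points, origin = sample(0:20, 1)) {
  w <- stats::rexp(n_points)
  ddist(w / sum(w), origin = origin)
}

# Gompertz-like control cohort shared by several tests
make_control_cohort <- function(n = 335, seed = 99, mean_days = 886) {
  sample_gompertz(calibrate_gompertz(mean_days, b = 0.006), n, 1, seed = seed)
}
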
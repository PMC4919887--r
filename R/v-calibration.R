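# Finite-window null calibration of the normalized-variance statistic.
#
# The population value of 4*Var(R2)/mean(R2)^2 is exactly 2 for 2D free
# diffusion, but the windowed plug-in estimator (unbiased sample variance of
# n two-term-averaged R2 values divided by the squared window mean) is
# biased low by O(1/n): the ratio bias and the lag-1 autocorrelation that
# the shared middle displacement induces between consecutive R2 values do
# not cancel. kappa(n) = 2 / E_null[raw estimator] restores expectation 2
# under the free-diffusion null. The null distribution of the raw estimator
# is scale-free (R2 values are chi-squared up to a common factor), so kappa
# depends only on n. Table generated once by data-raw/v_calibration.R
# (4e5-8e5 replicates per n; Monte-Carlo error in kappa < 0.1%).
.v_calib_table <- data.frame(
  n = c(4, 5, 6, 8, 10, 13, 16, 20, 26, 33, 38, 48, 60, 78,
        100, 140, 198, 298, 498, 998),
  kappa = c(1.53170, 1.42727, 1.35646, 1.26322, 1.20882, 1.16191, 1.12963,
            1.10312, 1.07844, 1.06121, 1.05350, 1.04322, 1.03379, 1.02641,
            1.01997, 1.01441, 1.00976, 1.00629, 1.00420, 1.00168)
)

#' Finite-window calibration factor for the V statistic
#'
#' Multiplicative factor applied by [normalized_variance()] so that the
#' windowed V estimator has expectation exactly 2 under 2D free diffusion
#' for any diffusion coefficient. Interpolated linearly in 1/n from a
#' frozen Monte-Carlo table (asymptotically `kappa ~ 1 + 2/n`).
#'
#' @param n number of R2 values in the window (>= 4).
#' @return calibration factor(s), >= 1.
#' @export
v_calibration_factor <- function(n) {
  if (any(n < 4)) stop("window too short: need at least 4 R2 values", call. = FALSE)
  x <- c(0, rev(1 / .v_calib_table$n))
  y <- c(1, rev(.v_calib_table$kappa))
  approx(x, y, xout = 1 / n, rule = 2)$y
}
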
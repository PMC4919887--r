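## Generates the finite-window null-calibration table for the normalized
## variance statistic V. Under 2D free diffusion the population value of
## 4*Var(R2)/mean(R2)^2 is exactly 2, but the windowed plug-in estimator
## (unbiased sample variance over n overlapping two-term-averaged R2 values)
## is biased low by O(1/n). kappa(n) = 2 / E_null[raw V] restores E[V] = 2.
## The null is scale-free, so kappa depends only on n.
## Output is pasted into R/v-calibration.R as .v_calib_table.
set.seed(20260901)
mean_raw_v <- function(n, reps) {
  tot <- 0; cnt <- 0; chunk <- max(1, floor(2e7 / (n + 1)))
  while (cnt < reps) {
    m <- min(chunk, reps - cnt)
    E <- matrix(rchisq(m * (n + 1), df = 2), m, n + 1)
    R2 <- (E[, 1:n, drop = FALSE] + E[, 2:(n + 1), drop = FALSE]) / 2
    mu <- rowMeans(R2)
    v  <- rowSums((R2 - mu)^2) / (n - 1)
    tot <- tot + sum(4 * v / mu^2); cnt <- cnt + m
  }
  tot / reps
}
ns <- c(4, 5, 6, 8, 10, 13, 16, 20, 26, 33, 38, 48, 60, 78, 100, 140, 198, 298, 498, 998)
reps <- ifelse(ns <= 60, 4e5, ifelse(ns <= 200, 2e5, 1e5))
kap <- numeric(length(ns))
for (i in seq_along(ns)) {
  m <- mean_raw_v(ns[i], reps[i])
  kap[i] <- 2 / m
  cat(sprintf("n=%4d  E[rawV]=%.5f  kappa=%.5f\n", ns[i], m, kap[i]))
}
cat("\n.v_calib_table <- data.frame(\n  n = c(", paste(ns, collapse = ", "), "),\n  kappa = c(",
    paste(sprintf("%.5f", kap), collapse = ", "), ")\n)\n")
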
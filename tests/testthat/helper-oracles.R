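# From-scratch recomputation of the moving z-score: for every index i the
# window statistics (mean, population SD) are recomputed directly from the
# retained samples, independent of the streaming path.
oracle_stress <- function(f, cap, warm_n, sd_floor = 1e-9) {
  vapply(seq_along(f), function(i) {
    if (i - 1 < warm_n) return(NA_real_)
    w <- f[max(1, i - cap + 1):i]
    m <- mean(w)
    sd_p <- sqrt(mean((w - m)^2))
    (f[i] - m) / max(sd_p, sd_floor)
  }, numeric(1))
}

# Textbook one-way ANOVA F and planned-contrast t (adaptive vs the mean of
# the two controls) computed from group summaries.
oracle_contrast <- function(tab, outcome) {
  y <- tab[[outcome]]
  g <- factor(tab$condition,
              levels = c("control_constant", "control_time",
                         "stress_adaptive"))
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  fit <- aov(y ~ g)
  ms <- summary(fit)[[1]]
  mse <- ms["Residuals", "Mean Sq"]
  L <- means[["stress_adaptive"]] -
    (means[["control_constant"]] + means[["control_time"]]) / 2
  se <- sqrt(mse * (1 / ns[["stress_adaptive"]] +
                      0.25 / ns[["control_constant"]] +
                      0.25 / ns[["control_time"]]))
  list(f = ms["g", "F value"], t = L / se, estimate = L)
}

# Shorthand: condition means of an experiment's outcome table.
condition_means <- function(outcomes, col) {
  tapply(outcomes[[col]], outcomes$condition, mean, na.rm = TRUE)
}
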
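# Independent oracles used across tests. These deliberately take different
# routes from the package implementation.

# A fast small phantom spec for tests that do not need the full default
# field of view.
small_phantom_spec <- function(...) {
  phantom_spec(image_size = 128L, pixel_spacing = 3, ...)
}

# Exhaustive Wilcoxon signed-rank oracle: enumerate all 2^n sign
# assignments of the observed ranks and compute the two-sided p directly.
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  wplus <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  lower <- mean(wplus <= w_obs)
  upper <- mean(wplus >= w_obs)
  min(1, 2 * min(lower, upper))
}

# ICC(3,1) oracle through stats::aov on the long two-way layout.
icc31_aov_oracle <- function(pre, post) {
  n <- length(pre)
  df <- data.frame(y = c(pre, post),
                   subject = factor(rep(seq_len(n), 2)),
                   occasion = factor(rep(1:2, each = n)))
  tab <- anova(stats::aov(y ~ subject + occasion, data = df))
  msb <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msb - mse) / (msb + mse)
}

# Per-pixel brute-force segmentation: double loop over pixels and scheme
# rows, no vectorization shared with the implementation.
segment_brute_force <- function(hu, comp, scheme) {
  comp_codes <- c(subcutaneous = 1L, muscular = 2L, visceral = 3L)
  out <- matrix(0L, nrow(hu), ncol(hu))
  for (i in seq_len(nrow(hu))) {
    for (j in seq_len(ncol(hu))) {
      for (s in seq_len(nrow(scheme))) {
        if (comp[i, j] == comp_codes[[scheme$compartment[s]]] &&
            hu[i, j] >= scheme$lo[s] && hu[i, j] <= scheme$hi[s]) {
          out[i, j] <- match(scheme$tissue[s], TISSUE_CLASSES)
          break
        }
      }
    }
  }
  out
}
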
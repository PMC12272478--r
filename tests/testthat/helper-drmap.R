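# Shared fixtures: analytic dose fields on small grids, and a compact
# grade-table constructor. Everything is generated in code.

# Dose grid from a closed-form field f(z, y, x), covering [-lim, lim]^3.
field_grid <- function(f, lim, h) {
  ax <- seq(-lim, lim, by = h)
  n <- length(ax)
  vals <- array(0, c(n, n, n))
  yy <- rep(ax, times = n); xx <- rep(ax, each = n)
  for (k in seq_len(n))
    vals[k, , ] <- f(ax[k], yy, xx)
  dose_grid(vals, spacing = c(h, h, h), origin = c(-lim, -lim, -lim))
}

uniform_grid <- function(value, lim, h) {
  field_grid(function(z, y, x) value, lim, h)
}

# One grade-table row per triple; triples given as a list of
# c(baseline, g12, g24) (NA allowed).
grade_table <- function(triples, endpoint = "urinary_incontinence") {
  do.call(rbind, lapply(seq_along(triples), function(i) {
    t3 <- triples[[i]]
    data.frame(patient_id = i, endpoint = endpoint,
               grade_baseline = t3[1], grade_12m = t3[2], grade_24m = t3[3],
               stringsAsFactors = FALSE)
  }))
}

# Random grade triples over 0..3 plus NA, reproducibly.
random_triples <- function(n, seed, p_na = 0.1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    t3 <- sample(0:3, 3, replace = TRUE)
    t3[stats::runif(3) < p_na] <- NA
    t3
  })
}
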
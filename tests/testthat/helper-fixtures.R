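# Shared fixtures built in code at test time.

the_table <- load_default_parameter_table()

# Default study-condition cohort (24 + 24, map-level missingness).
study_cohort <- function(seed, missing_seed = seed + 1000L, ...) {
  co <- simulate_cohort(the_table, cohort_config(seed = seed, ...))
  inject_missingness(co, seed = missing_seed)
}

# Small separable two-class problem: one strong feature + noise.
separable_data <- function(n = 30L, p = 6L, gap = 4, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + gap * y
  list(x = x, y = y)
}

# Pure-noise problem (labels independent of features).
noise_data <- function(n = 30L, p = 10L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("n", seq_len(p)))),
       y = rep(c(0L, 1L), length.out = n))
}

# A fixture table whose contralateral cells mirror the ipsilateral ones
# (used for symmetry tests).
symmetric_table <- function() {
  tab <- the_table
  p <- tab$parameters
  ipsi <- p[p$hemisphere == "ipsi", ]
  key <- with(p, paste(parameter, tissue, zone, group))
  ikey <- with(ipsi, paste(parameter, tissue, zone, group))
  contra <- p$hemisphere == "contra"
  p$mean[contra] <- ipsi$mean[match(key[contra], ikey)]
  p$sd[contra] <- ipsi$sd[match(key[contra], ikey)]
  tab$parameters <- p
  tab
}

# Zero-variance fixture table (every draw hits the group mean).
constant_table <- function() {
  tab <- the_table
  tab$parameters$sd <- 0
  tab
}
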
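# Shared fixtures, built in code so the suite ships no data files.

# A minimal balanced measurement table spanning all four age bands.
make_balanced_table <- function(n_per_cell = 30, analyte = "A", seed = 1,
                                sex_shift = 0, age_slope = 0, sd = 1, mean = 10) {
  set.seed(seed)
  rows <- list()
  for (sex in c("F", "M")) {
    for (band in default_age_bands()) {
      age <- sample(seq(band[1], band[2] - 1L), n_per_cell, replace = TRUE)
      mu <- mean + sex_shift * (sex == "M") + age_slope * (age - 38.5)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = analyte, value = rnorm(n_per_cell, mu, sd), sex = sex,
        age = age, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Exhaustive-window oracle for select_linear_region: same criterion, written
# independently with lm() per window.
brute_force_region <- function(x, y, min_span, penalty = 0.005) {
  n <- length(x)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 < min_span) next
      xi <- x[i:j]; yi <- y[i:j]
      r2 <- if (stats::var(yi) == 0) 1
            else if (stats::var(xi) == 0) 0
            else stats::cor(xi, yi)^2
      score <- min(max(r2, 0), 1) - penalty * (1 - (j - i + 1) / n)
      if (is.null(best) || score > best$score + 1e-15) {
        best <- list(start = i, end = j, score = score)
      }
    }
  }
  best
}
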
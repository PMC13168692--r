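# Shared fixtures, built in code.

# Closed unit cube with outward-consistent winding (12 triangles).
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),    # z = 0
             c(5, 6, 8), c(5, 8, 7),    # z = 1
             c(1, 2, 6), c(1, 6, 5),    # y = 0
             c(3, 7, 8), c(3, 8, 4),    # y = 1
             c(1, 5, 7), c(1, 7, 3),    # x = 0
             c(2, 4, 8), c(2, 8, 6))    # x = 1
  triangle_mesh(v, f)
}

worker_measurements <- function(scale = 1) {
  list(specimen_id = "w1", caste = "worker",
       head_width_mm = 3.7 * scale, head_thickness_mm = 2.1 * scale,
       mesosoma_width_mm = 4.2 * scale, metasoma_width_mm = 4.3 * scale,
       metasoma_anterior_length_mm = 3.1 * scale,
       metasoma_posterior_length_mm = 2.8 * scale)
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)

# Closed-form paired t statistic on differences, independent of t.test().
paired_t_oracle <- function(d) {
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# Closed-form two-variable OLS oracle.
ols_oracle <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  c(alpha = alpha, beta = beta)
}
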
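# Shared fixtures built in code.

# A small hand-written valid summary table: two compounds, two studies,
# three nonzero concentrations plus control each.
make_tiny_table <- function() {
  grid <- c(0, 5, 20, 80)
  rows <- expand.grid(concentration = grid, study = c("S1", "S2"),
                      compound = c("A", "B"), stringsAsFactors = FALSE)
  rows$mean <- round(expo_response(rows$concentration, a = 1,
                                   b = ifelse(rows$compound == "A", 10, 25),
                                   c = 0.2, d = 1.5), 6)
  rows$sd <- 0.1
  rows$n <- 3L
  summary_table(rows[, c("compound", "study", "concentration",
                         "mean", "sd", "n")], endpoint = "RAG1")
}

# A random valid summary table for property-style round-trip tests.
make_random_table <- function(seed) {
  set.seed(seed)
  grid <- sort(c(0, round(exp(runif(4, 0, log(100))), 3)))
  rows <- expand.grid(concentration = grid, study = "S1",
                      compound = c("X", "Y"), stringsAsFactors = FALSE)
  rows$mean <- round(runif(nrow(rows), 0.1, 2), 6)
  rows$sd <- round(runif(nrow(rows), 0, 0.5), 6)
  rows$n <- sample(2:6, nrow(rows), replace = TRUE)
  summary_table(rows[, c("compound", "study", "concentration",
                         "mean", "sd", "n")], endpoint = "E")
}

# Independent bisection oracle for the benchmark concentration: solves
# expo_response(x) = a * (1 + ces) without the closed form.
bmc_bisection_oracle <- function(a, b, c, d, ces, tol = 1e-12) {
  target <- a * (1 + ces)
  f <- function(x) expo_response(x, a, b, c, d) - target
  lo <- 1e-12 * b
  hi <- b
  while (sign(f(hi)) == sign(f(lo))) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = tol * b)$root
}
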
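# Independent oracles used by both the unit and the acceptance tiers.
# They deliberately avoid the code paths they check: binomial tails are
# enumerated from binomial coefficients (no pbinom), and the break oracle
# is a direct recursive transcription of the stop rule.

brute_tail <- function(hits, trials, upper) {
  ks <- if (upper) hits:trials else 0:hits
  sum(choose(trials, ks)) / 2^trials
}

brute_decision <- function(hits, trials, m, alpha) {
  if (brute_tail(hits, trials, upper = TRUE) * m < alpha) "Confirmed"
  else if (brute_tail(hits, trials, upper = FALSE) * m < alpha) "Rejected"
  else "Undecided"
}

oracle_breaks <- function(values, ratio = 0.4,
                          mode = c("head_over_tail", "head_over_all")) {
  mode <- match.arg(mode)
  m <- mean(values)
  head <- values[values > m]
  if (length(head) == 0) return(numeric(0))
  denom <- switch(mode, head_over_tail = length(values) - length(head),
                  head_over_all = length(values))
  if (denom == 0 || length(head) / denom > ratio) return(numeric(0))
  c(m, oracle_breaks(head, ratio, mode))
}

# heavy-tailed random samples for the break sweeps
heavy_sample <- function(i, seed_base = 0) {
  set.seed(seed_base + i)
  n <- sample(5:200, 1)
  if (i %% 2) rlnorm(n, sdlog = 1.5) else runif(n)^(-1 / 1.5)  # Pareto 1.5
}
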
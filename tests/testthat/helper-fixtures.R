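# Shared fixtures, memoized so expensive objects (stimulus set, full
# image audit) are built once per test run.
.fx <- new.env(parent = emptyenv())

fx_default_set <- function() {
  if (is.null(.fx$set)) .fx$set <- generate_stimulus_set()
  .fx$set
}

fx_default_audit <- function() {
  if (is.null(.fx$audit)) .fx$audit <- audit_triplets(fx_default_set())
  .fx$audit
}

# Random per-participant 2-cell median tables for statistical oracles.
random_median_table <- function(n_participants = 10, conditions = "c1") {
  g <- expand.grid(participant = sprintf("p%02d", seq_len(n_participants)),
                   condition = conditions,
                   variant_changed = c("metric", "nonaccidental"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$median_rt <- stats::rnorm(nrow(g), 900, 80)
  g$n_trials_used <- 40L
  g
}

# Independent hand-formula oracle for the one-tailed paired t test.
oracle_paired_t <- function(mp, nap) {
  d <- mp - nap
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = stats::pt(t, n - 1, lower.tail = FALSE))
}
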
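# Shared fixtures: solve the default model once per test run.

default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- glycolysis_model()
    m
  }
})

default_steady <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- solve_steady_state(default_model())
    s
  }
})

# Random non-negative states spanning several decades, reproducible.
random_states <- function(n, seed = 421) {
  set.seed(seed)
  init <- initial_state()
  lapply(seq_len(n), function(i) {
    init * exp(stats::runif(length(init), -1.5, 1.5))
  })
}

# Minimal accepted-ensemble-like tibble for the statistics modules.
toy_ensemble <- function(df) {
  df$accepted <- TRUE
  df$rejection_reason <- "none"
  structure(df, class = c("glyco_ensemble", class(df)))
}
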
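# Shared simulation fixtures, generated once per test run and memoised.
# Seeds are fixed so every test sees the same ensembles.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- switch(name,
      P2000 = run_ensemble(build_system("P"), x0 = 1, t_end = 5, n = 2000,
                           cap = 10000, base_seed = 2000),
      P5000 = run_ensemble(build_system("P"), x0 = 1, t_end = 5, n = 5000,
                           cap = 10000, base_seed = 5000),
      W2000 = run_ensemble(build_system("W"), x0 = 1, t_end = 5, n = 2000,
                           cap = 5000, base_seed = 2000),
      W5000 = run_ensemble(build_system("W"), x0 = 1, t_end = 5, n = 5000,
                           cap = 5000, base_seed = 5000),
      growth500 = run_ensemble(build_system("pure_growth"), x0 = 1,
                               t_end = 50, n = 500, cap = 10000,
                               base_seed = 77),
      stop("unknown fixture: ", name))
  }
  .fixture_cache[[name]]
}

# two-pass textbook moment oracle (independent of the streaming path)
two_pass_prefix <- function(x) {
  N <- length(x)
  list(mean = cumsum(x) / seq_len(N),
       var = vapply(seq_len(N), function(n)
         if (n < 2) NA_real_ else sum((x[1:n] - mean(x[1:n]))^2) / (n - 1),
         numeric(1)))
}

# nearest grid time to a target
grid_time_near <- function(ensemble, t) {
  g <- ensemble$grid$points
  g[which.min(abs(g - t))]
}
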
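# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-implementations of the definitions, kept independent
# of the package's code paths.

# Small simulated dataset used by several files.
small_sim <- function(seed = 1, ...) {
  cfg <- sim_config(n_individuals = 4, n_genes = 300, n_sets = 10,
                    set_size_range = c(5, 30), seed = seed, ...)
  list(config = cfg, sim = simulate_dataset(cfg))
}

# Brute-force running-sum ES oracle: full sequential walk over the list,
# signed maximal deviation, same declared tie rule (ties within 1e-9 resolve
# positive).
es_oracle <- function(scores, set, p = 1) {
  N <- length(scores)
  hits <- names(scores) %in% set
  w <- abs(scores)^p
  D <- sum(w[hits])
  Nh <- sum(hits)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hits[i]) cur + w[i] / D else cur - 1 / (N - Nh)
    run[i] <- cur
  }
  mx <- max(run)
  mn <- min(run)
  if (mx >= -mn - 1e-9) mx else mn
}

# Literal step-up BH oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Classical weighted paired t oracle via lm() per gene.
weighted_paired_t_oracle <- function(y, w, sheet) {
  fit <- stats::lm(y ~ 0 + factor(individual) + I(side == "R"),
                   data = sheet, weights = w)
  stats::summary.lm(fit)$coefficients["I(side == \"R\")TRUE", "t value"]
}
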
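# Shared fixtures built in code.

# Small random block protocol on a TR grid; non-overlapping alternating
# blocks of 1-3 conditions.
random_protocol <- function(n_cond = 2, tr = 2, max_scans = 60) {
  dur <- sample(c(8, 10, 12), 1)
  rest <- sample(c(4, 6), 1)
  cycle <- n_cond * (dur + rest)
  n_blocks <- max(1L, (max_scans * tr - rest) %/% cycle)
  conds <- lapply(seq_len(n_cond), function(k)
    list(onsets = rest + (k - 1) * (dur + rest) + (seq_len(n_blocks) - 1) * cycle,
         duration = dur))
  names(conds) <- paste0("c", seq_len(n_cond))
  stimulus_protocol(tr = tr, conditions = conds, max_scans = max_scans,
                    lead_in = rest, rest = rest)
}

# Brute-force OLS oracle, independent of the incremental path.
brute_ols_contrast <- function(X, y, w) {
  beta <- qr.solve(X, y)
  drop(crossprod(w, beta))
}

# A quick noiseless/noisy simulated run at reduced size.
tiny_sim <- function(seed = 1, grid = c(8, 8, 4), ...) {
  p <- make_paper_protocol()
  simulate_run(simulation_config(grid_shape = grid, seed = seed, ...), p)
}
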
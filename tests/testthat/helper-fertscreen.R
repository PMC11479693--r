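# shared test fixtures, built in code

# trace with single-sample impulse spikes: baseline exactly recoverable by the
# rolling median, so amplitudes are exact
impulse_trace <- function(spike_times, amplitude = 2, duration_h = 2, dt = 1,
                          baseline = 1, assay = "MOCA") {
  times <- seq(0, duration_h * 3600 - dt, by = dt)
  v <- rep(baseline, length(times))
  idx <- match(spike_times, times)
  stopifnot(!anyNA(idx))
  v[idx] <- baseline + amplitude
  calcium_trace(times, v, "impulse", assay)
}

path_items <- function(strengths) {
  codes <- c(supporting = "PP3", moderate = "PM2", strong = "PS3",
             very_strong = "PVS1")
  lapply(strengths, function(s) evidence_item(codes[[s]], "pathogenic", s))
}

# brute-force two-sided Fisher p via explicit binomial coefficients
# (independent of dhyper): probability-mass definition
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

sperm_cells <- function(n_detached, n_total, folded = FALSE) {
  data.frame(
    cell_id = sprintf("c%02d", seq_len(n_total)),
    acrosome_intact = TRUE,
    detachment_fraction = c(rep(0.8, n_detached), rep(0.1, n_total - n_detached)),
    folded_curved = folded
  )
}
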
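# shared fixture builders

# histogram object from named counts, e.g. make_hist(c(`0` = 10, `1` = 5), 12)
make_hist <- function(counts, n_neurons) {
  full <- stats::setNames(integer(n_neurons + 1), 0:n_neurons)
  full[names(counts)] <- counts
  structure(list(counts = full, n_neurons = n_neurons,
                 n_steps = sum(full)),
            class = "critnet_hist")
}

# histogram with counts drawn from an exact functional form over k = 1..kmax
law_hist <- function(f, kmax, n_neurons = kmax, scale = 1000,
                     n_silent = 0) {
  k <- seq_len(kmax)
  counts <- stats::setNames(round(scale * f(k)), k)
  if (n_silent > 0) counts <- c(stats::setNames(n_silent, 0), counts)
  make_hist(counts, n_neurons)
}

# fake PSD object from exact (frequency, power) points
make_psd <- function(frequencies, power) {
  structure(list(frequencies = frequencies, power = power,
                 slope = NA_real_, fit_band = NULL,
                 segment_length = NA, n_segments = NA,
                 window = "none", overlap = 0),
            class = "critnet_psd")
}

# short-run config for fast tests; overrides win over the quick defaults
quick_config <- function(...) {
  args <- utils::modifyList(list(duration = 1500, burn_in = 500),
                            list(...))
  do.call(sim_config, args)
}
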
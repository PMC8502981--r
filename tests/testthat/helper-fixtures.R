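# Shared fixtures: tiny protocols, series, and cached datasets. Everything
# is generated in code; the FK dataset used across forecaster tests is
# built once per test run.

tiny_protocol <- function(n = 3, cl = 300, amplitude = 0.4) {
  stim_protocol(50 + cl * (seq_len(n) - 1), duration = 2,
                amplitude = amplitude)
}

# piecewise-linear series helper
lin_series <- function(time, voltage, stimulus = NULL) {
  if (is.null(stimulus)) {
    tibble::tibble(time = time, voltage = voltage)
  } else {
    tibble::tibble(time = time, voltage = voltage, stimulus = stimulus)
  }
}

# small FK dataset shared by forecaster tests (30 beats keeps it fast)
fk_split_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fk_dataset(seed = 11, n_beats = 30,
                                n_warmup_beats = 4, n_train_beats = 20)
    }
    cache
  }
})

# independent transcription of the leaky reservoir update used as an
# oracle against the compiled implementation
esn_step_oracle <- function(W_in, W, alpha, x, h) {
  (1 - alpha) * h + alpha * tanh(as.numeric(W_in %*% x) +
                                   as.numeric(W %*% h))
}
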
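# Small in-code fixtures shared across test files.

tiny_session <- function(seed = 1) {
  p <- sim_params(n_ca1 = 6L, n_dmec = 4L,
                  dmec_mix = c(grid = 1, conjunctive = 0, head_direction = 1,
                               border = 1, other_spatial = 1),
                  run_s = 60, rest_s = 60, pre_rest_s = 30, of_s = 60,
                  event_rate_hz = 0.2)
  assemble_session(p, seed)
}

# inhomogeneous-Poisson train with sinusoidal rate modulation
modulated_train <- function(f_mod, depth, dur_s = 600, base_hz = 1, seed = 1) {
  set.seed(seed)
  dt <- 0.002
  tt <- seq(0, dur_s - dt, by = dt)
  sim_inhom_poisson(base_hz * (1 + depth * cos(2 * pi * f_mod * tt)), dt)
}

# posterior with unit mass at the bin containing x = V t T + c
delta_line_posterior <- function(V, c0, nt, nb = 300, bin_m = 0.02, T = 0.01) {
  post <- matrix(0, nb, nt)
  for (t in 0:(nt - 1)) {
    k <- floor((V * t * T + c0) / bin_m)
    stopifnot(k >= 0, k < nb)
    post[k + 1, t + 1] <- 1
  }
  post
}

random_posterior <- function(nt, nb = 300, seed = 1, peaky = FALSE) {
  set.seed(seed)
  if (peaky) {
    post <- matrix(0.01, nb, nt)
    for (t in seq_len(nt)) post[sample.int(nb, 3), t] <- c(5, 2, 1)
  } else {
    post <- matrix(stats::rexp(nb * nt), nb, nt)
  }
  sweep(post, 2, colSums(post), "/")
}

synthetic_lfp <- function(f_hz, dur_s = 60, fs = 250, amp = 30, noise = 1,
                          id = "ch", seed = 1) {
  set.seed(seed)
  tt <- seq(0, dur_s, by = 1 / fs)
  list(channel_id = id, region = "CA1", rate_hz = fs, start_s = 0,
       samples = amp * cos(2 * pi * f_hz * tt) + stats::rnorm(length(tt), 0, noise))
}
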
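# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept small so the default run stays fast.

# two-class oddball session; amplitude/noise ~ 2 so the ERP is recoverable
small_oddball <- function(n_per_class = 30, fs = 64, seed = 42,
                          n_channels = 2, amplitude = 5) {
  generate_oddball(synth_config(
    fs = fs, epoch_ms = 1000, n_channels = n_channels,
    class_spec = data.frame(label = 0:1, n_epochs = n_per_class,
                            erp_amplitude = c(0, amplitude),
                            erp_latency_mean = 400, erp_latency_sd = 40,
                            erp_width = 150),
    noise_sd = 2.5, pink_exponent = 1, seed = seed))
}

# trivially separable two-class data: distinct constant offsets plus noise
separable_epochs <- function(n_per_class = 40, n_samples = 32, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  dat <- array(stats::rnorm(n * n_samples, sd = 0.1), c(n, 1, n_samples))
  lab <- rep(0:1, each = n_per_class)
  shape <- sin(seq(0, 2 * pi, length.out = n_samples))
  for (i in which(lab == 1)) dat[i, 1, ] <- dat[i, 1, ] + 0.8 * shape
  eeg_epochs(dat, lab, fs = n_samples)
}

# direct O(n^2) DFT used as the spectrum oracle
dft_direct <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)))
  }, 0)
}

# scalar-loop BCE oracle over two equal-shape squashed statistic arrays
bce_loop <- function(target, arg) {
  stopifnot(length(target) == length(arg))
  tot <- 0
  for (j in seq_along(target))
    tot <- tot + target[j] * log(arg[j]) + (1 - target[j]) * log(1 - arg[j])
  -tot / length(target)
}
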
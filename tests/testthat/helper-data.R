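# Seeded random fixtures built in code.

# A random frame: per-axis sinusoid with random frequency/amplitude/
# phase plus Gaussian noise. Small W keeps the O(n^2) oracle DFT cheap.
make_frame <- function(seed, W = 64, rate = 32, label = "a") {
  set.seed(seed)
  t <- (seq_len(W) - 1) / rate
  axes <- vapply(1:3, function(ax) {
    f <- runif(1, 0.5, rate / 4)
    a <- runif(1, 0.2, 3)
    off <- runif(1, -1, 2)
    off + a * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
      rnorm(W, 0, runif(1, 0.05, 0.5))
  }, numeric(W))
  har_frame(axes, rate = rate, label = label)
}

make_stream <- function(seed, n = 200, rate = 50, label = "a",
                        subject = "s1") {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  d <- cbind(sin(2 * pi * 2 * t) + rnorm(n, 0, 0.1),
             cos(2 * pi * 2 * t) + rnorm(n, 0, 0.1),
             9.8 + rnorm(n, 0, 0.05))
  har_stream(d, rate = rate, label = label, subject = subject)
}

# Feature table with k_info informative + k_noise pure-noise columns,
# two classes. Informative columns differ in mean by `shift` sds.
make_weighted_table <- function(seed, n_per_class = 150, k_info = 5,
                                k_noise = 30, shift = 0.8) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("a", "b"), each = n_per_class)
  m <- matrix(rnorm(n * (k_info + k_noise)), n)
  for (j in seq_len(k_info))
    m[lab == "b", j] <- m[lab == "b", j] + shift
  colnames(m) <- c(paste0("info", seq_len(k_info)),
                   paste0("noise", seq_len(k_noise)))
  list(features = as.data.frame(m), labels = lab,
       informative = seq_len(k_info),
       noise = k_info + seq_len(k_noise))
}
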
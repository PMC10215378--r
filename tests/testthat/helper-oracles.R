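# Shared fixtures and independent oracles, built in code at test time.

# Reference parameter set used throughout: two well-separated stationary
# doses (Rmax ~ 2.54, Rmin ~ 6.67).
ref_params <- function() linlog_params(a = 0, b = 1, c = 10, d = 100, f = 1)

# Independent numeric oracle for the stationary doses: bracketed
# root-finding on the slope, never the closed form. The slope is negative
# at the logistic midpoint log(d)/f and positive once the logistic term
# decays below b, which bounds the brackets.
numeric_stationary <- function(params) {
  b <- params$b; cc <- params$c; f <- params$f
  mid <- params$log_d / f
  slope_fn <- function(x) linlog_slope(params, x)
  t_out <- (log(cc * f / b) + 30) / f  # slope surely positive beyond this
  left <- uniroot(slope_fn, c(mid - t_out, mid), tol = 1e-13)$root
  right <- uniroot(slope_fn, c(mid, mid + t_out), tol = 1e-13)$root
  list(rmax = left, rmin = right)
}

# Random valid parameter draws with two stationary points (c*f > 4b).
draw_two_point_params <- function(n, seed = 20260901) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    b <- runif(1, 0.05, 5)
    f <- runif(1, 0.1, 10)
    ratio <- runif(1, 1.05, 10)        # c*f / (4b)
    cc <- 4 * b * ratio / f
    logd <- runif(1, -2, 8)
    linlog_params(a = runif(1, -5, 5), b = b, c = cc, f = f, log_d = logd)
  })
}

# Low-noise variant of the default titration design.
low_noise_design <- function(seed = 1L, noise_sd = 0.01) {
  synthetic_design(noise_sd = noise_sd, seed = seed)
}

# 12 noiseless observations from the reference parameter set.
noiseless_ref_data <- function() {
  x <- seq(0.5, 6, by = 0.5)
  dose_response(x, linlog_eval(ref_params(), x))
}

# Write a small CSV into a fresh temp file and return its path.
write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
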
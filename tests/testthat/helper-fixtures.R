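# shared fixtures: small parameter sets and a quick trajectory builder

fast_times <- c(0, 1, 2, 5, 10, 15, 20, 30, 45, 60)

i154f_params <- function() capture_params(0.030, 0.300, 0.35, 0.02)
d122y_params <- function() capture_params(0.015, 0.450, 0.30, 0.005)

random_capture_params <- function() {
  capture_params(k_u = stats::runif(1, 0, 0.1),
                 k_f = stats::runif(1, 0.1, 2),
                 k_c = stats::runif(1, 0.05, 1),
                 k_agg = stats::runif(1, 0, 0.05))
}
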
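# shared fixtures: small discrete target with known probabilities, and a
# Gaussian numerosity posterior matching the running example
grid5_probs <- c(0.10, 0.30, 0.20, 0.25, 0.15)

grid5_spec <- function() {
  posterior_spec("discrete_grid", grid_values = 1:5,
                 grid_logmass = log(grid5_probs))
}

dots_spec <- function(mean = 24, sd = 3) posterior_spec("gaussian", mean, sd)

dots_partition <- function(boundary = 25) {
  partition_spec(boundary, labels = c("lower", "greater"))
}

beta11 <- function() response_prior(c(1, 1))
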
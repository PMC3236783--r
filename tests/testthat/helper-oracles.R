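# Independent oracle for integer assignment: explicit Gaussian densities,
# argmax by direct enumeration (ties to the first, i.e. smaller, candidate).
brute_force_assign <- function(v, sigma0, cv, k_max) {
  vapply(v, function(x) {
    k <- 0:k_max
    dens <- exp(-(x - k)^2 / (2 * (sigma0 + cv * k)^2)) / (sigma0 + cv * k)
    k[which.max(dens)]
  }, numeric(1))
}
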
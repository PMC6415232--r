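# Shared fixtures and the grid-minimisation oracle used to cross-check
# the root-finding solvers.

std_chain <- function(a0 = 0.1, z = 1, t = 0) chain_params(a0 = a0, z = z, t = t)
std_salt <- salt_1_1(0.01)

# Independent argmin by brute-force grid evaluation: a coarse log grid
# locates the global minimum, then a fine linear grid of 1e6 points over
# a +/- 0.01 nm window pins it to ~2e-8 nm resolution.  No derivatives.
grid_argmin <- function(gfun, lo = 1e-3, hi = 100, n_fine = 1e6) {
  bs <- exp(seq(log(lo), log(hi), length.out = 20000L))
  b0 <- bs[which.min(gfun(bs))]
  flo <- max(lo, b0 - 0.01)
  fhi <- min(hi, b0 + 0.01)
  bf <- seq(flo, fhi, length.out = n_fine)
  bf[which.min(gfun(bf))]
}

# One composite collapse free energy (spring term with b-dependent a),
# transcribed independently of the package internals.
collapse_g <- function(b, a0, t, z, lB, kappa) {
  0.5 * (a0 + t * lB / (8 * exp(1) * b)) * b^2 -
    (1 / z) * (2 - b / (z * lB)) * log(-expm1(-kappa * b)) -
    1 / z + b / (z^2 * lB)
}
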
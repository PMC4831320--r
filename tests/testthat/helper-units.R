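# Shared fixtures: a mid-family example unit and coarse lattices keep the
# property loops fast; resolution only affects accuracy, not orderings.

unit_mid <- contrast_encoder(sigma_s = 2, sigma_n = 2)

fast_grid <- function(unit, res = 8) encoder_grid(unit, res)

# continuum-limit masses, written out independently of the package oracle:
# Gaussian mass inside a centered disk of radius R and square of half-width a
ref_disk_mass <- function(sigma, R = 2) 1 - exp(-R^2 / (2 * sigma^2))
ref_square_mass <- function(sigma, a = 2) (2 * pnorm(a / sigma) - 1)^2
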
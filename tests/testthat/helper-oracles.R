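# Independent analytic oracles used by the acceptance suite ---------------
#
# Radial profile of an isotropic-Gaussian-blurred, radially symmetric
# structure, by quadrature of the exact 2D convolution kernel
#   g(rho) = int f(r) (r/sigma^2) exp(-(r^2+rho^2)/(2 sigma^2))
#                I0(r rho / sigma^2) dr,
# evaluated with the exponentially scaled Bessel I0 for stability. Pure
# test-side code: shares nothing with the package's image path.
oracle_blurred_radial <- function(rho, inner, outer, sigma,
                                  n_quad = 400L) {
  if (sigma <= 0) return(as.numeric(rho >= inner & rho <= outer))
  r <- seq(max(0, inner), outer, length.out = n_quad)
  dr <- r[2] - r[1]
  vapply(rho, function(p) {
    z <- r * p / sigma^2
    integ <- (r / sigma^2) * exp(-(r - p)^2 / (2 * sigma^2)) *
      besselI(z, 0, expon.scaled = TRUE)
    sum(integ) * dr
  }, numeric(1))
}

# expected averaged radial profile for a set of planted, size-normalized
# stacks: per stack a unit-sum structure (ring annulus or disk) scaled by
# s_i = 100 / gyradius_i with the blurred PSF; equal-weight average
oracle_average_profile <- function(rho, radii_px, half_width_px, sigma_px,
                                   kind = c("ring", "disk"),
                                   disk_ratio = NULL) {
  kind <- match.arg(kind)
  acc <- numeric(length(rho))
  for (R in radii_px) {
    g <- sqrt(R^2 + (2 * half_width_px)^2 / 12 + 2 * sigma_px^2)
    s <- 100 / g
    if (kind == "ring") {
      n_e <- s * (R - half_width_px); e_e <- s * (R + half_width_px)
    } else {
      n_e <- 0; e_e <- s * disk_ratio * R
      # a disk's own gyradius does not set the scale; the reference ring
      # in the same stack does, hence s from the ring geometry above
    }
    dens <- 1 / (pi * (e_e^2 - n_e^2))
    acc <- acc + dens * oracle_blurred_radial(rho, n_e, e_e, s * sigma_px)
  }
  acc / length(radii_px)
}

# first half-max crossing beyond the global peak, hand-rolled so the oracle
# path shares no code with extract_marker_radius()
oracle_half_max_radius <- function(rho, prof) {
  pk <- which.max(prof)
  half <- prof[pk] / 2
  for (i in (pk + 1):length(prof)) {
    if (prof[i] < half) {
      lo <- i - 1
      return(rho[lo] + (rho[i] - rho[lo]) * (prof[lo] - half) /
               (prof[lo] - prof[i]))
    }
  }
  NA_real_
}
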
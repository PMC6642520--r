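# Shared helpers for building small test inputs in code.

# Random valid frontier energies: I > A, positive gap.
random_frontier <- function() {
  e_homo <- stats::runif(1, -12, -3)
  gap <- stats::runif(1, 0.5, 8)
  frontier_energies(e_homo, e_homo + gap)
}

# Random small volumetric grid with values in [-1, 1).
random_grid <- function(counts = c(3L, 4L, 5L)) {
  axes <- diag(stats::runif(3, 0.3, 1.5))
  volumetric_grid(origin = stats::runif(3, -2, 2), axes = axes,
                  counts = counts,
                  atoms = data.frame(number = c(6L, 8L), charge = c(6, 8),
                                     x = c(0, 1), y = c(0, 1), z = c(0, 1)),
                  values = stats::runif(prod(counts), -1, 1))
}

# An isotropic Gaussian sampled on a cubic grid; closed-form integral
# A * (2*pi)^1.5 * sigma^3 when the blob lies well inside the box.
gaussian_grid <- function(n = 48L, box = 12, amp = 2.5, sigma = 0.8) {
  h <- box / n
  x <- (seq_len(n) - 0.5) * h - box / 2
  g1 <- exp(-x^2 / (2 * sigma^2))
  vals <- amp * outer(g1, outer(g1, g1))
  volumetric_grid(c(0, 0, 0), diag(rep(h, 3)), rep(n, 3L),
                  values = as.numeric(aperm(vals, c(3, 2, 1))))
}

# The qcf orbital block used across parser tests.
qcf_lines <- c("# toy spectrum", "unit eV",
               "orbital -10.0 2", "orbital -6.240 2",
               "orbital -1.733 0", "orbital 0.5 0")
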
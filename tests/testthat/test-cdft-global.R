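test_that("frontier extraction picks the band edges", {
  sp <- orbital_spectrum(c(-9, -5, -5, -1, 2), c(2, 2, 2, 0, 0))
  f <- frontier_from_spectrum(sp)
  expect_equal(f$e_homo, -5)   # degenerate HOMO level
  expect_equal(f$e_lumo, -1)
  full <- orbital_spectrum(c(-9, -5), c(2, 2))
  expect_error(frontier_from_spectrum(full), "no unoccupied")
})

test_that("vertical I/A follow the Koopmans sign convention", {
  expect_equal(vertical_ia(frontier_energies(-6.240, -1.733)),
               c(I = 6.240, A = 1.733))
  expect_equal(vertical_ia(frontier_energies(-4.2, 0)), c(I = 4.2, A = 0))
  # unbound anion: positive LUMO gives a negative electron affinity
  expect_equal(vertical_ia(frontier_energies(-6, 1)), c(I = 6, A = -1))
})

test_that("global descriptors reproduce hand-forced arithmetic", {
  d <- global_descriptors(frontier_energies(-2, 0))
  expect_equal(d$chi, 1)
  expect_equal(d$mu, -1)
  expect_equal(d$eta, 2)
  expect_equal(d$softness, 0.5)
  expect_equal(d$omega, 0.25)
  expect_equal(d$omega_minus, 1.125)
  expect_equal(d$omega_plus, 0.125)
  expect_equal(d$net_electrophilicity, 1.25)
  expect_identical(d$omega_minus - d$omega_plus, d$chi)
})

test_that("reference frontier energies give the published descriptor block", {
  d <- global_descriptors(frontier_energies(-6.240, -1.733))
  expect_equal(d$chi, 3.986, tolerance = 0.005 / 3.986)
  expect_equal(d$eta, 4.507, tolerance = 1e-12)
  expect_equal(d$omega, 1.763, tolerance = 0.005 / 1.763)
  expect_equal(d$omega_minus, 5.800, tolerance = 0.005 / 5.800)
  expect_equal(d$omega_plus, 1.814, tolerance = 0.005 / 1.814)
  expect_equal(d$net_electrophilicity, 7.614, tolerance = 0.005 / 7.614)
  expect_equal(round(d$lambda_max), 275)
})

test_that("degenerate frontiers are rejected", {
  expect_error(frontier_energies(-5, -5), "degenerate")
  expect_error(global_descriptors(c(I = 3, A = 3)), "degenerate")
  expect_error(lambda_max(0), "non-positive")
})

test_that("delta-SCF mode accepts an (I, A) pair", {
  ia <- finite_difference_ia(-100.00, -99.77, -100.06, unit = "ev")
  expect_equal(ia, c(I = 0.23, A = 0.06), tolerance = 1e-12)
  ia_h <- finite_difference_ia(-100.00, -99.99, -100.01)
  expect_equal(unname(ia_h["I"]), 0.27211386, tolerance = 1e-9)
  d <- global_descriptors(finite_difference_ia(-100, -99.8, -100.05,
                                               unit = "ev"))
  expect_equal(d$eta, 0.15, tolerance = 1e-12)
  # symmetric energies give I = A: hardness degenerates downstream
  expect_error(global_descriptors(finite_difference_ia(-100, -99.9, -100.1,
                                                       unit = "ev")),
               "degenerate")
  expect_error(finite_difference_ia(-100, NULL, -100.1), "required")
})

test_that("electrodonating minus electroaccepting power equals chi", {
  set.seed(101)
  for (i in 1:1000) {
    d <- global_descriptors(random_frontier())
    expect_lt(abs((d$omega_minus - d$omega_plus) - d$chi), 1e-10)
    expect_identical(d$net_electrophilicity, d$omega_minus + d$omega_plus)
    expect_gt(d$eta, 0)
  }
})

test_that("omega_minus dominates omega_plus for electron-rich frontiers", {
  set.seed(33)
  for (i in 1:200) {
    i_v <- stats::runif(1, 2, 12)
    a_v <- stats::runif(1, 0.1, i_v - 0.1)
    d <- global_descriptors(c(I = i_v, A = a_v))
    expect_gte(d$omega_minus, d$omega_plus)   # holds when I > A > 0
  }
})

test_that("chi and the charge-transfer powers increase with I at fixed A", {
  # chi rises with I everywhere; omega- and omega+ only once I clears
  # 7A/3 and 5A respectively (their I-derivatives change sign there), so
  # probe the regime above both thresholds
  a_v <- 1.5
  iv <- seq(5 * a_v + 0.5, 20, length.out = 30)
  ds <- lapply(iv, function(i) global_descriptors(c(I = i, A = a_v)))
  chi <- vapply(ds, `[[`, numeric(1), "chi")
  wm <- vapply(ds, `[[`, numeric(1), "omega_minus")
  wp <- vapply(ds, `[[`, numeric(1), "omega_plus")
  expect_true(all(diff(chi) > 0))
  expect_true(all(diff(wm) > 0))
  expect_true(all(diff(wp) > 0))
})

test_that("wavelength times gap is Planck's constant in eV nm", {
  f <- frontier_energies(-6.240, -1.733)
  expect_equal(lambda_max(f), 275.09, tolerance = 1e-4)
  expect_equal(lambda_max(2.0), 619.921, tolerance = 1e-5)
  set.seed(5)
  for (i in 1:100) {
    gap <- stats::runif(1, 0.1, 12)
    expect_lt(abs(lambda_max(gap) * gap - 1239.841984), 1e-9)
  }
})

test_that("KID diagnostics vanish in the constructed Koopmans limit", {
  f <- frontier_energies(-6.0, -1.7)
  k <- kid_diagnostics(-100, -100 + ev_to_hartree(6.0),
                       -100 - ev_to_hartree(1.7), f)
  expect_equal(k$j_i, 0, tolerance = 1e-10)
  expect_equal(k$j_a, 0, tolerance = 1e-10)
  expect_equal(k$j_hl, 0, tolerance = 1e-10)
})

test_that("KID diagnostics combine in quadrature", {
  f <- frontier_energies(-6.0, -1.7)
  k <- kid_diagnostics(-100, -100 + 6.2, -100 - 1.9, f, unit = "ev")
  expect_equal(k$j_i, 0.2, tolerance = 1e-12)
  expect_equal(k$j_a, 0.2, tolerance = 1e-12)
  expect_equal(k$j_hl, 0.28284, tolerance = 1e-4)
  expect_equal(k$j_hl, sqrt(k$j_i^2 + k$j_a^2), tolerance = 1e-12)
  expect_error(kid_diagnostics(-100, NULL, -100.1, f), "required")
})
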
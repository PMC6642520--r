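test_that("condensed Fukui values are the direct charge differences", {
  qn <- charge_set("m", c("C", "O"), c(0, 0), 0)
  qc <- charge_set("m", c("C", "O"), c(0.6, 0.4), 1)
  qa <- charge_set("m", c("C", "O"), c(-0.7, -0.3), -1)
  cf <- condensed_fukui(qn, qc, qa)
  expect_equal(cf$f_minus, c(0.6, 0.4))
  expect_equal(cf$f_plus, c(0.7, 0.3))
  expect_equal(cf$dual, c(0.1, -0.1))
  expect_equal(sum(cf$f_minus), 1)
  expect_equal(sum(cf$f_plus), 1)
  expect_equal(sum(cf$dual), 0)
})

test_that("condensed Fukui matches a per-atom subtraction oracle", {
  for (seed in 1:50) {
    tr <- make_charge_triplet(seed, n_atoms = 5 + seed %% 7)
    cf <- condensed_fukui(tr$q_n, tr$q_nm1, tr$q_np1)
    # oracle: plain elementwise loop, independent of the implementation
    n <- length(tr$q_n$q)
    fm <- fp <- dd <- numeric(n)
    for (k in seq_len(n)) {
      fm[k] <- tr$q_nm1$q[k] - tr$q_n$q[k]
      fp[k] <- tr$q_n$q[k] - tr$q_np1$q[k]
      dd[k] <- fp[k] - fm[k]
    }
    expect_equal(cf$f_minus, fm, tolerance = 1e-12)
    expect_equal(cf$f_plus, fp, tolerance = 1e-12)
    expect_equal(cf$dual, dd, tolerance = 1e-12)
    expect_equal(sum(cf$f_minus), 1, tolerance = 1e-6)
    expect_equal(sum(cf$f_plus), 1, tolerance = 1e-6)
    expect_equal(sum(cf$dual), 0, tolerance = 1e-6)
  }
})

test_that("condensed Fukui rejects inconsistent charge triplets", {
  qn <- charge_set("m", c("C", "O"), c(0, 0), 0)
  qc <- charge_set("m", c("C", "O"), c(0.6, 0.4), 1)
  qa <- charge_set("m", c("C", "O"), c(-0.7, -0.3), -1)
  other_scheme <- charge_set("hirshfeld", c("C", "O"), c(0.6, 0.4), 1)
  expect_error(condensed_fukui(qn, other_scheme, qa), "scheme")
  qc3 <- charge_set("m", c("C", "O", "H"), c(0.5, 0.4, 0.1), 1)
  expect_error(condensed_fukui(qn, qc3, qa), "atom-count")
  # wrong ionic charges: swapping cation and anion must fail
  expect_error(condensed_fukui(qn, qa, qc), "net charge")
})

test_that("charge-conservation noise shifts Fukui sums linearly", {
  eps <- c(1e-4, 1e-3, 5e-3)
  for (e in eps) {
    tr <- make_charge_triplet(99, 12, noise = e)
    cf <- condensed_fukui(tr$q_n, tr$q_nm1, tr$q_np1)
    expect_equal(sum(cf$f_minus), 1 + e, tolerance = 1e-10)
    expect_equal(sum(cf$f_plus), 1 + e, tolerance = 1e-10)
    expect_equal(sum(cf$dual), 0, tolerance = 1e-10)
  }
})

test_that("grid Fukui fields recover a constructed blob exactly", {
  tr <- make_grid_triplet(3, c(16L, 16L, 16L), n_blobs = 1L)
  fk <- grid_fukui(tr$rho_n, tr$rho_nm1, tr$rho_np1)
  # rho_nm1 = rho_n - g  =>  f_minus = g voxelwise
  g_expected <- tr$rho_n$values - tr$rho_nm1$values
  expect_equal(fk$f_minus$values, g_expected, tolerance = 1e-14)
  # dual is the voxelwise difference of the two channels
  expect_equal(fk$dual$values, fk$f_plus$values - fk$f_minus$values,
               tolerance = 1e-14)
})

test_that("synthetic density triplets yield normalized Fukui fields", {
  tr <- make_grid_triplet(17, c(32L, 32L, 32L), n_blobs = 2L)
  fk <- grid_fukui(tr$rho_n, tr$rho_nm1, tr$rho_np1)
  expect_equal(grid_integral(fk$f_minus), 1, tolerance = 1e-3)
  expect_equal(grid_integral(fk$f_plus), 1, tolerance = 1e-3)
  expect_lt(abs(grid_integral(fk$dual)), 1e-3)
})

test_that("grid Fukui is linear in the densities", {
  tr <- make_grid_triplet(5, c(16L, 16L, 16L), 1L)
  fk1 <- grid_fukui(tr$rho_n, tr$rho_nm1, tr$rho_np1)
  scale <- function(g, c) volumetric_grid(g$origin, g$axes, g$counts,
                                          g$atoms, c * g$values)
  fk3 <- grid_fukui(scale(tr$rho_n, 3), scale(tr$rho_nm1, 3),
                    scale(tr$rho_np1, 3))
  expect_equal(fk3$f_minus$values, 3 * fk1$f_minus$values, tolerance = 1e-12)
  expect_equal(fk3$dual$values, 3 * fk1$dual$values, tolerance = 1e-12)
})

test_that("non-congruent grids are rejected", {
  a <- volumetric_grid(c(0, 0, 0), diag(3), c(2, 2, 2), values = rep(1, 8))
  b <- volumetric_grid(c(0, 0, 0), diag(3), c(3, 3, 3), values = rep(1, 27))
  expect_error(grid_fukui(a, b, a), "counts differ")
  shifted <- volumetric_grid(c(0.1, 0, 0), diag(3), c(2, 2, 2),
                             values = rep(1, 8))
  expect_error(grid_fukui(a, shifted, a), "origin/axes")
})

test_that("site ranking orders by value with index tie-break", {
  qn <- charge_set("m", c("C", "N", "O"), c(0, 0, 0), 0)
  qc <- charge_set("m", c("C", "N", "O"), c(0.1, 0.5, 0.4), 1)
  qa <- charge_set("m", c("C", "N", "O"), c(-0.4, -0.3, -0.3), -1)
  cf <- condensed_fukui(qn, qc, qa)
  top <- rank_sites(cf, "f_minus", 2)
  expect_equal(top$atom, c(2, 3))
  expect_equal(top$value, c(0.5, 0.4))
  expect_equal(nrow(rank_sites(cf, "f_minus", 0)), 0)
  # tie on f_plus between atoms 2 and 3: lower index first
  tie <- rank_sites(cf, "f_plus", 3)
  expect_equal(tie$atom[tie$value == 0.3], c(2, 3))
  expect_error(rank_sites(cf, "f_minus", 4), "0..3")
  expect_error(rank_sites(cf, "f_total", 1))
})

test_that("condensed Fukui exports a tidy CSV", {
  qn <- charge_set("m", c("C", "O"), c(0, 0), 0)
  qc <- charge_set("m", c("C", "O"), c(0.6, 0.4), 1)
  qa <- charge_set("m", c("C", "O"), c(-0.7, -0.3), -1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fukui_csv(condensed_fukui(qn, qc, qa), path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("atom", "element", "f_minus", "f_plus", "dual"))
  expect_equal(back$f_minus, c(0.6, 0.4))
})
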
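make_mask <- function(n, frac = 1, seed = 1) {
  withr::local_seed(seed)
  inside <- array(runif(prod(n)) < frac, n)
  inside[1, 1, 1] <- TRUE
  structure_mask(inside, name = "fLung")
}

test_that("uniform dose gives a step-function DVH", {
  n <- c(6, 6, 6)
  d <- dose_grid(array(30, n))
  m <- make_mask(n)
  crv <- cumulative_dvh(d, m, bin_width = 0.5)
  expect_equal(crv$cumulative_percent[crv$bin_edges <= 30],
               rep(100, sum(crv$bin_edges <= 30)))
  expect_equal(crv$cumulative_percent[crv$bin_edges > 30],
               rep(0, sum(crv$bin_edges > 30)))
})

test_that("a two-level dose yields 50% volume between the levels", {
  n <- c(4, 4, 4)
  vals <- array(10, n); vals[1:2, , ] <- 10; vals[3:4, , ] <- 40
  d <- dose_grid(vals)
  m <- make_mask(n)
  expect_equal(volume_at_dose(d, m, 20), 50)
  crv <- cumulative_dvh(d, m, bin_width = 1)
  expect_equal(crv$cumulative_percent[crv$bin_edges == 20], 50)
})

test_that("linear dose ramp matches the analytic DVH line within one bin", {
  n <- c(60, 4, 4)
  ramp <- array(rep(seq(0, 60, length.out = 60), 16), n)
  d <- dose_grid(ramp)
  m <- make_mask(n)
  crv <- cumulative_dvh(d, m, bin_width = 0.5)
  inside <- crv$bin_edges <= 60
  analytic <- 100 * (1 - crv$bin_edges[inside] / 60)
  # discrete voxel counting tracks the analytic line to within one bin step
  expect_lt(max(abs(crv$cumulative_percent[inside] - analytic)),
            100 * 0.5 / 60 + 100 / 60)
})

test_that("Vx conventions: V0 is 100%, the comparison is inclusive", {
  n <- c(5, 5, 5)
  d <- dose_grid(array(22, n))
  m <- make_mask(n, frac = 0.5, seed = 2)
  expect_equal(volume_at_dose(d, m, 0), 100)
  expect_equal(volume_at_dose(d, m, 22), 100)   # >= is inclusive
  expect_equal(volume_at_dose(d, m, 20), 100)
  expect_equal(volume_at_dose(d, m, 25), 0)
})

test_that("Vx equals a brute-force voxel count on random dose grids", {
  n <- c(8, 8, 8)
  for (seed in 1:3) {
    withr::local_seed(seed)
    d <- dose_grid(array(runif(prod(n), 0, 70), n))
    m <- make_mask(n, frac = 0.6, seed = seed + 10)
    for (lev in c(5, 20, 45)) {
      manual <- 100 * sum(d$values[m$inside] >= lev) / sum(m$inside)
      expect_equal(volume_at_dose(d, m, lev), manual, tolerance = 1e-14)
    }
  }
})

test_that("the functional dose-volume vector obeys its invariants", {
  n <- c(10, 10, 10)
  withr::local_seed(6)
  d <- dose_grid(array(rexp(prod(n), rate = 1 / 25), n))
  m <- make_mask(n, frac = 0.5, seed = 7)
  fv <- extract_fv_vector(d, m)
  expect_named(unclass(fv), paste0("V", seq(5, 60, 5)))
  expect_true(all(fv >= 0 & fv <= 100))
  expect_true(all(diff(unclass(fv)) <= 0))
  # uniform 22 Gy: first four levels full, the rest empty
  fv22 <- extract_fv_vector(dose_grid(array(22, n)), m)
  expect_equal(unname(unclass(fv22)), c(rep(100, 4), rep(0, 8)))
  # zero dose: nothing receives 5 Gy or more
  expect_true(all(extract_fv_vector(dose_grid(array(0, n)), m) == 0))
})

test_that("mean dose equals the DVH integral within one bin width", {
  n <- c(12, 12, 12)
  withr::local_seed(9)
  d <- dose_grid(array(runif(prod(n), 0, 55), n))
  m <- make_mask(n, frac = 0.7, seed = 9)
  bw <- 0.1
  crv <- cumulative_dvh(d, m, bin_width = bw)
  integral <- bw * sum(crv$cumulative_percent / 100)
  expect_lt(abs(mean(d$values[m$inside]) - integral), bw)
})

test_that("absolute-volume output scales with voxel volume", {
  n <- c(6, 6, 6)
  d <- dose_grid(array(30, n), spacing = c(5, 5, 5))
  m <- structure_mask(array(TRUE, n), spacing = c(5, 5, 5))
  fv_cc <- extract_fv_vector(d, m, absolute = TRUE)
  expect_equal(unname(fv_cc[["V20"]]), prod(n) * 125 / 1000)
})

test_that("dose on a finer grid is resampled to the mask grid", {
  # dose defined at 1 mm; mask at 2 mm covering the same extent
  nd <- c(21, 21, 21)
  w <- ventidose:::world_coordinate_arrays(image_grid(array(0, nd), c(1, 1, 1)))
  d <- dose_grid(3 * w$x, spacing = c(1, 1, 1))
  m <- structure_mask(array(TRUE, c(11, 11, 11)), spacing = c(2, 2, 2))
  v30 <- volume_at_dose(d, m, 30)
  # analytic: dose >= 30 where x >= 10 mm, i.e. 6 of 11 mask columns
  expect_equal(v30, 100 * 6 / 11, tolerance = 1e-9)
  expect_error(cumulative_dvh(d, structure_mask(array(FALSE, nd))), "empty")
})

test_that("halving the voxel size changes each Vx by less than 1%", {
  # edge-aligned grids covering the same 120 mm box, 4 mm vs 2 mm voxels
  analytic_fv <- function(n1, h) {
    g0 <- image_grid(array(0, rep(n1, 3)), rep(h, 3), origin = rep(h / 2, 3))
    w <- ventidose:::world_coordinate_arrays(g0)
    r2 <- (w$x - 60)^2 + (w$y - 60)^2 + (w$z - 60)^2
    d <- dose_grid(60 * exp(-r2 / (2 * 35^2)), rep(h, 3),
                   origin = rep(h / 2, 3))
    m <- structure_mask(array(TRUE, rep(n1, 3)), rep(h, 3),
                        origin = rep(h / 2, 3))
    unclass(extract_fv_vector(d, m))
  }
  expect_lt(max(abs(analytic_fv(30, 4) - analytic_fv(60, 2))), 1)
})
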
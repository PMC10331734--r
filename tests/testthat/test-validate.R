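make_traj <- function(frames) {
  at <- data.frame(name = c("A", "B", "C", "D"),
                   element = c("C", "C", "C", "C"),
                   stringsAsFactors = FALSE)
  xfp_structure(at, frames)
}

# four atoms whose 1-2-3-4 dihedral equals `phi` (degrees)
frame_with_dihedral <- function(phi) {
  rad <- phi * pi / 180
  rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
        c(1, cos(rad), sin(rad)))
}

test_that("angle series evaluate per frame and recenter wrapped dihedrals", {
  static <- make_traj(list(frame_with_dihedral(100), frame_with_dihedral(100)))
  d <- angle_definition("phi", "dihedral", c("A", "B", "C", "D"))
  s <- angle_series(static, d)
  expect_length(s, 2L)
  expect_equal(s[1], s[2])

  phis <- c(178, 179, -179, -178, 179, -180)
  wrap <- make_traj(lapply(phis, frame_with_dihedral))
  s2 <- angle_series(wrap, d)
  # contiguous branch near 180: no split at the +/-180 seam
  expect_lt(diff(range(s2)), 10)
  # recentering changes values only by multiples of 360
  raw <- vapply(seq_along(phis), function(f) {
    dihedral_angle(wrap, 1, 2, 3, 4, frame = f)
  }, 0)
  expect_equal((s2 - raw) %% 360, rep(0, length(phis)), tolerance = 1e-9)

  # frame-by-frame equality with direct geometry calls on a random fixture
  withr::with_seed(8, {
    frames <- lapply(1:20, function(i) matrix(rnorm(12, sd = 2), 4, 3))
  })
  rnd <- make_traj(frames)
  ba <- angle_definition("theta", "bond_angle", c("A", "B", "C"))
  expect_equal(angle_series(rnd, ba),
               vapply(1:20, function(f) bond_angle(rnd, 1, 2, 3, frame = f), 0))
  expect_error(angle_series(rnd, angle_definition("x", "bond_angle",
                                                  c("A", "B", "ZZ"))),
               "ZZ")
  expect_error(angle_definition("x", "dihedral", c("A", "B", "C")), "4 atom")
})

test_that("gaussian fits recover synthetic normal draws", {
  center_err <- sigma_err <- numeric(20)
  for (i in 1:20) {
    x <- gen_ou_angle_series(120, 5, 0, 1e5, seed = 200 + i)
    f <- fit_gaussian(x, bin_width = 2)
    expect_true(f$converged)
    center_err[i] <- abs(f$center - 120)
    sigma_err[i] <- abs(f$sigma - 5)
  }
  expect_lt(mean(center_err), 0.1)
  expect_lt(mean(sigma_err), 0.15)
  # spec'd parameter-recovery property: mean errors under 5% of sigma
  expect_lt(mean(center_err), 0.05 * 5)
  expect_lt(mean(sigma_err), 0.05 * 5)
})

test_that("gaussian fit rejects degenerate series and respects symmetry", {
  expect_error(fit_gaussian(rep(1, 500), 2), "degenerate")
  expect_error(fit_gaussian(rnorm(50), 2), "100 samples")
  # symmetric bimodal: converged center sits at the symmetry point
  withr::with_seed(33, {
    x <- c(rnorm(5e4, 90, 4), rnorm(5e4, 110, 4))
  })
  f <- fit_gaussian(x, 2)
  if (f$converged) expect_equal(f$center, 100, tolerance = 0.5)
})

test_that("fit comparisons report center shifts in reference sigmas and width ratios", {
  gf <- function(center, sigma) {
    structure(list(center = center, sigma = sigma, amplitude = 1,
                   bin_width = 2, n_samples = 1000, converged = TRUE),
              class = "gaussian_fit")
  }
  same <- compare_fits(gf(100, 4), gf(100, 4))
  expect_equal(same$delta_center, 0)
  expect_equal(same$delta_center_in_sigma, 0)
  expect_equal(same$width_ratio, 1)
  cmp <- compare_fits(gf(100, 4), gf(104, 8))
  expect_equal(cmp$delta_center, -4)
  expect_equal(cmp$delta_center_in_sigma, 0.5)
  expect_equal(cmp$width_ratio, 0.5)
  expect_equal(compare_fits(gf(0, 4), gf(0, 5))$width_ratio, 0.8)
  bad <- gf(0, 1); bad$converged <- FALSE
  expect_error(compare_fits(bad, gf(0, 1)), "converged")
})

test_that("equilibration ratio matches closed-form OLS and is scale invariant", {
  # pure ramp: slope equals total rise; sd of a ramp is analytic
  n <- 101L
  y <- seq(0, 5, length.out = n)
  r <- equilibration_ratio(y, n)
  expect_equal(r$slope, 5, tolerance = 1e-12)
  expect_equal(r$sd, sd(y), tolerance = 1e-12)
  expect_equal(r$sd_over_slope_ratio, sd(y) / 5)

  withr::with_seed(55, z <- rnorm(2000))
  rz <- equilibration_ratio(z, 1000)
  r10 <- equilibration_ratio(z * 10, 1000)
  expect_equal(rz$sd_over_slope_ratio, r10$sd_over_slope_ratio,
               tolerance = 1e-12)
  shifted <- equilibration_ratio(z + 100, 1000)
  expect_equal(rz$sd_over_slope_ratio, shifted$sd_over_slope_ratio,
               tolerance = 1e-9)
  # a zero-slope noisy series is dominated by fluctuation, not drift
  expect_gt(rz$sd_over_slope_ratio, 50)
  expect_error(equilibration_ratio(z, 2), "at least 3")
  expect_error(equilibration_ratio(z[1:10], 20), "exceeds")
  flat <- equilibration_ratio(c(1, 2, 1), 3)
  expect_true(is.infinite(flat$sd_over_slope_ratio))
})

test_that("beta-sheet slopes come out in residues per microsecond", {
  expect_equal(beta_slope(rep(118L, 10), 0.1)$slope_res_per_us, 0)
  # exact linear decline of 2 residues over 1 us
  counts <- round(seq(118, 116, length.out = 5))
  expect_equal(beta_slope(c(118, 117.5, 117, 116.5, 116) * 2,
                          0.25)$slope_res_per_us, -4)
  withr::with_seed(66, {
    noisy <- pmax(0, round(118 - 2.3 * seq(0, 1, length.out = 100) +
                             rnorm(100, 0, 1.5)))
  })
  bs <- beta_slope(noisy, 1 / 99)
  t_us <- (0:99) / 99
  oracle <- coef(lm(noisy ~ t_us))[[2]]
  expect_equal(bs$slope_res_per_us, oracle, tolerance = 1e-9)
  expect_error(beta_slope(c(1, 2), 0.1), "at least 3")
  expect_error(beta_slope(c(1, -2, 3), 0.1), "nonnegative")
})

test_that("identical trajectories compare with zero center shifts", {
  set.seed(77)
  # one oscillating dihedral sampled over many frames
  phis <- 100 + gen_ou_angle_series(0, 6, 0.3, 400, seed = 78)
  frames <- lapply(phis, frame_with_dihedral)
  traj <- make_traj(frames)
  defs <- list(angle_definition("phi", "dihedral", c("A", "B", "C", "D")))
  tab <- compare_angle_distributions(traj, traj, defs, bin_widths = 2)
  expect_equal(tab$delta_center, 0)
  expect_equal(tab$width_ratio, 1)
})
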
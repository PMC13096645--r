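test_that("compass bump matches the rectified cosine on the column grid", {
  cfg <- circuit_config()
  a <- encode_compass(0, 0, cfg)
  expect_equal(a$values,
               c(1, sqrt(2) / 2, 0, 0, 0, 0, 0, sqrt(2) / 2),
               tolerance = 1e-12)
  # exactly half the columns carry activity for an on-grid heading
  expect_equal(sum(a$values > 0), 3)
  off <- encode_compass(10, 0, cfg)
  expect_equal(sum(off$values > 0), 4)
  expect_equal(max(off$values), 1)
  expect_error(encode_compass(NaN), "finite")
})

test_that("a 3-cell rotation moves the bump peak to the 135-degree column", {
  a <- encode_compass(0, 3)
  expect_equal(which.max(a$values), 4)
  expect_equal(a$preferred[4], 135)
  expect_equal(celestial_rotation_cells(135), 3L)
  expect_equal(celestial_rotation_cells(-135), -3L)
  expect_equal(celestial_rotation_cells(0), 0L)
})

test_that("rotation by whole cells is equivariant with rotating the heading", {
  for (k in c(-3, -1, 0, 1, 2, 5, 8, 11)) {
    for (h in c(-120, 0, 37.5, 170)) {
      expect_equal(encode_compass(h + k * 45, 0)$values,
                   encode_compass(h, k)$values)
    }
  }
})

test_that("population-vector decoding inverts encoding", {
  withr::with_seed(101, {
    hs <- runif(200, -5000, 5000)
    # rectified cosine on an even grid: the frequency-2 alias cancels, so the
    # population vector is exact up to floating point
    cfg <- circuit_config()
    for (h in hs) {
      expect_lt(abs(wrap_deg(decode_compass(encode_compass(h, 0, cfg)) - h)), 1e-6)
    }
    # von-Mises kernel: aliasing of the +/-7 harmonic on 8 columns bounds the
    # decode error by 2 I_7(kappa) / I_1(kappa) radians
    kap <- 3
    cfgv <- circuit_config(bump_kernel = "vonmises", kernel_kappa = kap)
    bound <- 2 * besselI(kap, 7) / besselI(kap, 1) * 180 / pi
    for (h in hs[1:100]) {
      expect_lt(abs(wrap_deg(decode_compass(encode_compass(h, 0, cfgv)) - h)), bound)
    }
  })
})

test_that("decoding agrees with the brute-force circular mean on random activities", {
  withr::with_seed(7, {
    for (i in 1:100) {
      v <- runif(8)
      phi <- (0:7) * 45
      got <- decode_compass(v)
      want <- wrap_deg(oracle_circular_mean(v, phi))
      expect_lt(abs(wrap_deg(got - want)), 1e-6)
    }
  })
})

test_that("decoding rejects degenerate activity patterns", {
  expect_equal(decode_compass(c(0, 0, 1, 0, 0, 0, 0, 0)), 90)
  expect_error(decode_compass(rep(0, 8)), "all-zero")
  expect_error(decode_compass(rep(1, 8)), "resultant")
})

test_that("goal field decays by exactly (1 - lambda) per inputless update", {
  cfg <- circuit_config()           # decay 0.2
  g <- update_goal(goal_field(cfg), encode_compass(30), 1, 1, cfg)
  m0 <- sum(goal_combined(g))
  g1 <- update_goal(g, encode_compass(30), 0, 0, cfg)
  expect_equal(goal_combined(g1), goal_combined(g) * 0.8)
  g5 <- g
  for (i in 1:5) g5 <- update_goal(g5, encode_compass(-60), 0, 0, cfg)
  expect_equal(sum(goal_combined(g5)), m0 * 0.8^5)
})

test_that("lateralised input writes offset goal bumps with the correct sign", {
  cfg <- circuit_config(decay = 0)
  g <- update_goal(goal_field(cfg), encode_compass(0), 1, 0, cfg)
  expect_equal(decode_compass(g$left), -45)
  expect_equal(sum(g$right), 0)
  g <- update_goal(goal_field(cfg), encode_compass(0), 0, 1, cfg)
  expect_equal(decode_compass(g$right), 45)
  expect_error(update_goal(goal_field(cfg), encode_compass(0), 1.2, 0, cfg), "f_left")
  expect_error(update_goal(goal_field(cfg), encode_compass(0), 0, -0.1, cfg), "f_right")
})

test_that("constant input converges to the geometric-series amplitude", {
  cfg <- circuit_config()           # decay 0.2
  cmp <- encode_compass(0, 0, cfg)
  c_in <- 0.6
  g <- goal_field(cfg)
  for (i in 1:50) g <- update_goal(g, cmp, c_in, 0, cfg)
  want_amp <- oracle_goal_amplitude(c_in, cfg$decay, 50)
  expect_equal(max(g$left), want_amp, tolerance = 1e-9)
  # within 1% of the infinite-horizon limit c / lambda
  expect_lt(abs(max(g$left) - c_in / cfg$decay) / (c_in / cfg$decay), 0.01)
  # the bank shape is the shifted compass bump, uniformly scaled
  expect_equal(decode_compass(g$left), -45)
})

test_that("steering is null at the goal, signed toward it, and antisymmetric", {
  cfg <- circuit_config()
  cmp <- encode_compass(0, 0, cfg)
  g_aligned <- update_goal(goal_field(cfg), encode_compass(0), 1, 1, cfg)
  expect_equal(steer(g_aligned, cmp, cfg, noise = 0)$turn_deg, 0)

  # goal 90 degrees clockwise of the heading: expect a right (positive) turn
  g_right <- goal_field(cfg)
  g_right$left <- encode_compass(90, 0, cfg)$values
  st <- steer(g_right, cmp, cfg, noise = 0)
  expect_gt(st$turn_deg, 0)
  # and symmetrically for a goal counter-clockwise of the heading
  g_left <- goal_field(cfg)
  g_left$left <- encode_compass(-90, 0, cfg)$values
  expect_lt(steer(g_left, cmp, cfg, noise = 0)$turn_deg, 0)

  # swapping the left and right inputs mirrors the written goal about the
  # heading and negates the noise-free turn command
  withr::with_seed(3, {
    for (i in 1:20) {
      h <- runif(1, -180, 180)
      ab <- runif(2)
      cmp_h <- encode_compass(h, 0, cfg)
      g <- update_goal(goal_field(cfg), cmp_h, ab[1], ab[2], cfg)
      g_sw <- update_goal(goal_field(cfg), cmp_h, ab[2], ab[1], cfg)
      expect_equal(steer(g, cmp_h, cfg, noise = 0)$turn_deg,
                   -steer(g_sw, cmp_h, cfg, noise = 0)$turn_deg,
                   tolerance = 1e-9)
    }
  })
})

test_that("an empty goal field yields noise-only turning", {
  cfg <- circuit_config()           # motor noise 10 deg/step
  cmp <- encode_compass(20, 0, cfg)
  draws <- withr::with_seed(11, {
    vapply(1:10000, function(i) steer(goal_field(cfg), cmp, cfg)$turn_deg, numeric(1))
  })
  se <- 10 / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
  expect_equal(sd(draws), 10, tolerance = 0.05)
  expect_true(all(abs(draws) <= cfg$turn_cap))
})

test_that("a noise-free agent with a fixed goal homes in monotonically", {
  cfg <- circuit_config(motor_noise_sd = 0)
  g <- goal_field(cfg)
  g$left <- encode_compass(0, 0, cfg)$values
  # any start except the antipodal unstable equilibrium
  for (start in c(-170, -135, -90, -45, 30, 90, 135, 170)) {
    h <- start
    errs <- numeric(50)
    for (t in 1:50) {
      st <- steer(g, encode_compass(h, 0, cfg), cfg, noise = 0)
      h <- wrap_deg(h + st$turn_deg)
      errs[t] <- abs(wrap_deg(h))
    }
    expect_true(all(diff(c(abs(start), errs)) <= 1e-9))
    expect_lt(errs[50], cfg$column_spacing)
  }
})

test_that("circuit configuration invariants are enforced", {
  expect_error(circuit_config(n_columns = 5), "even")
  expect_error(circuit_config(n_columns = 2), "even")
  expect_error(circuit_config(decay = 1.2), "decay")
  expect_error(circuit_config(motor_noise_sd = -1), "motor_noise_sd")
  expect_equal(circuit_config(n_columns = 12)$column_spacing, 30)
})
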
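test_that("turn ratio handles pure, balanced, and silent traces", {
  t12 <- seq(0, 12, by = 0.1)
  expect_equal(turn_ratio(data.frame(time = t12, omega = rep(10, length(t12)))), 1)
  balanced <- data.frame(time = 0:12, omega = c(rep(10, 6), 0, rep(-10, 6)))
  expect_equal(turn_ratio(balanced), 0)
  expect_equal(turn_ratio(data.frame(time = 0:5, omega = rep(0, 6))), 0)
})

test_that("turn ratio at 10 Hz matches a dense-grid quadrature oracle", {
  f <- function(t) sin(t) + 0.3
  tt <- seq(0, 12, by = 0.1)
  got <- turn_ratio(data.frame(time = tt, omega = f(tt)))
  want <- oracle_turn_ratio(f, 0, 12)
  expect_lt(abs(got - want), 1e-3)
  # a second waveform with more crossings; tolerance from the trapezoid
  # error bound (b - a) h^2 |f''| / 12 on each integral relative to |omega|
  g <- function(t) cos(3 * t) - 0.2
  got2 <- turn_ratio(data.frame(time = tt, omega = g(tt)))
  expect_lt(abs(got2 - oracle_turn_ratio(g, 0, 12)), 12 * 0.1^2 * 9 / 12 / 5)
})

test_that("turn ratio is antisymmetric and bounded", {
  withr::with_seed(33, {
    for (i in 1:30) {
      tr <- data.frame(time = cumsum(runif(40, 0.05, 0.2)),
                       omega = rnorm(40, sd = 15))
      r <- turn_ratio(tr)
      expect_true(r >= -1 && r <= 1)
      flipped <- tr
      flipped$omega <- -flipped$omega
      expect_equal(turn_ratio(flipped), -r)
    }
  })
})

test_that("preferred-side proportion counts turning time on the larger side", {
  all_right <- data.frame(time = 0:12, omega = rep(5, 13))
  expect_equal(preferred_side_proportion(all_right), 1)
  # 9 s right, 3 s left, with a zero sample at the switch
  mixed <- data.frame(time = 0:12, omega = c(rep(10, 9), 0, rep(-10, 3)))
  expect_equal(preferred_side_proportion(mixed), 0.75)
  flipped <- mixed
  flipped$omega <- -flipped$omega
  expect_equal(preferred_side_proportion(flipped), 0.75)
  expect_equal(preferred_side_proportion(data.frame(time = 0:3, omega = rep(0, 4))), 0.5)
})

test_that("path discretisation places vertices at exact arc lengths", {
  straight <- data.frame(x = seq(0, 36, by = 0.5), y = 0)
  seg <- discretise_path(straight, 12)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$s, c(0, 12, 24, 36))
  expect_true(all(seg$turn_angle[c(-1, -4)] == 0))
  # right-angle elbow, arms 24 each, L = 12: one 90-degree junction
  elbow <- data.frame(x = c(0, 24, 24), y = c(0, 0, 24))
  se <- discretise_path(elbow, 12)
  expect_equal(nrow(se), 5)
  turns <- se$turn_angle[!is.na(se$turn_angle)]
  expect_equal(sort(turns), c(0, 0, 90))
  expect_error(discretise_path(data.frame(x = c(0, 5), y = c(0, 0)), 12), "too short")
})

test_that("arc-length bookkeeping is exact on random walks", {
  withr::with_seed(44, {
    for (i in 1:20) {
      n <- 150
      ang <- cumsum(rnorm(n, sd = 25))
      path <- data.frame(x = cumsum(cos_deg(ang)), y = cumsum(sin_deg(ang)))
      total <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
      L <- runif(1, 2, 8)
      if (total < 2 * L) next
      seg <- discretise_path(path, L)
      spacing <- sqrt(diff(seg$x)^2 + diff(seg$y)^2)
      # vertices sit at cumulative arc lengths 0, L, 2L, ... exactly
      expect_equal(seg$s, (seq_len(nrow(seg)) - 1) * L, tolerance = 1e-9)
      expect_equal(nrow(seg) - 1, floor(total / L))
      expect_true(all(spacing <= L + 1e-9))
      # rebuild the polyline from the first vertex, bearings and spacings
      rx <- seg$x[1] + c(0, cumsum(spacing * cos_deg(seg$bearing[-nrow(seg)])))
      ry <- seg$y[1] + c(0, cumsum(spacing * sin_deg(seg$bearing[-nrow(seg)])))
      expect_equal(rx, seg$x, tolerance = 1e-9)
      expect_equal(ry, seg$y, tolerance = 1e-9)
    }
  })
})

test_that("directional error is exact on cardinal cases and rotation invariant", {
  p <- function(xe, ye) data.frame(x = c(0, xe), y = c(0, ye))
  expect_equal(directional_error(p(5, 0), 0), 0)
  expect_equal(directional_error(p(-3, 0), 0), 180)
  expect_equal(directional_error(p(2, 2), 0), 45)
  expect_error(directional_error(p(0, 0), 0), "coincide")
  withr::with_seed(55, {
    for (i in 1:25) {
      path <- data.frame(x = cumsum(rnorm(30)), y = cumsum(rnorm(30)))
      goal <- runif(1, -180, 180)
      rot <- runif(1, -180, 180)
      r <- rot * pi / 180
      rotated <- data.frame(x = cos(r) * path$x - sin(r) * path$y,
                            y = sin(r) * path$x + cos(r) * path$y)
      expect_equal(directional_error(rotated, goal + rot),
                   directional_error(path, goal), tolerance = 1e-9)
    }
  })
})

test_that("circular mean and SE behave on symmetric and degenerate inputs", {
  cm <- circular_mean_se(c(10, 350))
  expect_equal(cm$mean, 0)
  same <- circular_mean_se(c(72, 72, 72))
  expect_equal(same$se, 0)
  expect_error(circular_mean_se(c(0, 180)), "resultant|undefined")
  expect_error(circular_mean_se(5), "at least 2")
  # ids average within individual first
  cm_id <- circular_mean_se(c(0, 0, 0, 90, 90), ids = c(1, 1, 1, 2, 2))
  expect_equal(cm_id$mean, 45)
  expect_equal(cm_id$n, 2)
})

test_that("the circular mean covers the generating direction", {
  hits <- withr::with_seed(66, {
    vapply(1:1000, function(i) {
      mu <- runif(1, -180, 180)
      a <- wrap_deg(mu + rnorm(40, sd = 30))   # wrapped-normal sample
      cm <- circular_mean_se(a)
      abs(wrap_deg(cm$mean - mu)) < 3 * cm$se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.99)
})

test_that("exact signed-rank p-values match full enumeration and known values", {
  # six positive values, one-sided: exactly 1 / 2^6
  expect_equal(signed_rank_exact(c(3, 1, 4, 1.5, 5, 9), "greater")$p, 1 / 64)
  expect_equal(signed_rank_exact(c(3, 1, 4, 1.5, 5, 9), "greater")$p, 0.015625)
  expect_equal(signed_rank_exact(5, "greater")$p, 0.5)
  # zeros are dropped before ranking
  expect_equal(signed_rank_exact(c(0, 0, 2, 3), "greater")$n, 2)
  expect_error(signed_rank_exact(c(0, 0)), "zero")
  withr::with_seed(88, {
    for (i in 1:25) {
      n <- sample(2:10, 1)
      v <- round(rnorm(n, 0.3), sample(c(0, 1), 1))   # ties likely
      v <- v[v != 0]
      if (length(v) == 0) next
      for (alt in c("greater", "less", "two_sided")) {
        expect_equal(signed_rank_exact(v, alt)$p, oracle_signed_rank(v, alt))
      }
    }
  })
})

test_that("signed-rank agrees with the reference exact distribution", {
  # stats::wilcox.test as an independent cross-check (no ties, no zeros)
  withr::with_seed(99, {
    for (i in 1:10) {
      v <- rnorm(10, 0.4)
      expect_equal(signed_rank_exact(v, "greater")$p,
                   wilcox.test(v, alternative = "greater", exact = TRUE)$p.value)
      expect_equal(signed_rank_exact(v, "two_sided")$p,
                   wilcox.test(v, alternative = "two.sided", exact = TRUE)$p.value)
    }
  })
  # two-sided is twice the smaller one-sided tail, capped at 1
  v <- c(1.5, -2, 3, -0.5, 2.5, 1)
  pg <- signed_rank_exact(v, "greater")$p
  pl <- signed_rank_exact(v, "less")$p
  expect_equal(signed_rank_exact(v, "two_sided")$p, min(1, 2 * min(pg, pl)))
})
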
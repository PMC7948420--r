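test_that("integration recovers analytic areas on clean signals", {
  rt <- seq(0, 30, by = 0.002)
  pulse <- ifelse(rt >= 10 & rt <= 11, 100, 0)
  expect_equal(integrate_peak(chromatogram_trace(rt, pulse))$area, 100,
               tolerance = 0.01)
  # Gaussian with analytic area 500
  y <- 500 / (0.2 * sqrt(2 * pi)) * exp(-(rt - 15)^2 / (2 * 0.2^2))
  p <- integrate_peak(chromatogram_trace(rt, y))
  expect_equal(p$area, 500, tolerance = 0.01)
  expect_equal(p$rt_apex, 15, tolerance = 0.05)
  expect_true(p$rt_start < p$rt_apex && p$rt_apex < p$rt_end)
  flat <- integrate_peak(chromatogram_trace(rt, rep(0, length(rt))))
  expect_equal(flat$area, 0)
  expect_true(flat$empty)
})

test_that("an explicit rt window overrides bound detection", {
  rt <- seq(0, 30, by = 0.01)
  y <- 200 / (0.2 * sqrt(2 * pi)) * exp(-(rt - 10)^2 / (2 * 0.2^2)) +
    300 / (0.2 * sqrt(2 * pi)) * exp(-(rt - 20)^2 / (2 * 0.2^2))
  p1 <- integrate_peak(chromatogram_trace(rt, y), rt_window = c(8, 12))
  expect_equal(p1$area, 200, tolerance = 0.02)
  p2 <- integrate_peak(chromatogram_trace(rt, y), rt_window = c(18, 22))
  expect_equal(p2$area, 300, tolerance = 0.02)
})

test_that("occupancy arithmetic and scale invariance", {
  expect_equal(occupancy(1, 3), 0.25)
  expect_equal(occupancy(0, 5), 0)
  expect_true(is.na(occupancy(0, 0)))
  expect_true(attr(occupancy(0, 0), "undefined"))
  expect_error(occupancy(-1, 2), "non-negative")
  set.seed(4)
  for (k in 1:10) {
    a <- runif(2, 0, 100); c0 <- runif(1, 0.01, 50)
    expect_equal(occupancy(a[1], a[2]), occupancy(c0 * a[1], c0 * a[2]))
  }
})

test_that("planted occupancies are recovered from trace pairs", {
  p <- gen_xic_pair(0.25, noise_sigma = 0, seed = 2)
  occ <- occupancy(integrate_peak(p$modified)$area,
                   integrate_peak(p$unmodified)$area)
  expect_equal(as.numeric(occ), 0.25, tolerance = 0.01)
  p0 <- gen_xic_pair(0, noise_sigma = 0.05, seed = 3)
  expect_false(any(abs(p0$modified$intensity) == 0)) # pure noise, not blank
  occ0 <- occupancy(integrate_peak(p0$modified)$area,
                    integrate_peak(p0$unmodified)$area)
  expect_lt(as.numeric(occ0), 0.02)
  errs <- vapply(1:25, function(s) {
    p <- gen_xic_pair(0.2, noise_sigma = 0.05, seed = s)
    as.numeric(occupancy(integrate_peak(p$modified)$area,
                         integrate_peak(p$unmodified)$area)) - 0.2
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.03)
})

test_that("isobaric peaks are assigned to nearest expected retention times", {
  rt <- seq(0, 30, by = 0.01)
  two <- 100 * exp(-(rt - 10)^2 / (2 * 0.1^2)) +
    80 * exp(-(rt - 20)^2 / (2 * 0.1^2))
  asg <- disambiguate_isobaric(chromatogram_trace(rt, two), c(10, 20))
  expect_equal(nrow(asg), 2)
  expect_equal(asg$assigned, c(1L, 2L))
  expect_false(any(asg$ambiguous))
  # symmetric tie is flagged
  one <- 100 * exp(-(rt - 15)^2 / (2 * 0.1^2))
  tie <- disambiguate_isobaric(chromatogram_trace(rt, one), c(10, 20))
  expect_true(tie$ambiguous)
  expect_true(is.na(tie$assigned))
  # out-of-tolerance peak flagged
  far <- disambiguate_isobaric(chromatogram_trace(rt, one), c(3, 27),
                               tol_min = 0.5)
  expect_true(far$ambiguous)
  # three planted peaks recovered in order
  three <- 100 * exp(-(rt - 5)^2 / (2 * 0.1^2)) +
    90 * exp(-(rt - 12)^2 / (2 * 0.1^2)) +
    110 * exp(-(rt - 22)^2 / (2 * 0.1^2))
  asg3 <- disambiguate_isobaric(chromatogram_trace(rt, three),
                                c(5.1, 11.9, 22.2))
  expect_equal(asg3$assigned, c(1L, 2L, 3L))
  expect_warning(
    disambiguate_isobaric(chromatogram_trace(rt, three), c(5.1, 11.9)),
    "more detected peaks")
})

test_that("methylation distributions normalize and flag ablation", {
  expect_equal(unname(methylation_distribution(c(100, 100, 100, 100))$fractions),
               rep(0.25, 4))
  d <- methylation_distribution(c(100, 100, 200, 0))
  expect_equal(unname(d$fractions), c(0.25, 0.25, 0.5, 0))
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
  ko <- methylation_distribution(c(0, 0, 0, 0))
  expect_true(ko$all_absent)
  # permutation of state labels permutes fractions identically
  a <- c(40, 15, 15, 30)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(methylation_distribution(a[perm])$fractions),
               unname(methylation_distribution(a)$fractions[perm]))
  # planted distribution recovered from integrated traces
  target <- c(0.40, 0.15, 0.15, 0.30)
  areas <- vapply(1:4, function(i) {
    tr <- gen_xic_pair(1, total_area = target[i] * 5000, noise_sigma = 0.05,
                       seed = 30 + i)$modified
    integrate_peak(tr)$area
  }, numeric(1))
  got <- methylation_distribution(areas)$fractions
  expect_lt(max(abs(got - target)), 0.02)
})
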
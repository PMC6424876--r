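test_that("grid_spec validates extents, spacing and roi", {
  g <- grid_spec(c(8, 8))
  expect_s3_class(g, "pace_grid")
  expect_equal(sum(g$roi), 64)
  expect_error(grid_spec(c(1, 8)), "extents")
  expect_error(grid_spec(c(8, 8), spacing = 0), "spacing")
  expect_error(grid_spec(c(4, 4), roi = matrix(FALSE, 4, 4)), "at least one")
  expect_error(grid_spec(c(4, 4), roi = matrix(TRUE, 3, 3)), "dimensions")
})

test_that("a single central Gaussian peak has its stated maximum", {
  g <- grid_spec(c(17, 17))
  m <- pace:::gaussian_sum_map(g, centers = matrix(c(9, 9), 1),
                               sigmas = 0.2 * 17, amplitudes = 1)
  expect_equal(max(m), 1.0)
  expect_equal(which(m == max(m)), 9 + (9 - 1) * 17)
})

test_that("two-Gaussian map matches an independent per-voxel loop oracle", {
  g <- grid_spec(c(16, 16))
  centers <- rbind(c(4.3, 11.2), c(12.8, 5.5))
  sig <- c(2.1, 3.7); amp <- c(0.8, 1.3)
  m <- pace:::gaussian_sum_map(g, centers, sig, amp)
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    for (k in 1:2) {
      d2 <- (i - centers[k, 1])^2 + (j - centers[k, 2])^2
      oracle[i, j] <- oracle[i, j] + amp[k] * exp(-d2 / (2 * sig[k]^2))
    }
  }
  expect_equal(m, oracle)
  expect_equal(mean(m), mean(oracle))
})

test_that("dose-map simulation is bit-reproducible under a fixed seed", {
  a <- simulate_dose_maps(5, grid_spec(c(12, 12)), seed = 42)
  b <- simulate_dose_maps(5, grid_spec(c(12, 12)), seed = 42)
  expect_identical(a$dose, b$dose)
  expect_true(all(vapply(a$dose, min, numeric(1)) >= 0))
})

test_that("DVH equalization gives every map one flat DVH, preserving order", {
  maps <- simulate_dose_maps(4, grid_spec(c(10, 10)), seed = 3)$dose
  eq <- equalize_dvh(maps, d_max = 2)
  sorted <- lapply(eq, function(m) sort(as.vector(m)))
  expect_equal(sorted[[1]], sorted[[2]])
  expect_equal(sorted[[2]], sorted[[3]])
  expect_equal(sorted[[1]], 2 * (1:100) / 100)
  # spatial ordering of voxels by dose is preserved
  expect_equal(order(maps[[1]]), order(eq[[1]]))
  # already-uniform map is a fixed point up to grid quantization
  u <- matrix((1:100) / 100, 10, 10)
  expect_equal(equalize_dvh(list(u), d_max = 1)[[1]], u)
  expect_error(equalize_dvh(list(matrix(1, 10, 10))), "constant")
})

test_that("3-voxel rank transform follows the stated plotting positions", {
  g <- grid_spec(3)
  m <- array(c(5, 1, 3), dim = 3)
  eq <- equalize_dvh(list(m), d_max = 1, grid = g)[[1]]
  expect_equal(as.vector(eq), c(1, 1 / 3, 2 / 3))
})

test_that("RS maps: homogeneous is 1 on the ROI; s2g matches brute force", {
  g <- grid_spec(c(8, 8))
  h <- make_rs_map(g, "homogeneous")
  expect_true(all(h[g$roi] == 1))
  centers <- rbind(c(0.25, 0.25), c(0.75, 0.75))
  s <- make_rs_map(g, "s2g", centers = centers, sigmas = c(0.15, 0.15),
                   amplitudes = c(1, 0.6))
  cvox <- centers * 8 + 0.5
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) for (k in 1:2) {
    d2 <- (i - cvox[k, 1])^2 + (j - cvox[k, 2])^2
    oracle[i, j] <- oracle[i, j] +
      c(1, 0.6)[k] * exp(-d2 / (2 * (0.15 * 8)^2))
  }
  expect_equal(s, oracle)
  # equal amplitudes, symmetric centers -> symmetric under the point
  # reflection exchanging the two centers
  ssym <- make_rs_map(g, "s2g")
  expect_equal(ssym, ssym[8:1, 8:1])
  expect_error(make_rs_map(g, "banana"))
})

test_that("g2eud obeys its fixed points, hand value and reductions", {
  g <- grid_spec(c(4, 4))
  rs <- make_rs_map(g, "s2g")
  u <- matrix(0.7, 4, 4)
  for (n in c(0.05, 0.5, 1, 2)) {
    expect_equal(g2eud(u, rs, n), 0.7)
  }
  # hand evaluation: (1*4^2 + 3*16^2)/4 = 196 -> 14 exactly
  expect_equal(g2eud(matrix(c(4, 16), 1, 2), matrix(c(1, 3), 1, 2), 0.5), 14)
  # homogeneous RS reduces exactly to the standard gEUD
  d <- generate_dose_map(g); set.seed(2); d <- generate_dose_map(g)
  hom <- make_rs_map(g, "homogeneous")
  for (n in c(0.1, 0.37, 1)) {
    expect_equal(g2eud(d, hom, n), geud(d, n))
  }
  # n = 1: exactly the RS-weighted mean dose
  expect_equal(g2eud(d, rs, 1), sum(d * rs) / sum(rs))
  expect_error(g2eud(d, rs, 0), "n must be")
  expect_error(g2eud(d, matrix(0, 4, 4), 0.5), "zero")
})

test_that("g2eud is monotone nondecreasing in every voxel dose", {
  set.seed(9)
  g <- grid_spec(c(5, 5))
  rs <- make_rs_map(g, "s2g")
  d <- generate_dose_map(g)
  for (n in c(0.1, 1, 3)) {
    base <- g2eud(d, rs, n)
    for (v in sample(25, 5)) {
      d2 <- d; d2[v] <- d2[v] + 0.5
      expect_gte(g2eud(d2, rs, n), base - 1e-12)
    }
  }
})

test_that("thresholding: strict inequality and target event rates", {
  expect_equal(label_outcomes(c(0.2, 0.9), 0.5), c(0L, 1L))
  expect_equal(label_outcomes(rep(0.5, 4), 0.5), rep(0L, 4))
  th <- choose_threshold(c(1, 2, 3, 4), 0.5)
  expect_true(th >= 2 && th < 3)
  expect_equal(sum(label_outcomes(c(1, 2, 3, 4), th)), 2)
  # quantile property at scale: event rate within 1/N of target
  set.seed(4)
  gv <- rexp(1000)
  for (q in c(0.18, 0.25, 0.5)) {
    thq <- choose_threshold(gv, q)
    expect_lte(abs(mean(gv > thq) - q), 1 / 1000 + 1e-12)
  }
  # 98-patient clinical-scale event count: 18 +/- 1 events at rate 0.18
  g98 <- rexp(98)
  th98 <- choose_threshold(g98, 0.18)
  expect_lte(abs(sum(g98 > th98) - 0.18 * 98), 1)
  expect_error(choose_threshold(rep(1, 5), 0.3), "degenerate")
  expect_error(choose_threshold(1:5, 0), "target_event_rate")
})

test_that("simulate_cohort labels outcomes consistently with its threshold", {
  co <- tiny_s2g_cohort(n = 30, seed = 21)
  th <- attr(co, "d_th")
  expect_equal(co$outcome, as.integer(co$g2eud > th))
  expect_true(all(co$outcome %in% 0:1))
  rs <- attr(co, "rs_map")
  g <- attr(co, "grid")
  recomputed <- vapply(co$dose, g2eud, numeric(1), rs = rs, n = 0.3, grid = g)
  expect_equal(recomputed, co$g2eud)
})

test_that("equalized cohorts share identical gEUD for any exponent", {
  # (homogeneous RS would make equalized maps indistinguishable: the
  # g2EUD distribution degenerates and threshold choice errors out)
  expect_error(
    simulate_cohort(6, grid_spec(c(10, 10)), equalize = TRUE,
                    event_rate = 0.5, seed = 8),
    "degenerate"
  )
  co <- simulate_cohort(6, grid_spec(c(10, 10)), equalize = TRUE,
                        rs = make_rs_map(c(10, 10), "s2g"),
                        event_rate = 0.5, seed = 8)
  for (n in c(0.05, 0.3, 1)) {
    g <- vapply(co$dose, geud, numeric(1), n = n)
    expect_lt(diff(range(g)), 1e-12)
  }
})
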
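test_that("repeatability coefficient matches hand arithmetic and is scale-free", {
  expect_equal(repeatability_coefficient(data.frame(q1 = 5, q2 = 5, q3 = 5)), 0)
  # (4.8, 5.0, 5.2): sd 0.2, mean 5 -> CV 0.04 -> 1.96*sqrt(2)*0.04
  r <- repeatability_coefficient(data.frame(q1 = 4.8, q2 = 5.0, q3 = 5.2))
  expect_equal(r, 0.1108743433, tolerance = 1e-9)
  tri <- data.frame(q1 = c(4.8, 3.1), q2 = c(5.0, 3.0), q3 = c(5.2, 3.3))
  expect_equal(repeatability_coefficient(tri),
               repeatability_coefficient(tri * 10), tolerance = 1e-12)
  expect_error(repeatability_coefficient(
    data.frame(q1 = 1, q2 = 0, q3 = -1)), "positive")
})

test_that("interchangeability applies the maximal acceptable difference", {
  p <- make_pairs(q_t = c(5.0, 4.0, 6.0), q_ist = c(5.5, 5.0, 6.0))
  res <- interchangeability(p, r_qt = 0.10)
  # pair 1: threshold 5.25*0.1*sqrt(2) = 0.742 > 0.5 -> interchangeable
  expect_equal(res$threshold[1], 5.25 * 0.1 * sqrt(2), tolerance = 1e-12)
  expect_true(res$interchangeable[1])
  # identical values always interchangeable for positive R_QT
  expect_true(res$interchangeable[3])
  res2 <- interchangeability(make_pairs(4.0, 5.0), r_qt = 0.05)
  expect_false(res2$interchangeable)  # threshold 0.318 < 1.0
  # rate is invariant to rescaling all flows
  p10 <- p; p10$q_t_lmin <- p10$q_t_lmin * 10; p10$q_ist_lmin <- p10$q_ist_lmin * 10
  expect_equal(interchangeability(p10, 0.1)$rate, res$rate)
})

test_that("repeated-measures Bland-Altman matches a hand variance decomposition", {
  p <- rbind(make_pairs(q_t = c(5, 5, 5), q_ist = c(5.5, 5.7, 5.9),
                        subject_id = 1L),
             make_pairs(q_t = c(4, 4), q_ist = c(3.9, 4.1), subject_id = 2L))
  ba <- bland_altman(p)
  # d: (0.5,0.7,0.9 | -0.1,0.1); subject means 0.7, 0
  # between = var(c(0.7,0)) = 0.245; within = (0.04+0.02)/2 = 0.03
  expect_equal(ba$bias, 0.42)
  expect_equal(ba$sd_adj, sqrt(0.275), tolerance = 1e-10)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sqrt(0.275),
               tolerance = 1e-10)
  # bias CI from subject means: 0.35 +/- qt(.975,1)*sd(c(.7,0))/sqrt(2)
  expect_equal(ba$bias_ci,
               0.42 + c(-1, 1) * qt(0.975, 1) * sd(c(0.7, 0)) / sqrt(2),
               tolerance = 1e-10)
})

test_that("identical methods give zero bias and zero-width limits", {
  p <- rbind(make_pairs(c(4, 5, 6), c(4, 5, 6), 1L),
             make_pairs(c(3, 5), c(3, 5), 2L))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 0)
  # a constant offset is reproduced exactly with zero-width limits
  p$q_ist_lmin <- p$q_t_lmin + 0.79
  ba2 <- bland_altman(p)
  expect_equal(ba2$bias, 0.79)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)
})

test_that("adjusted limits exceed pooled limits under between-subject heterogeneity", {
  p <- rbind(make_pairs(q_t = c(5, 5, 5), q_ist = c(5.5, 5.7, 5.9), 1L),
             make_pairs(q_t = c(4, 4), q_ist = c(3.9, 4.1), 2L))
  d <- p$q_ist_lmin - p$q_t_lmin
  expect_gt(bland_altman(p)$sd_adj, sd(d))
})

test_that("per-subject constant offsets cancel in the delta-from-baseline analysis", {
  # each animal has its own offset; differences from baseline agree exactly
  p <- rbind(make_pairs(c(4, 3.5, 6), c(4, 3.5, 6) + 1.2, 1L),
             make_pairs(c(5, 4.2, 7), c(5, 4.2, 7) - 0.8, 2L))
  ba <- bland_altman(p, mode = "delta")
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 0, tolerance = 1e-12)
})

test_that("delta computation enumerates consecutive and baseline changes", {
  p <- make_pairs(q_t = c(4, 5, 4.5), q_ist = c(4.2, 5.4, 4.0))
  d_prev <- delta_pairs(p, reference = "previous")
  expect_equal(nrow(d_prev), 2)                 # 3 pairs -> 2 deltas
  expect_equal(d_prev$dq_t, c(1, -0.5))
  expect_equal(d_prev$dq_ist, c(1.2, -1.4))
  expect_equal(d_prev$radius, (d_prev$dq_t + d_prev$dq_ist) / 2)
  d_base <- delta_pairs(p, reference = "baseline")
  expect_equal(d_base$dq_t, c(0, 1, 0.5))
  # constant series: all deltas zero
  expect_true(all(delta_pairs(make_pairs(rep(5, 4), rep(6, 4)))$dq_t == 0))
  # percent scale divides by the subject baseline
  d_pct <- delta_pairs(p, reference = "previous", scale = "percent")
  expect_equal(d_pct$dq_t, c(1, -0.5) / 4 * 100)
  expect_equal(d_pct$dq_ist, c(1.2, -1.4) / 4.2 * 100)
})

test_that("four-quadrant concordance matches hand enumeration with exclusion", {
  # mean_q 5, 15% zone -> |radius| >= 0.75; 10 changes: 2 inside the zone,
  # 1 discordant among the 8 kept -> 7/8 concordant
  d <- make_deltas(
    dq_t  = c(1,  2, -1, 1.5, -2,  1,  2,  2,  0.5, -0.3),
    dq_ist = c(1, 1.8, -1.2, 1, -2, 0.8, 2.2, -0.4, 0.5, -0.2))
  fq <- four_quadrant(d, mean_q = 5)
  expect_equal(fq$n_included, 8)
  expect_equal(fq$concordance, 100 * 7 / 8)
  expect_equal(fq$exclusion_threshold, 0.75)
  # perfect agreement and perfect disagreement
  ident <- make_deltas(c(1, -2, 3), c(1, -2, 3))
  expect_equal(four_quadrant(ident, 5)$concordance, 100)
  expect_equal(four_quadrant(ident, 5)$slope, 1)
  expect_equal(four_quadrant(ident, 5)$r, 1)
  opp <- make_deltas(c(2, -3, 4), c(-2, 3, -4))
  # opposite-sign changes have radius 0 and would all be excluded; widen
  expect_equal(four_quadrant(opp, 5, exclusion_pct = 0)$concordance, 0)
  expect_true(four_quadrant(make_deltas(0.1, 0.1), 5)$empty)
})

test_that("polar angles follow the half-circle geometry", {
  d <- make_deltas(c(1, 1, -1), c(1, 0, -1))
  pa <- polar_analysis(d, mean_q = 1, exclusion_pct = 0)
  expect_equal(pa$angles[1], 0)       # (1,1): on the polar axis
  expect_equal(pa$angles[2], -45)     # (1,0)
  expect_equal(pa$angles[3], 0)       # (-1,-1) reflects onto (1,1)
  expect_true(all(pa$angles > -90 & pa$angles <= 90))
  # identical methods: zero bias, full concordance at any exclusion
  ident <- make_deltas(c(1, -2, 3, 2), c(1, -2, 3, 2))
  pa2 <- polar_analysis(ident, mean_q = 5, exclusion_pct = 15)
  expect_equal(pa2$angular_bias, 0)
  expect_equal(pa2$polar_concordance, 100)
  expect_equal(four_quadrant(ident, 5, 15)$concordance, 100)
})

test_that("TIM separates interpretable changes and classifies them by the boundary lines", {
  # R_QT = 0.1; reference 4 -> 6 has disjoint CIs [3.6,4.4], [5.4,6.6]
  p1 <- make_pairs(q_t = c(4, 6), q_ist = c(4, 6))
  t1 <- tim_classify(p1, 0.1)
  expect_equal(as.character(t1$classes), "interchangeable")
  # 4 -> 4.5: CIs [3.6,4.4] and [4.05,4.95] overlap -> uninterpretable
  t2 <- tim_classify(make_pairs(c(4, 4.5), c(4, 9)), 0.1)
  expect_equal(as.character(t2$classes), "uninterpretable")
  # boundary arithmetic, anchored at (4, 4): X in [Y*0.9, Y*1.1]
  expect_equal(as.character(tim_classify(
    make_pairs(c(4, 6), c(4, 5)), 0.1)$classes), "uncertain")
  # 6 vs predicted band from q_ist2 = 4: [3.6, 4.4]; own CI [5.4, 6.6]
  expect_equal(as.character(tim_classify(
    make_pairs(c(4, 6), c(4, 4)), 0.1)$classes), "non-interchangeable")
  expect_error(tim_classify(make_pairs(c(4, -6), c(4, 6)), 0.1), "positive")
})

test_that("TIM fractions partition all consecutive changes", {
  set.seed(5)
  p <- do.call(rbind, lapply(1:4, function(s)
    make_pairs(runif(6, 3, 8), runif(6, 3, 8), subject_id = s)))
  res <- tim_classify(p, 0.08)
  expect_equal(res$n_changes, 4 * 5)
  expect_equal(sum(res$fractions), 100)
  expect_false(anyNA(res$classes))
  # the symmetric boundary variant is accepted and still partitions
  expect_equal(sum(tim_classify(p, 0.08, boundary = "symmetric")$fractions),
               100)
})

test_that("linear regression matches the hand normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- 2 * x + 1
  lr <- linear_regression(x, y)
  expect_equal(lr$slope, 2); expect_equal(lr$intercept, 1)
  expect_equal(lr$r, 1)
  # hand 5-point set: solve normal equations directly
  x2 <- c(0.5, 1.2, 2.0, 3.1, 4.4); y2 <- c(1.0, 1.8, 2.1, 3.9, 4.2)
  sl <- sum((x2 - mean(x2)) * (y2 - mean(y2))) / sum((x2 - mean(x2))^2)
  lr2 <- linear_regression(x2, y2)
  expect_equal(lr2$slope, sl, tolerance = 1e-12)
  expect_equal(lr2$intercept, mean(y2) - sl * mean(x2), tolerance = 1e-12)
  set.seed(11)
  expect_lt(abs(linear_regression(rnorm(1e4), rnorm(1e4))$r), 0.05)
  expect_error(linear_regression(rep(1, 5), 1:5), "degenerate")
})
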
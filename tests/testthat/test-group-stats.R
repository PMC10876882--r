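test_that("Benjamini-Hochberg adjustment matches the hand step-up values", {
  # step-up: p_(i) * m / i, cumulative minimum from the largest
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(41)
  for (i in 1:10) {
    p <- runif(8)
    adj <- bh_adjust(p)
    # monotone: adjustment preserves the significance ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # adjusted values never fall below the raw ones
    expect_true(all(adj >= p - 1e-12))
    # hand oracle
    o <- order(p)
    hand <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
    expect_equal(adj[o], pmin(hand, 1))
  }
})

make_metric_table <- function(n_young = 6, n_old = 6,
                              methods = c("none", "GSR", "aCompCor"),
                              subject_sd = 1, noise_sd = 1,
                              method_shift = 0, age_shift = 0) {
  subjects <- sprintf("s%02d", seq_len(n_young + n_old))
  groups <- rep(c("young", "old"), c(n_young, n_old))
  d <- expand.grid(subject = subjects, method = methods,
                   stringsAsFactors = FALSE)
  d$group <- groups[match(d$subject, subjects)]
  b <- stats::rnorm(length(subjects), 0, subject_sd)
  d$value <- b[match(d$subject, subjects)] +
    stats::rnorm(nrow(d), 0, noise_sd) +
    method_shift * (d$method == methods[2]) +
    age_shift * (d$group == "old")
  d
}

test_that("mixed ANOVA detects injected effects and ignores their absence", {
  set.seed(42)
  d <- make_metric_table(method_shift = 3)
  a <- mixed_anova_metric(d)
  expect_setequal(a$factor, c("age", "method", "age:method"))
  expect_lt(a$p[a$factor == "method"], 0.01)
  expect_gt(a$p[a$factor == "age"], 0.05)

  d2 <- make_metric_table(age_shift = 5)
  a2 <- mixed_anova_metric(d2)
  expect_lt(a2$p[a2$factor == "age"], 0.01)

  # near-constant response: no factor explains anything
  d3 <- make_metric_table()
  d3$value <- 1 + rnorm(nrow(d3), 0, 1e-6)
  a3 <- mixed_anova_metric(d3)
  expect_true(all(a3$p > 0.05))

  # permuting method labels within subject destroys the method effect
  set.seed(43)
  d4 <- d
  for (s in unique(d4$subject)) {
    idx <- which(d4$subject == s)
    d4$value[idx] <- d4$value[sample(idx)]
  }
  a4 <- mixed_anova_metric(d4)
  expect_gt(a4$p[a4$factor == "method"], 0.05)
})

test_that("power ANOVA runs on band-power layouts and rejects missing cells", {
  set.seed(48)
  d <- expand.grid(subject = sprintf("s%d", 1:8),
                   method = c("GSR", "aCompCor"), source = c("GM", "WM"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "young", "old")
  d$band <- "cardiac"
  d$value <- rnorm(nrow(d)) + 2 * (d$source == "GM")
  a <- power_anova(d, "cardiac")
  expect_setequal(a$factor, c("age", "tissue", "method", "age:method"))
  expect_lt(a$p[a$factor == "tissue"], 0.05)
  expect_error(power_anova(d[-1, ], "cardiac"), "unbalanced")
  expect_error(power_anova(d, "respiratory"), "no rows")
})

test_that("one observation per subject reduces to fixed-effects ANOVA", {
  # balanced two-way between-subjects design: every row is a new subject,
  # so the subject random intercept is confounded with the residual and the
  # fit must reduce to the classical fixed-effects table
  set.seed(45)
  d <- expand.grid(rep_i = 1:4, age = c("young", "old"),
                   method = c("A", "B", "C"), stringsAsFactors = FALSE)
  d$subject <- factor(sprintf("s%02d", seq_len(nrow(d))))
  d$age <- factor(d$age); d$method <- factor(d$method)
  d$value <- rnorm(nrow(d)) + 1.5 * (d$age == "old") +
    0.8 * (d$method == "B")
  a <- denoisebench:::fit_lmm_anova(value ~ age + method + age:method, d,
                                    "containment")
  # hand oracle: balanced two-way ANOVA from cell/margin means
  grand <- mean(d$value)
  ss_age <- 12 * sum((tapply(d$value, d$age, mean) - grand)^2)
  ss_met <- 8 * sum((tapply(d$value, d$method, mean) - grand)^2)
  cell <- tapply(d$value, list(d$age, d$method), mean)
  ss_cells <- 4 * sum((cell - grand)^2)
  ss_int <- ss_cells - ss_age - ss_met
  ss_err <- sum((d$value - cell[cbind(as.character(d$age),
                                      as.character(d$method))])^2)
  mse <- ss_err / 18
  expect_equal(a$F[a$factor == "age"], (ss_age / 1) / mse, tolerance = 1e-8)
  expect_equal(a$F[a$factor == "method"], (ss_met / 2) / mse,
               tolerance = 1e-8)
  expect_equal(a$F[a$factor == "age:method"], (ss_int / 2) / mse,
               tolerance = 1e-8)
  expect_equal(a$den_df, rep(18, 3))
})

test_that("follow-up tests pair correctly and adjust within family", {
  set.seed(46)
  d <- make_metric_table(methods = c("none", "GSR", "WM-CSF"),
                         method_shift = 1.5)
  ft <- followup_tests(d, "method")
  expect_equal(nrow(ft), 3)
  expect_equal(ft$p_adjusted, bh_adjust(ft$p))
  gsr_rows <- ft[ft$level_1 == "none" & ft$level_2 == "GSR", ]
  expect_equal(gsr_rows$direction, "<")

  # age family: unpaired per method
  fa <- followup_tests(d, "age")
  expect_equal(nrow(fa), 3)

  # identical paired values are flagged, tiny jitter gives a huge |t|
  d2 <- make_metric_table(methods = c("A", "B"), noise_sd = 0)
  ft2 <- followup_tests(d2, "method")
  expect_equal(ft2$direction, "=")
  d3 <- d2
  jit <- d3$method == "B"
  d3$value[jit] <- d3$value[jit] + 1 + rnorm(sum(jit), 0, 1e-8)
  ft3 <- followup_tests(d3, "method")
  expect_gt(abs(ft3$t), 1e6)
  expect_error(followup_tests(d2[d2$method == "A", ], "method"),
               "two methods")
})
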
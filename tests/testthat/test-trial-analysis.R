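printed_hub <- function() {
  mk <- function(cid, arm, num, den) {
    a <- data.frame(clinic_id = cid, measure_id = "total",
                    window = c("baseline", "treatment"),
                    numerator = num, denominator = den)
    attr(a, "arm") <- arm
    a
  }
  hub_collect(list(mk("ctl", "control", c(138L, 157L), c(5308L, 5792L)),
                   mk("int", "intervention", c(742L, 768L), c(18331L, 18668L))))
}

test_that("summarize_trial reproduces every printed rate, change and DiD", {
  tr <- summarize_trial(printed_hub())
  cell <- function(a, w) tr$cells$rate_display[tr$cells$arm == a & tr$cells$window == w]
  expect_equal(cell("intervention", "baseline"), 4.0)
  expect_equal(cell("intervention", "treatment"), 4.1)
  expect_equal(cell("control", "baseline"), 2.6)
  expect_equal(cell("control", "treatment"), 2.7)
  expect_equal(tr$per_arm$change_display, c(0.1, 0.1))
  expect_equal(tr$did_display, 0)
  # 2 d.p. display resolves the 4.11-style ambiguity
  tr2 <- summarize_trial(printed_hub(), digits = 2)
  expect_equal(tr2$cells$rate_display[tr2$cells$arm == "intervention" &
                                        tr2$cells$window == "treatment"], 4.11)
})

test_that("summarize_trial demands both arms and both windows", {
  mk <- function(cid, arm) {
    a <- data.frame(clinic_id = cid, measure_id = "total",
                    window = c("baseline", "treatment"),
                    numerator = c(1L, 2L), denominator = c(10L, 10L))
    attr(a, "arm") <- arm
    a
  }
  hub <- hub_collect(list(mk("c1", "control")))
  expect_error(summarize_trial(hub), "missing arm/window")
})

test_that("gee_test guards its preconditions and degenerate data", {
  set.seed(12)
  cnt <- simulate_trial_counts(n_clinics_per_arm = 4L)
  one_arm <- cnt[cnt$arm == "control" | cnt$clinic_id == "int1", ]
  expect_error(gee_test(one_arm), ">= 2 clinics per arm")
  zero <- cnt
  zero$fired <- 0L
  expect_warning(fit <- gee_test(zero), "degenerate")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p_value))
})

test_that("doubling every clinic's counts leaves the estimates unchanged", {
  set.seed(13)
  cnt <- simulate_trial_counts(n_clinics_per_arm = 4L)
  f1 <- gee_test(cnt)
  cnt2 <- cnt
  cnt2$fired <- 2L * cnt2$fired
  cnt2$eligible <- 2L * cnt2$eligible
  f2 <- gee_test(cnt2)
  # the working-correlation moment estimate shifts with n, so allow the
  # coefficients a small finite-sample wobble; the fitted rates must agree
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-3)
  expect_equal(stats::plogis(f2$coefficients), stats::plogis(f1$coefficients),
               tolerance = 1e-3)
})

test_that("on a null simulation the GEE estimate matches an independent GLM", {
  set.seed(14)
  cnt <- simulate_trial_counts(n_clinics_per_arm = 6L,
                               eligible_per_clinic = 4000)
  fit <- gee_test(cnt)
  # independence-working-correlation oracle: plain binomial GLM
  oracle <- stats::glm(cbind(fired, eligible - fired) ~ arm * window,
                       family = stats::binomial(), data = cnt)
  expect_lt(abs(fit$estimate - stats::coef(oracle)[[4]]), 0.05)
  expect_lt(abs(fit$estimate), 4 * fit$se)
  # and across replicates the null estimates center on zero
  ests <- vapply(1:40, function(s) {
    set.seed(1400 + s)
    gee_test(simulate_trial_counts(n_clinics_per_arm = 4L))$estimate
  }, 0)
  expect_lt(abs(mean(ests)), 3 * stats::sd(ests) / sqrt(length(ests)))
})

test_that("sample_size matches its own simulation-based power oracle", {
  ss <- sample_size(0.20, 0.20)
  expect_gte(ss$n_per_arm_ceil, 1400)
  expect_lte(ss$n_per_arm_ceil, 1450)
  # simulate the two-proportion design at the returned n
  set.seed(15)
  n <- ss$n_per_arm_ceil
  R <- 2000
  z975 <- stats::qnorm(0.975)
  rej <- 0
  for (i in seq_len(R)) {
    x1 <- stats::rbinom(1, n, ss$p_control)
    x2 <- stats::rbinom(1, n, ss$p_intervention)
    p1 <- x1 / n; p2 <- x2 / n
    pb <- (x1 + x2) / (2 * n)
    z <- (p1 - p2) / sqrt(2 * pb * (1 - pb) / n)
    rej <- rej + (abs(z) > z975)
  }
  emp <- rej / R
  mcse <- sqrt(emp * (1 - emp) / R)
  expect_lt(abs(emp - 0.8), 3 * mcse)
  expect_lt(abs(power_for_n(0.20, 0.16, n) - emp), 3 * mcse + 0.01)
})

test_that("sample_size is monotone in power and linear in design effect", {
  lo <- sample_size(0.20, 0.20, power = 0.8)
  hi <- sample_size(0.20, 0.20, power = 0.9)
  expect_lt(lo$n_per_arm, hi$n_per_arm)
  de1 <- sample_size(0.20, 0.20, design_effect = 1)
  de2 <- sample_size(0.20, 0.20, design_effect = 2)
  expect_equal(de2$n_per_arm, 2 * de1$n_per_arm)
  expect_error(sample_size(0.20, 0), "infinite")
  cl <- sample_size(0.20, 0.20, encounters_per_clinic = 120)
  expect_identical(cl$clinics_per_arm, as.integer(ceiling(cl$n_per_arm / 120)))
})
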
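test_that("beta-binomial mass matches the binomial limit and an integration oracle", {
  # phi = 0 is exactly binomial
  expect_equal(dbetabinom(3, 10, 0.3, 0), dbinom(3, 10, 0.3))
  # small phi converges to the binomial
  expect_equal(dbetabinom(3, 10, 0.3, 1e-9), dbinom(3, 10, 0.3),
               tolerance = 1e-6)
  # arbitrary (y, n, p, phi) against numeric integration over the
  # mixing beta density
  set.seed(42)
  for (k in 1:25) {
    n <- sample(1:30, 1)
    y <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    phi <- runif(1, 0.01, 0.6)
    expect_equal(dbetabinom(y, n, p, phi), oracle_bb_mass(y, n, p, phi),
                 tolerance = 1e-8)
  }
  expect_error(dbetabinom(5, 3, 0.5, 0.1), "y > n")
})

test_that("masses over y = 0..n sum to one", {
  set.seed(7)
  for (k in 1:50) {
    n <- sample(1:30, 1)
    p <- runif(1, 0.02, 0.98)
    phi <- runif(1, 0, 0.8)
    expect_lt(abs(sum(dbetabinom(0:n, n, p, phi)) - 1), 1e-10)
  }
})

test_that("log-likelihood handles limits and empty trials", {
  # phi = 0 is exactly the binomial log-mass, and small phi approaches it
  expect_equal(betabin_loglik(3, 10, TRUE, qlogis(0.3), 0, 0, 0),
               dbinom(3, 10, 0.3, log = TRUE))
  expect_equal(betabin_loglik(3, 10, TRUE, qlogis(0.3), 0, 1e-6, 1e-6),
               dbinom(3, 10, 0.3, log = TRUE), tolerance = 1e-4)
  # n = 0 contributes zero
  expect_equal(betabin_loglik(c(3, 0), c(10, 0), c(TRUE, TRUE),
                              qlogis(0.3), 0, 0.05, 0.05),
               betabin_loglik(3, 10, TRUE, qlogis(0.3), 0, 0.05, 0.05))
  expect_error(betabin_loglik(5, 3, TRUE, 0, 0, 0.1, 0.1), "y > n")
})

test_that("null data give beta1 near zero and large p", {
  y <- rep(c(30, 40, 50), 4)
  n <- rep(100, 12)
  grp <- rep(c("case", "control"), each = 6)
  f <- fit_betabin(y, n, grp, case = "case")
  expect_true(f$converged)
  expect_lt(abs(coef(f)[["beta1"]]), 0.05)
  expect_gt(f$p_value, 0.5)
})

test_that("simulated group PSIs are recovered", {
  set.seed(31)
  n <- sample(150:250, 40, replace = TRUE)
  grp <- rep(c("case", "control"), each = 20)
  psi <- ifelse(grp == "case", 0.7, 0.3)
  y <- vapply(seq_along(n), function(i) rbetabinom(1, n[i], psi[i], 0.02),
              0L)
  f <- fit_betabin(y, n, grp, case = "case")
  expect_true(f$converged)
  expect_lt(abs(plogis(coef(f)[["beta0"]]) - 0.3), 0.05)
  expect_lt(abs(plogis(sum(coef(f))) - 0.7), 0.05)
  expect_lt(f$p_value, 1e-6)
})

test_that("degenerate all-zero counts never crash", {
  y <- rep(0L, 12)
  n <- rep(50L, 12)
  grp <- rep(c("case", "control"), each = 6)
  f <- fit_betabin(y, n, grp, case = "case")
  expect_s3_class(f, "betabin_fit")
  expect_true(is.na(f$p_value) || f$p_value > 0.5)
})

test_that("group-label swap negates beta1 and preserves the p-value", {
  set.seed(13)
  n <- sample(50:200, 24, replace = TRUE)
  grp <- rep(c("case", "control"), each = 12)
  psi <- ifelse(grp == "case", 0.6, 0.45)
  y <- vapply(seq_along(n), function(i) rbetabinom(1, n[i], psi[i], 0.03),
              0L)
  f1 <- fit_betabin(y, n, grp, case = "case")
  f2 <- fit_betabin(y, n, grp, case = "control")
  expect_equal(coef(f1)[["beta1"]], -coef(f2)[["beta1"]],
               tolerance = 1e-4)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-4)
})

test_that("doubling all counts can only sharpen a planted effect", {
  set.seed(17)
  n <- sample(80:150, 20, replace = TRUE)
  grp <- rep(c("case", "control"), each = 10)
  psi <- ifelse(grp == "case", 0.65, 0.35)
  y <- vapply(seq_along(n), function(i) rbetabinom(1, n[i], psi[i], 0.02),
              0L)
  f1 <- fit_betabin(y, n, grp, case = "case")
  f2 <- fit_betabin(2L * y, 2L * n, grp, case = "case")
  # PSI (hence delta PSI) is unchanged by uniform count scaling
  expect_equal(plogis(coef(f2)[["beta0"]]), plogis(coef(f1)[["beta0"]]),
               tolerance = 0.02)
  expect_lte(f2$p_value, f1$p_value * 1.01 + 1e-8)
})

test_that("model methods behave like standard fitted-model accessors", {
  y <- c(20, 25, 30, 60, 65, 70)
  n <- rep(100, 6)
  grp <- rep(c("control", "case"), each = 3)
  f <- fit_betabin(y, n, grp, case = "case")
  expect_named(coef(f), c("beta0", "beta1"))
  expect_equal(dim(vcov(f)), c(2, 2))
  expect_s3_class(logLik(f), "logLik")
  expect_output(print(f), "beta-binomial")
  expect_output(print(summary(f)), "z =")
})

test_that("BH adjustment matches the hand formula and the reference", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # NAs excluded from m, preserved in place
  out <- adjust_bh(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  set.seed(99)
  for (k in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("event summaries carry signed effects and a strict alpha cut", {
  cnt <- rbind(
    data.frame(event_id = "e1", sample_id = paste0("c", 1:4),
               group = "case", reads_iso1 = c(40, 40, 40, 40),
               reads_iso2 = c(60, 60, 60, 60)),
    data.frame(event_id = "e1", sample_id = paste0("k", 1:4),
               group = "control", reads_iso1 = c(60, 60, 60, 60),
               reads_iso2 = c(40, 40, 40, 40)))
  cnt$psi <- compute_psi(cnt$reads_iso1, cnt$reads_iso2)
  fits <- data.frame(event_id = "e1", beta0 = 0, beta1 = 0.8,
                     se_beta1 = 0.1, phi_case = 0.01, phi_control = 0.01,
                     converged = TRUE, p_value = 0.009)
  s <- summarize_events(cnt, fits, case = "case", control = "control",
                        alpha = 0.01)
  expect_equal(s$delta_psi, 0.2)
  expect_true(s$significant)          # 0.009 < 0.01
  fits$p_value <- 0.01
  s2 <- summarize_events(cnt, fits, case = "case", control = "control",
                         alpha = 0.01)
  expect_false(s2$significant)        # boundary is strict
  # non-converged fits are excluded from the BH family
  fits3 <- rbind(fits, data.frame(event_id = "e2", beta0 = NA, beta1 = NA,
                                  se_beta1 = NA, phi_case = NA,
                                  phi_control = NA, converged = FALSE,
                                  p_value = NA))
  cnt2 <- rbind(cnt, within(cnt, event_id <- "e2"))
  s3 <- summarize_events(cnt2, fits3, case = "case", control = "control")
  expect_equal(s3$p_adj[s3$event_id == "e1"], 0.01)  # m = 1
  expect_true(is.na(s3$p_adj[s3$event_id == "e2"]))
})
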
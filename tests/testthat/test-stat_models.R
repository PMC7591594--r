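test_that("a 2x2 table recovers the closed-form log odds ratio", {
  d <- data.frame(y = rep(c(0, 0, 1, 1), c(40, 10, 20, 30)),
                  x = rep(c(0, 1, 0, 1), c(40, 10, 20, 30)))
  fit <- fit_multinomial(d, "y", "x")
  expect_equal(unname(coef(fit)["1", "x"]), log(6), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["1", "(Intercept)"]), log(20 / 40),
               tolerance = 1e-6)
  s <- summary(fit)$table
  expect_equal(s$exp_B, exp(s$B), tolerance = 1e-6)
})

test_that("the null model has McFadden R2 of exactly 0", {
  d <- data.frame(y = factor(rep(c("a", "b", "c"), c(30, 20, 10))))
  fit <- fit_multinomial(d, "y", character())
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-10)
  expect_equal(fit$mcfadden_r2, 0, tolerance = 1e-10)
  expect_equal(mcfadden_r2(fit), fit$mcfadden_r2)
})

test_that("three-level fits match independent optimisers", {
  set.seed(30)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta2 <- 0.5 + 1.0 * x1 - 0.5 * x2
  eta3 <- -0.2 + 0.8 * x2
  p <- cbind(1, exp(eta2), exp(eta3)); p <- p / rowSums(p)
  y <- apply(p, 1, function(pr) sample(3, 1, prob = pr))
  d <- data.frame(y = factor(y), x1 = x1, x2 = x2)
  fit <- fit_multinomial(d, "y", c("x1", "x2"))

  # generic numerical MLE oracle: optim() on an independently coded
  # likelihood
  nll <- function(theta) {
    B <- matrix(theta, 2, 3, byrow = TRUE)
    X <- cbind(1, x1, x2)
    eta <- X %*% t(B)
    denom <- 1 + rowSums(exp(eta))
    ll <- sum(log(ifelse(y == 1, 1,
                         exp(eta[cbind(seq_len(n), pmax(y - 1, 1))])) / denom))
    -ll
  }
  o <- optim(rep(0, 6), nll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  B_oracle <- matrix(o$par, 2, 3, byrow = TRUE)
  expect_lt(max(abs(coef(fit) - B_oracle)), 1e-4)

  # cross-check against nnet::multinom
  m <- nnet::multinom(y ~ x1 + x2, d, trace = FALSE, reltol = 1e-12)
  expect_lt(max(abs(coef(fit) - coef(m))), 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-8)
})

test_that("fits are invariant to row permutation; centring shifts intercepts only", {
  set.seed(31)
  n <- 300
  d <- data.frame(y = factor(sample(c("a", "b", "c"), n, TRUE)),
                  x = rnorm(n))
  f1 <- fit_multinomial(d, "y", "x")
  f2 <- fit_multinomial(d[sample(n), ], "y", "x")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
  d3 <- d; d3$x <- d$x - 5
  f3 <- fit_multinomial(d3, "y", "x")
  expect_equal(coef(f3)[, "x"], coef(f1)[, "x"], tolerance = 1e-6)
  expect_equal(coef(f3)[, "(Intercept)"],
               coef(f1)[, "(Intercept)"] + 5 * coef(f1)[, "x"],
               tolerance = 1e-5)
})

test_that("coefficient recovery on simulated multinomial data is unbiased", {
  set.seed(32)
  B_true <- rbind(c(0.5, 1.0, -0.5), c(-0.2, 0.0, 0.8))
  err <- matrix(0, 2, 3)
  reps <- 10
  for (r in seq_len(reps)) {
    n <- 2000
    x1 <- rnorm(n); x2 <- rnorm(n)
    X <- cbind(1, x1, x2)
    eta <- X %*% t(B_true)
    p <- cbind(1, exp(eta)); p <- p / rowSums(p)
    y <- apply(p, 1, function(pr) sample(3, 1, prob = pr))
    d <- data.frame(y = factor(y), x1 = x1, x2 = x2)
    fit <- fit_multinomial(d, "y", c("x1", "x2"))
    err <- err + (coef(fit) - B_true)
  }
  expect_lt(max(abs(err / reps)), 0.1)
})

test_that("errors are raised for degenerate designs and separation", {
  d <- data.frame(y = factor(c("a", "a", "b", "b")),
                  x = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8))
  expect_error(fit_multinomial(d, "y", c("x", "x2")), "collinear")
  # perfectly separated data cannot converge to finite coefficients
  set.seed(33)
  n <- 60
  x <- rnorm(n)
  dsep <- data.frame(y = factor(x > 0), x = x)
  expect_error(fit_multinomial(dsep, "y", "x"), "non-convergence")
  dna <- data.frame(y = c("a", NA, "b"), x = 1:3)
  expect_error(fit_multinomial(dna, "y", "x"), "missing")
})

test_that("prediction, residuals and simulation behave coherently", {
  set.seed(34)
  n <- 200
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < plogis(1.5 * x), "b", "a"))
  d <- data.frame(y = y, x = x)
  fit <- fit_multinomial(d, "y", "x")
  P <- predict(fit)
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
  expect_identical(colnames(P), c("a", "b"))
  cls <- predict(fit, newdata = data.frame(x = c(-3, 3)), type = "class")
  expect_identical(as.character(cls), c("a", "b"))
  r <- residuals(fit, d)
  expect_equal(rowSums(r), rep(0, n), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), as.integer(c(n, 2)))
  expect_true(all(unlist(lapply(sims, levels)) %in% levels(y)))
})

test_that("stepwise selection keeps strong predictors and rejects noise", {
  set.seed(35)
  # a planted B = 2 predictor is always kept
  for (r in 1:5) {
    n <- 500
    x <- rnorm(n)
    y <- factor(ifelse(runif(n) < plogis(2 * x), "b", "a"))
    d <- data.frame(y = y, x = x, junk = rnorm(n))
    sel <- stepwise_select(d, "y", c("x", "junk"))
    expect_true("x" %in% sel$selected)
  }
  # pure-noise predictors on null data are rejected at close to the
  # nominal rate
  rejected <- 0L
  for (r in 1:100) {
    n <- 500
    d <- data.frame(y = factor(sample(c("a", "b"), n, TRUE)), z = rnorm(n))
    sel <- stepwise_select(d, "y", "z")
    if (!"z" %in% sel$selected) rejected <- rejected + 1L
  }
  expect_gte(rejected, 90L)
  # a predictor identical to an included one is rejected with no LL change
  set.seed(36)
  n <- 300
  x <- rnorm(n)
  y <- factor(ifelse(runif(n) < plogis(x), "b", "a"))
  d <- data.frame(y = y, x = x, x_copy = x)
  sel <- stepwise_select(d, "y", c("x", "x_copy"))
  expect_identical(sel$selected, "x")
  expect_identical(sel$trace$lr[2], 0)
})

test_that("the collinearity screen keeps the designated representatives", {
  expect_identical(
    collinearity_screen(c("exh_duration_log2s", "exh_amplitude", "exh_slope",
                          "exh_onset_level", "exh_offset_level",
                          "hold_present")),
    c("exh_slope", "exh_offset_level", "hold_present"))
  expect_identical(
    collinearity_screen(c("inh_slope", "inh_offset_level",
                          "speech_lag_log2s")),
    c("inh_slope", "inh_offset_level", "speech_lag_log2s"))
  # uncorrelated synthetic predictors pass through untouched
  expect_identical(collinearity_screen(c("alpha", "beta")),
                   c("alpha", "beta"))
  # the pre-registered families carry the published predictor sets
  expect_identical(mnl_config("exhalatory")$predictors,
                   c("exh_slope", "exh_offset_level", "hold_present"))
  expect_identical(mnl_config("exhalatory")$reference, "WSS-INH")
  expect_identical(mnl_config("inhalatory_tt")$predictors,
                   c("inh_slope", "inh_offset_level", "speech_lag_log2s"))
  expect_identical(mnl_config("silent_cycle")$reference, "Hold")
})
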
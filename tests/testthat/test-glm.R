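test_that("intercept-only log-link fit matches a one-parameter ML oracle", {
  set.seed(3)
  y <- exp(rnorm(50, 2, 0.3)) + rnorm(50, 0, 0.5)
  d <- data.frame(y = y)
  m <- fit_driver_glm("y", character(0), d)
  # Gaussian likelihood in mu alone is maximized at the sample mean;
  # independent numeric oracle instead of the closed form
  oracle <- optimize(function(mu) sum((y - mu)^2), range(y))$minimum
  expect_equal(unname(exp(coef(m)[1])), oracle, tolerance = 1e-5)
  expect_equal(unname(exp(coef(m)[1])), mean(y), tolerance = 1e-6)
  expect_true(all(abs(fitted(m) - fitted(m)[1]) < 1e-12))
})

test_that("noiseless log-linear data are recovered exactly", {
  set.seed(4)
  d <- data.frame(x = rnorm(100))
  d$y <- exp(1 + 2 * d$x)
  m <- fit_driver_glm("y", "x", d)
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-6)
  expect_equal(m$diagnostics$r2, 1, tolerance = 1e-9)
})

test_that("coefficients are consistent under noise (Monte-Carlo, n = 2000)", {
  set.seed(5)
  d <- data.frame(x = rnorm(2000))
  d$y <- exp(0.5 + 0.3 * d$x) + rnorm(2000, 0, 0.1)
  m <- fit_driver_glm("y", "x", d)
  expect_equal(unname(coef(m)), c(0.5, 0.3), tolerance = 0.05)
})

test_that("diagnostics satisfy their identities and responses with zeros fit", {
  set.seed(6)
  d <- data.frame(x = rnorm(200))
  d$y <- pmax(round(exp(1 + 0.5 * d$x) + rnorm(200, 0, 2)), 0)  # richness-like, has zeros
  expect_true(any(d$y == 0))
  m <- fit_driver_glm("y", "x", d)
  expect_true(m$converged)
  dg <- m$diagnostics
  expect_equal(dg$rmse, sqrt(dg$mse), tolerance = 1e-12)
  expect_true(dg$r2 >= 0 && dg$r2 <= 1)
  expect_true(is.finite(dg$aic))
  # r2 is non-decreasing in the term set when refit without selection
  d$x2 <- rnorm(200)
  m2 <- fit_driver_glm("y", c("x", "x2"), d)
  expect_true(m2$diagnostics$r2 >= dg$r2 - 1e-12)
  expect_error(fit_driver_glm("y", "nope", d), "not found")
  expect_error(fit_driver_glm("y", "x", d[1:2, ]), "need n >")
})

test_that("stepwise selection is a no-op when the scope admits no moves", {
  set.seed(7)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  d$y <- exp(0.5 + 0.4 * d$x1) + rnorm(60, 0, 0.3)
  m <- stepwise_aic("y", d, scope_lower = c("x1", "x2"),
                    scope_upper = c("x1", "x2"), start_terms = c("x1", "x2"))
  expect_setequal(m$terms, c("x1", "x2"))
  expect_equal(nrow(m$path), 1L)
  expect_error(stepwise_aic("y", d, scope_lower = "x1", scope_upper = "x2"),
               "subset")
})

test_that("accepted stepwise path decreases AIC monotonically and ends stable", {
  set.seed(8)
  n <- 150
  d <- as.data.frame(matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("x", 1:6))))
  d$y <- exp(1 + 0.5 * d$x1 - 0.4 * d$x2) + rnorm(n, 0, 0.5)
  m <- stepwise_aic("y", d, scope_upper = paste0("x", 1:6))
  expect_true(all(diff(m$path$aic) < 0))
  expect_true(all(c("x1", "x2") %in% m$terms))
  # final AIC never exceeds the start model's
  expect_lte(tail(m$path$aic, 1), m$path$aic[1])
})

test_that("identity-link stepwise reproduces the classical least-squares stepwise path", {
  set.seed(9)
  for (i in 1:20) {
    n <- 60
    d <- as.data.frame(matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("x", 1:5))))
    beta <- sample(c(0, 0, 0.8, -0.6, 0.4))
    d$y <- drop(1 + as.matrix(d) %*% beta + rnorm(n, 0, 1))
    mine <- stepwise_aic("y", d, scope_upper = paste0("x", 1:5), link = "identity")
    oracle <- stats::step(lm(y ~ 1, data = d),
                          scope = list(lower = ~1, upper = ~ x1 + x2 + x3 + x4 + x5),
                          direction = "both", trace = 0)
    expect_setequal(mine$terms, attr(terms(oracle), "term.labels"))
  }
})

test_that("two-stage selection honours the stage-1 scope lock", {
  sim <- quiet_sim(n_sites = 200L, n_pesticides = 10L, seed = 21)
  env <- transform_environment(sim$environment)
  vg <- attr(sim$environment, "var_groups")
  d <- cbind(env, as.data.frame(sim$concentrations),
             sim$responses["richness_bacteria"])
  filt <- near_zero_variance_filter(sim$concentrations)
  m <- two_stage_selection("richness_bacteria", d, soil_terms = vg$soil,
                           climate_terms = vg$climate,
                           pesticide_terms = filt$kept)
  # every environmental term retained at stage 1 is present in the final model
  expect_true(all(m$stage1$terms %in% m$terms))
  # group labels partition the selected terms
  expect_setequal(unlist(m$groups, use.names = FALSE), m$terms)
  expect_true(all(m$groups$pesticides %in% filt$kept))
})

test_that("VIFs match the closed form and flag exact collinearity", {
  set.seed(10)
  n <- 5000
  # near-orthogonal design: VIFs ~ 1
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$y <- exp(0.5 + 0.1 * d$a + 0.1 * d$b) + rnorm(n, 0, 0.2)
  m <- fit_driver_glm("y", c("a", "b"), d)
  v <- vif_check(m)
  expect_true(all(abs(v$vif - 1) < 0.01))

  # correlation 0.9 -> VIF = 1 / (1 - r^2) for both terms
  z <- rnorm(n)
  d2 <- data.frame(a = z, b = 0.9 * z + sqrt(1 - 0.81) * rnorm(n))
  r <- cor(d2$a, d2$b)
  d2$y <- exp(0.5 + 0.1 * d2$a + 0.1 * d2$b) + rnorm(n, 0, 0.2)
  m2 <- fit_driver_glm("y", c("a", "b"), d2)
  v2 <- vif_check(m2)
  expect_equal(v2$vif, rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  expect_equal(v2$vif[1], 5.263, tolerance = 0.3)

  # independent oracle: car::vif on an identity-link fit (constant weights)
  m2i <- fit_driver_glm("y", c("a", "b"), d2, link = "identity")
  expect_equal(v2$vif, unname(car::vif(m2i$fit)), tolerance = 1e-10)

  # factor term: GVIF^(1/(2 df)) matches the car convention at identity link
  d4 <- data.frame(f = factor(sample(letters[1:3], 300, TRUE)), x = rnorm(300))
  d4$y <- rnorm(300) + 5
  m4 <- fit_driver_glm("y", c("f", "x"), d4, link = "identity")
  v4 <- vif_check(m4)
  cv <- car::vif(m4$fit)
  expect_equal(v4$gvif_scaled, unname(cv[, 3]), tolerance = 1e-10)
  expect_equal(v4$df, unname(as.integer(cv[, "Df"])))

  # duplicated column -> aliased -> infinite VIF, flagged
  d3 <- d[1:200, ]; d3$b <- d3$a
  m3 <- fit_driver_glm("y", c("a", "b"), d3)
  v3 <- vif_check(m3)
  expect_true(all(!is.finite(v3$vif)) && all(v3$flagged))
  expect_error(vif_check(fit_driver_glm("y", "a", d)), "at least 2")
})

test_that("QQ diagnostics separate normal from heavy-tailed residuals", {
  set.seed(11)
  n <- 300
  d <- data.frame(x = rnorm(n))
  mu <- exp(1 + 0.3 * d$x)
  d$y_norm <- mu + rnorm(n)
  d$y_t2 <- mu + rt(n, df = 2)
  qn <- residual_diagnostics(fit_driver_glm("y_norm", "x", d))
  qt <- residual_diagnostics(fit_driver_glm("y_t2", "x", d))
  expect_gt(qn$qq_cor, 0.99)
  expect_lt(qt$qq_cor, qn$qq_cor)
  # zero residuals: degenerate perfect fit
  d$y_exact <- mu
  qe <- residual_diagnostics(fit_driver_glm("y_exact", "x", d))
  expect_true(qe$perfect_fit)
  expect_equal(qe$qq_cor, 1)
})
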
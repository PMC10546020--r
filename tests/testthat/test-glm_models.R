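test_that("IQR outlier rule removes gross outliers and spares degenerate data", {
  d <- data.frame(y = c(1:9, 100))
  res <- remove_outliers(d, "y")
  expect_equal(res$removed$y, 100)
  expect_equal(nrow(res$data), 9L)

  d2 <- data.frame(y = rep(5, 10))
  res2 <- remove_outliers(d2, "y")
  expect_equal(nrow(res2$removed), 0L)

  # seeded sample against a brute-force quantile-rule oracle (type 7)
  set.seed(20)
  y <- c(rnorm(195), rnorm(5, 0, 12))
  res3 <- remove_outliers(data.frame(y = y), "y")
  q1 <- quantile(y, 0.25, type = 7, names = FALSE)
  q3 <- quantile(y, 0.75, type = 7, names = FALSE)
  oracle_out <- y[y < q1 - 1.5 * (q3 - q1) | y > q3 + 1.5 * (q3 - q1)]
  expect_equal(sort(res3$removed$y), sort(oracle_out))
})

test_that("the date-stratified split is 60/40, seeded and exhaustive", {
  d <- expand.grid(plot = 1:25, date = as.Date("2022-06-01") + 14 * (0:9))
  spl <- stratified_split(d, train_fraction = 0.6, seed = 3)
  tr_by_date <- table(spl$train$date)
  va_by_date <- table(spl$validation$date)
  expect_true(all(tr_by_date == 15L))
  expect_true(all(va_by_date == 10L))
  expect_equal(nrow(spl$train) + nrow(spl$validation), nrow(d))

  spl2 <- stratified_split(d, train_fraction = 0.6, seed = 3)
  expect_identical(spl, spl2)
  spl3 <- stratified_split(d, train_fraction = 0.6, seed = 4)
  expect_false(identical(spl$train, spl3$train))

  # singleton stratum goes to training
  d1 <- rbind(d, data.frame(plot = 1, date = as.Date("2023-01-01")))
  spl4 <- stratified_split(d1, train_fraction = 0.6, seed = 3)
  expect_true(as.Date("2023-01-01") %in% spl4$train$date)
  expect_false(as.Date("2023-01-01") %in% spl4$validation$date)
})

test_that("intercept-only fits satisfy their closed-form relations", {
  set.seed(5)
  y_beta <- rbeta(300, 8, 8)   # symmetric around 0.5
  fb <- fit_glm(y_beta, family = "beta", terms = "intercept")
  expect_equal(plogis(fb$coefficients[["intercept"]]), mean(y_beta),
               tolerance = 0.02)

  y_gam <- rgamma(300, shape = 4, rate = 2)
  fg <- fit_glm(y_gam, family = "gamma", terms = "intercept")
  expect_equal(exp(fg$coefficients[["intercept"]]), mean(y_gam),
               tolerance = 1e-8)   # gamma mean MLE is the sample mean
})

test_that("gaussian/identity equals ordinary least squares", {
  set.seed(6)
  vi <- runif(80)
  y <- 1.5 + 2 * vi + rnorm(80, 0, 0.3)
  f <- fit_glm(y, vi = vi, family = "gaussian")
  ols <- lm(y ~ vi)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
  expect_equal(f$dispersion, sum(residuals(ols)^2) / 80, tolerance = 1e-10)
})

test_that("the beta/logit ML fit matches an independent ML implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(31)
  d <- recovery_design(250L)
  mu <- plogis(beta_truth[1] + beta_truth[2] * d$vi + beta_truth[3] * d$gdd +
                 beta_truth[4] * d$vi * d$gdd)
  y <- rbeta(250, mu * phi_truth, (1 - mu) * phi_truth)
  f <- fit_glm(y, vi = d$vi, gdd = d$gdd, family = "beta")
  dat <- data.frame(y = y, vi = d$vi, gdd = d$gdd)
  g <- suppressWarnings(glmmTMB::glmmTMB(y ~ vi * gdd, data = dat,
                                         family = glmmTMB::beta_family()))
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-3)
  expect_equal(unname(f$coefficients),
               unname(glmmTMB::fixef(g)$cond[c(1, 2, 3, 4)]),
               tolerance = 1e-3)
  expect_equal(unname(f$dispersion), unname(glmmTMB::sigma(g)),
               tolerance = 1e-2)
})

test_that("responses invalid for the family are rejected with row indices", {
  expect_error(fit_glm(c(0.2, 0.5, 1.0, 0.4, 0.3, 0.6), family = "beta",
                       terms = "intercept"), "rows: 3")
  expect_error(fit_glm(c(1, 2, -3, 4, 5, 6), family = "gamma",
                       terms = "intercept"), "rows: 3")
})

test_that("predictions apply the inverse link", {
  mk <- function(family, terms, coefs) {
    structure(list(family = family, terms = terms, coefficients = coefs,
                   converged = TRUE, predictor_vi = "vi"),
              class = "cotton_glm")
  }
  expect_equal(predict_response(mk("beta", "intercept", c(intercept = 0))),
               0.5)
  expect_equal(predict_response(mk("gamma", "intercept", c(intercept = 0))),
               1.0)
  expect_equal(predict_response(mk("gaussian", c("intercept", "vi"),
                                   c(intercept = 2, vi = 0)), vi = 7), 2)
  expect_error(predict_response(mk("beta", c("intercept", "vi"),
                                   c(intercept = 0, vi = 1))),
               "missing predictor")
})

test_that("training scores follow their closed forms", {
  set.seed(8)
  vi <- runif(60)
  y <- 2 + 3 * vi + rnorm(60, 0, 0.5)
  m1 <- fit_glm(y, vi = vi, family = "gaussian")
  m0 <- fit_glm(y, family = "gaussian", terms = "intercept")

  # a model scored against itself has zero generalized R^2
  expect_equal(score_train(m0, m0)[["r2"]], 0)

  sc <- score_train(m1, m0)
  n <- 60; k <- 3   # two mean coefficients + sigma^2
  ll <- m1$loglik
  expect_equal(sc[["aicc"]], -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
  expect_equal(sc[["bic"]], -2 * ll + k * log(n), tolerance = 1e-9)
  l0 <- m0$loglik
  expect_equal(sc[["r2"]],
               (1 - exp(-(2 / n) * (ll - l0))) / (1 - exp((2 / n) * l0)),
               tolerance = 1e-12)
})

test_that("generalized R^2 is non-decreasing over nested gamma models", {
  set.seed(12)
  vi <- runif(120); gdd <- runif(120, 200, 1600)
  y <- rgamma(120, shape = 10,
              rate = 10 / exp(2 + 1.2 * vi + 0.001 * gdd))
  m0 <- fit_glm(y, vi = vi, gdd = gdd, family = "gamma", terms = "intercept")
  m1 <- fit_glm(y, vi = vi, gdd = gdd, family = "gamma",
                terms = c("intercept", "vi"))
  m2 <- fit_glm(y, vi = vi, gdd = gdd, family = "gamma",
                terms = c("intercept", "vi", "gdd"))
  m3 <- fit_glm(y, vi = vi, gdd = gdd, family = "gamma",
                terms = c("intercept", "vi", "gdd", "vi_gdd"))
  r2s <- c(score_train(m0, m0)[["r2"]], score_train(m1, m0)[["r2"]],
           score_train(m2, m0)[["r2"]], score_train(m3, m0)[["r2"]])
  expect_true(all(diff(r2s) >= -1e-10))
})

test_that("cross-validation metrics behave at the extremes", {
  mk <- function(coefs) {
    structure(list(family = "gaussian", terms = c("intercept", "vi"),
                   coefficients = coefs, converged = TRUE,
                   predictor_vi = "vi"), class = "cotton_glm")
  }
  y <- c(1, 2, 3, 4)
  perfect <- mk(c(intercept = 0, vi = 1))
  cv <- cross_validate(perfect, y, vi = y)
  expect_equal(cv[["r2_cv"]], 1)
  expect_equal(cv[["rmse_cv"]], 0)

  constant <- mk(c(intercept = 2.5, vi = 0))
  cv2 <- cross_validate(constant, y, vi = y)
  expect_true(is.na(cv2[["r2_cv"]]))
  expect_equal(cv2[["rmse_cv"]], sqrt(mean((y - 2.5)^2)))  # population sd

  set.seed(14)
  yv <- rnorm(30); vv <- yv + rnorm(30, 0, 0.5)
  slope <- mk(c(intercept = 0.1, vi = 0.9))
  cv3 <- cross_validate(slope, yv, vi = vv)
  pred <- 0.1 + 0.9 * vv
  expect_equal(cv3[["r2_cv"]], cor(pred, yv)^2, tolerance = 1e-12)
  expect_equal(cv3[["rmse_cv"]], sqrt(mean((pred - yv)^2)), tolerance = 1e-12)
})

test_that("model ranking orders by RMSEcv with documented tie-breaks", {
  sc <- data.frame(predictor = c("A", "B", "C", "D"),
                   r2 = c(0.8, 0.8, 0.8, 0.8),
                   aicc = c(10, 12, 11, 9),
                   bic = c(15, 17, 16, 14),
                   r2cv = c(0.90, 0.93, 0.89, 0.93),
                   rmsecv = c(0.10, 0.08, 0.10, 0.08))
  r <- rank_models(sc)
  expect_equal(r$predictor, c("D", "B", "A", "C"))
  expect_equal(r$rank, 1:4)

  # permutation invariance
  set.seed(2)
  for (i in 1:5) {
    rp <- rank_models(sc[sample(4), ])
    expect_equal(rp$predictor, r$predictor)
  }
})

test_that("mechanistic RUE with exact IPAR predictions reduces to the measured series", {
  set.seed(16)
  n_dates <- 5L
  d <- data.frame(plot_id = rep(c("p1", "p2"), each = n_dates),
                  gdd = rep(seq(400, 1600, length.out = n_dates), 2),
                  cum_par = rep(seq(300, 1100, length.out = n_dates), 2))
  d$ipar_obs <- runif(nrow(d), 0.3, 0.95)
  d$biomass <- ave(runif(nrow(d), 50, 300), d$plot_id, FUN = cumsum)
  # model whose prediction is exactly the observed interception
  d$lin <- qlogis(d$ipar_obs)
  exact <- structure(list(family = "beta", terms = "vi",
                          coefficients = c(vi = 1), converged = TRUE,
                          predictor_vi = "lin"), class = "cotton_glm")
  out <- mechanistic_rue(d, exact, use_measured_biomass = TRUE)
  for (pid in c("p1", "p2")) {
    rows <- out$plot_id == pid
    expect_equal(out$rue_mech[rows],
                 rue_series(d$biomass[rows],
                            d$ipar_obs[rows] * d$cum_par[rows]),
                 tolerance = 1e-12)
  }
  expect_error(mechanistic_rue(d[c(1, 6), ], exact,
                               use_measured_biomass = TRUE),
               "fewer than 2 dates")
})
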
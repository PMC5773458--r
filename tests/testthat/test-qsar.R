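# Prediction, fold changes, weighted least squares, LOO Q2, GA feature
# selection, validation and contribution profiles.

test_that("prediction with the generalized preset matches hand arithmetic", {
  gen <- qsar_preset("table2_generalized")
  zero <- setNames(rep(0, 9), paste0("FP", 1:9))
  expect_equal(predict_pic50(gen, zero), 0.755)
  fp <- zero; fp[c("FP2", "FP4", "FP7")] <- 1; fp["FP9"] <- 2.0
  expect_equal(predict_pic50(gen, fp), 0.755 + 0.621 + 0.821 + 0.724 + 1.969 * 2)
  # FP4 toggle moves the prediction by exactly its coefficient
  fp0 <- fp; fp0["FP4"] <- 0
  expect_equal(predict_pic50(gen, fp) - predict_pic50(gen, fp0), 0.821)
  # missing feature errors
  expect_error(predict_pic50(gen, zero[1:8]), "missing selected feature")
})

test_that("the steroid preset carries its published column", {
  st <- qsar_preset("table2_steroid")
  expect_setequal(st$features, c("FP1", "FP2", "FP3", "FP4", "FP7", "FP9"))
  expect_equal(unname(st$coefficients[c("FP1", "FP4", "FP9")]),
               c(0.296, 0.823, 2.234))
  expect_equal(st$intercept, 0.270)
})

test_that("coefficients translate to the quoted fold changes", {
  expect_equal(fold_change(0.724), 5.3)
  expect_equal(fold_change(1.278), 19)
  expect_equal(fold_change(2.237), 173)
})

test_that("weighted MLR equals the lm() oracle and interpolates noiseless data", {
  set.seed(3)
  n <- 60
  x <- data.frame(a = rnorm(n), b = runif(n), c = rbinom(n, 1, 0.5))
  y <- 1.5 + 2 * x$a - 0.7 * x$b + 0.3 * x$c + rnorm(n, 0, 0.4)
  w <- runif(n, 0.2, 2)
  m <- fit_weighted_mlr(x, y, w)
  ref <- lm(y ~ a + b + c, data = cbind(x, y = y), weights = w)
  expect_equal(unname(m$coefficients), unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  # equal weights match ordinary least squares
  m1 <- fit_weighted_mlr(x, y)
  ref1 <- lm(y ~ a + b + c, data = cbind(x, y = y))
  expect_equal(unname(m1$coefficients), unname(coef(ref1)[-1]), tolerance = 1e-10)
  # noiseless data: exact interpolation of the generating coefficients
  y0 <- 1.5 + 2 * x$a - 0.7 * x$b + 0.3 * x$c
  m0 <- fit_weighted_mlr(x, y0, w)
  expect_equal(unname(m0$coefficients), c(2, -0.7, 0.3), tolerance = 1e-8)
  expect_equal(m0$intercept, 1.5, tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(4)
  x <- data.frame(a = rnorm(30))
  x$b <- 2 * x$a
  expect_error(fit_weighted_mlr(x, rnorm(30)), "collinear.*b")
})

test_that("LOO shortcut equals explicit refits for weighted least squares", {
  set.seed(5)
  n <- 40
  x <- data.frame(a = rnorm(n), b = runif(n))
  y <- 1 + x$a - 2 * x$b + rnorm(n, 0, 0.5)
  w <- runif(n, 0.1, 1)
  short <- loo_q2(x, y, w, method = "shortcut")
  refit <- loo_q2(x, y, w, method = "refit")
  expect_equal(short$e_loo, refit$e_loo, tolerance = 1e-8)
  expect_equal(short$q2, refit$q2, tolerance = 1e-8)
})

test_that("cohort fits recover the generating model", {
  gen <- qsar_preset("table2_generalized")
  # noiseless: exact recovery
  co0 <- make_cohort(synthetic_spec(seed = 19, noise_sigma = 0, coord_sigma = 0))
  m0 <- fit_weighted_mlr(co0[, paste0("FP", 1:9)], co0$pIC50)
  expect_equal(unname(m0$coefficients), unname(gen$coefficients), tolerance = 1e-8)
  expect_equal(m0$intercept, 0.755, tolerance = 1e-8)
  # noisy, n = 200, balanced prevalences: averaged over 20 seeds the
  # estimates sit within 10 percent (intercept within 0.15)
  prev <- setNames(rep(0.5, 7), paste0("FP", 1:7))
  est <- vapply(1:20, function(k) {
    co <- make_cohort(synthetic_spec(seed = 200 + k, n_steroid = 100,
                                     n_aza = 100, feature_prevalence = prev,
                                     logpc_range = c(0.2, 2.2),
                                     noise_sigma = 0.3, coord_sigma = 0), gen)
    w <- ifelse(co$class == "steroid", 1, 0.1)
    m <- fit_weighted_mlr(co[, paste0("FP", 1:9)], co$pIC50, w)
    c(m$coefficients, intercept = m$intercept)
  }, numeric(10))
  mean_est <- rowMeans(est)
  expect_true(all(abs(mean_est[1:9] - gen$coefficients) /
                    gen$coefficients <= 0.10))
  expect_lt(abs(mean_est[10] - 0.755), 0.15)
})

test_that("the GA drops null features and keeps informative ones", {
  # 11-feature candidate pool; two candidates carry zero true coefficient
  set.seed(77)
  n <- 150
  pool <- data.frame(
    FP1 = rbinom(n, 1, 0.5), FP2 = rbinom(n, 1, 0.5), FP3 = rbinom(n, 1, 0.5),
    FP4 = rbinom(n, 1, 0.5), FP5 = rbinom(n, 1, 0.5), FP6 = rbinom(n, 1, 0.5),
    FP7 = rbinom(n, 1, 0.5),
    cand_OH = rbinom(n, 1, 0.5), cand_NO2 = rbinom(n, 1, 0.5),  # true zeros
    FP8 = runif(n, 1.4, 7.2) * rbinom(n, 1, 0.5),
    FP9 = runif(n, 0.2, 2.2)
  )
  beta <- c(0.229, 0.621, 0.710, 0.821, 1.278, 2.237, 0.724, 0, 0, 1.0, 1.969)
  y_base <- as.matrix(pool) %*% beta + 0.755
  excl <- vapply(1:20, function(k) {
    set.seed(900 + k)
    y <- y_base + rnorm(n, 0, 0.3)
    res <- ga_select(pool, as.numeric(y),
                     config = ga_config(pop_size = 30, generations = 40,
                                        seed = k))
    !any(c("cand_OH", "cand_NO2") %in% res$selected)
  }, logical(1))
  expect_gte(mean(excl), 0.9)
  # informative features survive (check the last run's selection)
  res <- ga_select(pool, as.numeric(y_base + rnorm(n, 0, 0.3)),
                   config = ga_config(pop_size = 30, generations = 40, seed = 1))
  expect_true(all(c("FP4", "FP6", "FP8", "FP9") %in% res$selected))
  expect_true(is.finite(res$full_fitness))
})

test_that("a single candidate feature is selected trivially", {
  set.seed(6)
  x <- data.frame(FP9 = runif(30, 0.2, 2.2))
  y <- 0.5 + 2 * x$FP9 + rnorm(30, 0, 0.1)
  res <- ga_select(x, y, config = ga_config(seed = 2))
  expect_equal(res$selected, "FP9")
})

test_that("validation reports are exact for perfect data and degenerate splits", {
  set.seed(7)
  n <- 60
  x <- data.frame(FP4 = rbinom(n, 1, 0.5), FP9 = runif(n, 0.2, 2.2))
  cls <- rep(c("steroid", "azaheterocycle"), n / 2)
  y <- 0.755 + 0.821 * x$FP4 + 1.969 * x$FP9
  rep0 <- validate_qsar(x, y, cls, train_fraction = 0.7, seed = 1)
  expect_equal(rep0$train$r2, 1, tolerance = 1e-9)
  expect_equal(rep0$train$q2, 1, tolerance = 1e-9)
  expect_equal(rep0$train$mae, 0, tolerance = 1e-9)
  expect_equal(rep0$external$r2, 1, tolerance = 1e-9)
  # degenerate split: external metrics equal training metrics
  y2 <- y + rnorm(n, 0, 0.3)
  repd <- validate_qsar(x, y2, cls, train_fraction = 1, seed = 1)
  expect_equal(repd$external$mae, mean(abs(y2 - predict_pic50(repd$model, x))))
  expect_equal(repd$external$n, repd$train$n)
  # tiny class errors out
  expect_error(validate_qsar(x[1:5, ], y[1:5], c("a", "a", "a", "b", "b")),
               "at least 3")
})

test_that("contribution profiles reconcile with predictions and groups", {
  gen <- qsar_preset("table2_generalized")
  fp <- setNames(rep(0, 9), paste0("FP", 1:9))
  fp["FP9"] <- 1.5
  prof <- contribution_profile(gen, fp)
  expect_equal(prof$groups$hydrophobic, 1.969 * 1.5)
  expect_equal(prof$total, predict_pic50(gen, fp), tolerance = 1e-9)
  # all-zero fingerprint: all groups zero, total = intercept
  prof0 <- contribution_profile(gen, fp * 0)
  expect_true(all(abs(unlist(prof0$groups)) < 1e-12))
  expect_equal(prof0$total, 0.755)
  # a log P_C difference of 0.325 moves the hydrophobic group by 0.640
  fp2 <- fp; fp2["FP9"] <- 1.5 - 0.325
  d <- prof$groups$hydrophobic - contribution_profile(gen, fp2)$groups$hydrophobic
  expect_equal(round(d, 3), 0.640)
})

test_that("model JSON round-trips", {
  m <- qsar_preset("table2_generalized")
  path <- tempfile(fileext = ".json")
  write_qsar_model(m, path)
  back <- read_qsar_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$provenance, "table2_generalized")
})
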
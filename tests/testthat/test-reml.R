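test_that("REML matches a grid-search maximizer of the restricted
           likelihood (single kernel, n = 12)", {
  set.seed(101)
  K <- crossprod(matrix(rnorm(12 * 12), 12)) / 12
  diag(K) <- diag(K) + 0.1
  u <- drop(crossprod(chol(K), rnorm(12)))
  y <- 5 + sqrt(2) * u + rnorm(12, 0, 1)
  fit <- fit_reml(y, list(add = K))
  grids <- list(sa = seq(0.01, 8, length.out = 200),
                se = seq(0.01, 8, length.out = 200))
  best <- reml_grid_oracle(y, list(K), grids)
  cell <- c(diff(grids$sa[1:2]), diff(grids$se[1:2]))
  expect_lt(abs(fit$estimates[["add"]] - best[[1]]), cell[1] * 1.01)
  expect_lt(abs(fit$estimates[["residual"]] - best[[2]]), cell[2] * 1.01)
  # and the fitted maximum is at least as high as the grid's
  ll_fit <- restricted_logL_oracle(y, list(K), fit$estimates)
  ll_grid <- restricted_logL_oracle(y, list(K), best)
  expect_gte(ll_fit, ll_grid - 1e-8)
  expect_equal(fit$logL, ll_fit, tolerance = 1e-6)
})

test_that("REML matches a coarse grid oracle with two kernels (n = 15)", {
  set.seed(103)
  K1 <- crossprod(matrix(rnorm(15 * 15), 15)) / 15
  K2 <- crossprod(matrix(rnorm(15 * 15), 15)) / 15
  diag(K1) <- diag(K1) + 0.2
  diag(K2) <- diag(K2) + 0.2
  y <- 2 + drop(crossprod(chol(K1), rnorm(15))) +
    0.8 * drop(crossprod(chol(K2), rnorm(15))) + rnorm(15, 0, 0.7)
  fit <- fit_reml(y, list(add = K1, dom = K2))
  grids <- list(s1 = seq(0.005, 5, length.out = 40),
                s2 = seq(0.005, 5, length.out = 40),
                se = seq(0.005, 5, length.out = 40))
  best <- reml_grid_oracle(y, list(K1, K2), grids)
  ll_fit <- restricted_logL_oracle(y, list(K1, K2), fit$estimates)
  ll_grid <- restricted_logL_oracle(y, list(K1, K2), best)
  expect_gte(ll_fit, ll_grid - 1e-8)
  cell <- diff(grids$s1[1:2])
  for (j in 1:3)
    expect_lt(abs(fit$estimates[[j]] - best[[j]]), cell * 1.5)
})

test_that("an identity-like kernel is reported as confounded", {
  set.seed(107)
  y <- rnorm(30)
  expect_warning(fit_reml(y, list(add = diag(30))), "confounded")
})

test_that("a true-zero dominance component is boundary-fixed and the AD
           model never beats the A model by more than noise", {
  dat <- small_study()  # simulated with dominance variance 0
  spA <- model_spec("GBLUP-A")
  spAD <- model_spec("GBLUP-AD")
  fitA <- fit_reml(dat$y, dat$kernels, spec = spA)
  fitAD <- fit_reml(dat$y, dat$kernels, spec = spAD)
  expect_true(fitAD$boundary[["dom"]])
  expect_identical(fitAD$estimates[["dom"]], 0)
  expect_identical(fitAD$se[["dom"]], 0)
  expect_gte(fitAD$AIC, fitA$AIC - 1e-4)
  # AIC bookkeeping: -2 logL + 2 * free parameters
  expect_equal(fitA$AIC, -2 * fitA$logL + 2 * fitA$n_params)
  expect_identical(fit_reml(dat$y, dat$kernels, spec = spAD,
                            aic_count = "all")$n_params, 3L)
})

test_that("the restricted-likelihood gradient vanishes at the optimum in
           unconstrained coordinates", {
  dat <- small_study()
  fit <- fit_reml(dat$y, dat$kernels, spec = model_spec("GBLUP-A"))
  th <- fit$estimates
  eps <- 1e-4 * max(th)
  for (j in which(!fit$boundary)) {
    up <- dn <- th
    up[j] <- th[j] + eps
    dn[j] <- th[j] - eps
    Ks <- list(unclass(dat$kernels$G_A))
    grad <- (restricted_logL_oracle(dat$y, Ks, up) -
             restricted_logL_oracle(dat$y, Ks, dn)) / (2 * eps)
    expect_lt(abs(grad * th[j]), 1e-2)  # scale-free gradient criterion
  }
})

test_that("fits are equivariant under permutation of individuals", {
  dat <- small_study()
  sp <- model_spec("GBLUP-AD")
  fit <- fit_reml(dat$y, dat$kernels, spec = sp)
  set.seed(109)
  perm <- sample(names(dat$y))
  yp <- dat$y[perm]
  fitp <- fit_reml(yp, dat$kernels, spec = sp)
  expect_equal(fitp$estimates, fit$estimates, tolerance = 1e-6)
  expect_equal(fitp$logL, fit$logL, tolerance = 1e-6)
  pr <- predict_blup(dat$y, dat$kernels, fit, spec = sp)
  prp <- predict_blup(yp, dat$kernels, fitp, spec = sp)
  m <- match(pr$predictions$id, prp$predictions$id)
  expect_equal(prp$predictions$egv[m], pr$predictions$egv, tolerance = 1e-5)
})

test_that("BLUP and PEV equal the Gaussian-conditioning closed form
           (known zero mean, n = 8)", {
  set.seed(113)
  K <- crossprod(matrix(rnorm(64), 8)) / 8
  diag(K) <- diag(K) + 0.3
  s2u <- 1.7
  s2e <- 0.6
  y <- drop(crossprod(chol(s2u * K + s2e * diag(8)), rnorm(8)))
  names(y) <- paste0("i", 1:8)
  vc <- structure(list(estimates = c(add = s2u, residual = s2e),
                       boundary = c(add = FALSE, residual = FALSE),
                       label = NULL),
                  class = "VarianceComponents")
  pred <- predict_blup(y, list(add = K), vc, fixed_mean = FALSE)
  oracle <- conditioning_oracle(y, K, s2u, s2e)
  expect_equal(unname(pred$predictions$ebv), oracle$u_hat, tolerance = 1e-10)
  expect_equal(unname(pred$predictions$sep_ebv), sqrt(oracle$pev),
               tolerance = 1e-10)
  expect_equal(pred$predictions$egv, pred$predictions$ebv)
  expect_equal(pred$predictions$sep_egv, pred$predictions$sep_ebv)
})

test_that("BLUP interpolates the data in the vanishing-residual limit", {
  set.seed(127)
  K <- crossprod(matrix(rnorm(100), 10)) / 10
  diag(K) <- diag(K) + 0.5
  y <- 3 + drop(crossprod(chol(K), rnorm(10)))
  names(y) <- paste0("i", 1:10)
  vc <- structure(list(estimates = c(add = 1, residual = 1e-10),
                       boundary = c(add = FALSE, residual = FALSE),
                       label = NULL),
                  class = "VarianceComponents")
  pred <- predict_blup(y, list(add = K), vc)
  expect_equal(pred$predictions$egv, unname(y) - pred$beta_hat,
               tolerance = 1e-6)
})

test_that("EBV variance is shrunk below h2 times phenotypic variance", {
  dat <- small_study()
  sp <- model_spec("GBLUP-A")
  fit <- fit_reml(dat$y, dat$kernels, spec = sp)
  pred <- predict_blup(dat$y, dat$kernels, fit, spec = sp)
  h2 <- heritability(fit)$h2
  expect_lte(var(pred$predictions$ebv), h2 * var(dat$y) * 1.05)
})

test_that("goodness-of-fit correlations and t-tests behave", {
  set.seed(131)
  y <- rnorm(27)
  mk_pred <- function(v) structure(
    list(predictions = data.frame(id = seq_along(v), ebv = v, egv = v),
         label = NULL), class = "PredictionResult")
  exact <- goodness_of_fit(mk_pred(y), y)
  expect_equal(exact["additive", "r"], 1, tolerance = 1e-12)
  expect_lt(exact["additive", "p"], 1e-12)

  # orthonormal basis with both columns centered (orthogonal to intercept)
  Q <- qr.Q(qr(cbind(1, y - mean(y), rnorm(27))))[, 2:3]
  zero <- goodness_of_fit(mk_pred(Q[, 2]), y)
  expect_equal(zero["additive", "r"], 0, tolerance = 1e-10)
  expect_equal(zero["additive", "t"], 0, tolerance = 1e-10)
  expect_equal(zero["additive", "p"], 1, tolerance = 1e-10)

  # a constructed vector with correlation exactly 0.5 against y
  v <- 0.5 * Q[, 1] + sqrt(0.75) * Q[, 2]
  half <- goodness_of_fit(mk_pred(v), y)
  expect_equal(half["additive", "r"], 0.5, tolerance = 1e-10)
  expect_equal(half["additive", "t"], 0.5 * 5 / sqrt(0.75),
               tolerance = 1e-10)
  expect_equal(round(half["additive", "t"], 4), 2.8868)
})

test_that("model comparison ranks by AIC with the penalty applied", {
  mk <- function(logL, k, label) structure(
    list(logL = logL, n_params = k, AIC = -2 * logL + 2 * k, label = label),
    class = "VarianceComponents")
  tab <- model_comparison(list(mk(-100, 2, "m2"), mk(-100, 3, "m3")))
  expect_equal(tab$AIC[tab$label == "m2"], 204)
  expect_identical(tab$label[1], "m2")
  expect_equal(tab$delta_AIC, c(0, 2))
})
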
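# Design matrices, AI-REML fitting, likelihood ratios and heritabilities

test_that("design matrices use treatment coding and expand nested slopes", {
  ph <- data.frame(sex = factor(c("F", "F", "M", "M")),
                   age = c(30, 40, 50, 60))
  dm <- build_design_matrix(ph, fixed_effects_spec(factors = "sex"))
  expect_equal(ncol(dm$X), 2)
  expect_equal(unname(dm$X[, "sexM"]), c(0, 0, 1, 1))

  dm2 <- build_design_matrix(
    ph, fixed_effects_spec(factors = "sex",
                           nested_slopes = list(c("age", "sex"))))
  expect_true(all(c("age.sexF", "age.sexM") %in% colnames(dm2$X)))
  expect_equal(unname(dm2$X[, "age.sexF"]), c(30, 40, 0, 0))
  expect_equal(unname(dm2$X[, "age.sexM"]), c(0, 0, 50, 60))
})

test_that("aliased factor columns are dropped to full rank", {
  # village is constant within each population: its indicators are aliased
  ph <- data.frame(population = factor(rep(c("P1", "P2"), each = 4)),
                   village = factor(rep(c("V1", "V2"), each = 4)))
  expect_warning(
    dm <- build_design_matrix(
      ph, fixed_effects_spec(factors = c("population", "village"))),
    "aliased")
  expect_equal(ncol(dm$X), qr(cbind(1, ph$population == "P2",
                                    ph$village == "V2"))$rank)
  # a single-level factor is dropped with a warning
  ph2 <- data.frame(sex = factor(rep("F", 5)), age = 1:5)
  expect_warning(build_design_matrix(ph2,
                                     fixed_effects_spec(factors = "sex")),
                 "one observed level")
})

test_that("intercept-only REML equals the n-1 sample variance", {
  f <- reml_fit(c(1, 2, 3))
  expect_equal(unname(f$sigma2), 1)
  f2 <- reml_fit(rnorm(20) * 3 + 7)
  expect_equal(unname(f2$sigma2), var(f2$y), tolerance = 1e-8)
})

test_that("AI-REML matches a grid-search likelihood oracle", {
  withr::local_seed(101)
  K <- kronecker(diag(4), matrix(0.5, 3, 3)); diag(K) <- 1
  n <- 12
  X <- cbind(1, rnorm(n))
  y <- drop(t(chol(3 * K + diag(2, n))) %*% rnorm(n)) + X %*% c(5, 1)
  fit <- reml_fit(y, X, kernels = list(fam = K), tol = 1e-10)

  logl <- function(s2) {
    V <- s2[1] * K + diag(s2[2], n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    -0.5 * (as.numeric(determinant(V)$modulus) +
            log(det(XtViX)) + sum(y * (P %*% y)))
  }
  # coarse-to-fine grid over both variances
  g <- expand.grid(a = seq(0.1, 12, by = 0.1), b = seq(0.1, 12, by = 0.1))
  v <- mapply(function(a, b) logl(c(a, b)), g$a, g$b)
  c0 <- unlist(g[which.max(v), ])
  g2 <- expand.grid(a = seq(max(1e-4, c0[1] - 0.11), c0[1] + 0.11,
                            by = 1e-3),
                    b = seq(max(1e-4, c0[2] - 0.11), c0[2] + 0.11,
                            by = 1e-3))
  v2 <- mapply(function(a, b) logl(c(a, b)), g2$a, g2$b)
  c1 <- unlist(g2[which.max(v2), ])
  expect_lt(abs(fit$sigma2[[1]] - c1[[1]]), 1.5e-3)
  expect_lt(abs(fit$sigma2[[2]] - c1[[2]]), 1.5e-3)
  expect_gte(fit$logL_reml, max(v2) - 1e-8)
})

test_that("AI-REML agrees with a derivative-free optimizer on a 3-component model", {
  withr::local_seed(103)
  n <- 40
  K1 <- tcrossprod(matrix(rnorm(n * 3), n, 3)) / 3 + diag(0.05, n)
  K2 <- kronecker(diag(8), matrix(1, 5, 5))
  X <- cbind(1, rnorm(n))
  V0 <- 2 * K1 + 1.5 * K2 + diag(1, n)
  y <- drop(t(chol(V0)) %*% rnorm(n)) + drop(X %*% c(1, 2))
  fit <- reml_fit(y, X, kernels = list(k1 = K1, k2 = K2))

  logl <- function(ls2) {
    s2 <- exp(ls2)
    V <- s2[1] * K1 + s2[2] * K2 + diag(s2[3], n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    -0.5 * (as.numeric(determinant(V)$modulus) +
            log(det(XtViX)) + sum(y * (P %*% y)))
  }
  opt <- optim(log(pmax(fit$sigma2, 0.2)), function(p) -logl(p),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(unname(fit$sigma2), unname(exp(opt$par)), tolerance = 1e-4)
  expect_gte(fit$logL_reml + 1e-6, -opt$value)
})

test_that("REML log-likelihood is invariant to equivalent fixed-effect codings", {
  withr::local_seed(107)
  n <- 18
  K <- tcrossprod(matrix(rnorm(n * 4), n, 4)) / 4 + diag(0.1, n)
  f <- factor(rep(c("a", "b", "c"), each = 6))
  y <- rnorm(n) + as.numeric(f)
  X1 <- model.matrix(~f)                       # treatment coding
  X2 <- model.matrix(~ 0 + f)                  # cell means coding
  f1 <- reml_fit(y, X1, kernels = list(K = K))
  f2 <- reml_fit(y, X2, kernels = list(K = K))
  expect_equal(f1$logL_reml, f2$logL_reml, tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
})

test_that("the LRT is a floored doubled log-likelihood difference on nested fits", {
  withr::local_seed(109)
  n <- 15
  K <- tcrossprod(matrix(rnorm(n * 3), n, 3)) / 3 + diag(0.1, n)
  y <- rnorm(n)
  f0 <- reml_fit(y)
  f1 <- reml_fit(y, kernels = list(K = K))
  expect_equal(lrt(f0, f0), 0)
  expect_equal(lrt(f0, f1), max(0, 2 * (f1$logL_reml - f0$logL_reml)))
  # constructed near-degenerate pair: alternative marginally below null
  f1b <- f1; f1b$logL_reml <- f0$logL_reml - 1e-9
  expect_equal(lrt(f0, f1b), 0)
  # synthetic fits with a known gap of 2 log-units give exactly 4
  f1c <- f1; f1c$logL_reml <- f0$logL_reml + 2
  expect_equal(lrt(f0, f1c), 4)
  # different response is rejected
  f2 <- reml_fit(y + 1)
  expect_error(lrt(f2, f1), "same response")
  expect_error(lrt(f1, f0), "more components")
})

test_that("heritabilities divide by the summed variance and report the genetic total", {
  fit <- structure(list(sigma2 = c(genomic = 3, regional = 1,
                                   residual = 6)),
                   class = "reml_fit")
  h <- heritabilities(fit)
  expect_equal(as.numeric(h), c(0.3, 0.1, 0.6))
  expect_equal(attr(h, "total_genetic"), 0.4)
  fit0 <- structure(list(sigma2 = c(genomic = 0, residual = 2)),
                    class = "reml_fit")
  expect_equal(attr(heritabilities(fit0), "total_genetic"), 0)
  fitz <- structure(list(sigma2 = c(genomic = 0, residual = 0)),
                    class = "reml_fit")
  expect_error(heritabilities(fitz), "zero")
})

test_that("fit methods expose GLS coefficients, fitted values and simulation", {
  withr::local_seed(113)
  n <- 30
  K <- tcrossprod(matrix(rnorm(n * 5), n, 5)) / 5 + diag(0.1, n)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(2, 1)) + drop(t(chol(K + diag(0.5, n))) %*% rnorm(n))
  fit <- reml_fit(y, X, kernels = list(K = K))
  expect_length(coef(fit), 2)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_s3_class(summary(fit), "summary.reml_fit")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
  expect_equal(as.numeric(logLik(fit)), fit$logL_reml)
})

test_that("bounded components are reported and kept in the model", {
  withr::local_seed(127)
  n <- 40
  K <- kronecker(diag(8), matrix(0.6, 5, 5)); diag(K) <- 1
  y <- rnorm(n)                  # no genetic signal at all
  fit <- reml_fit(y, kernels = list(K = K))
  expect_length(fit$sigma2, 2)   # component retained even if on the bound
  expect_true(all(fit$sigma2 >= 0))
  if (fit$bounded[1]) expect_equal(unname(fit$sigma2[1]), 0)
})

test_that("two-step mode holds a named component fixed", {
  withr::local_seed(131)
  n <- 30
  K <- tcrossprod(matrix(rnorm(n * 6), n, 6)) / 6 + diag(0.1, n)
  y <- drop(t(chol(2 * K + diag(1, n))) %*% rnorm(n))
  fit <- reml_fit(y, kernels = list(genomic = K),
                  fixed_sigma2 = c(genomic = 1.5))
  expect_equal(unname(fit$sigma2["genomic"]), 1.5)
})
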
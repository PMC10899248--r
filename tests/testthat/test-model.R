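test_that("free-parameter counts follow the family definitions", {
  expect_identical(gcsem_model("cholesky", k = 8)$n_par, 72L)
  expect_identical(gcsem_model("ipc", k = 8, n_shared = 3)$n_par, 68L)
  m1 <- gcsem_model("cholesky", k = 1)
  expect_identical(m1$n_par, 2L)
  # bifactor = general column + grouping + specifics + residual Cholesky;
  # grouping columns restricted to disjoint trait blocks for identification
  cons <- data.frame(part = "genetic",
                     row = c(4:6, 1:3), col = rep(2:3, each = 3), value = 0)
  mb <- gcsem_model("bifactor", k = 6, n_shared = 2, constraints = cons)
  expect_identical(mb$n_par, 6L + 6L + 6L + 21L)
})

test_that("constraints are validated and counted", {
  cons <- data.frame(part = "genetic", row = 1, col = 2, value = 0)
  m <- gcsem_model("ipc", k = 5, n_shared = 2, constraints = cons)
  expect_identical(m$n_par, gcsem_model("ipc", k = 5, n_shared = 2)$n_par - 1L)
  expect_error(
    gcsem_model("cholesky", k = 3,
                constraints = data.frame(part = "genetic", row = 1, col = 3)),
    "structurally absent")
  expect_error(gcsem_model("bifactor", k = 8, n_shared = 3), "unidentified")
})

test_that("rotated log-likelihood equals the dense Kronecker density", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(1:3, 1)
    n <- sample(5:12, 1)
    g <- random_grm(n, seed = seed + 100)
    Y <- matrix(rnorm(n * k), n, dimnames = list(g$ids$IID, NULL))
    mod <- gcsem_model("cholesky", k = k)
    th <- random_theta(mod, seed + 200)
    L <- gcsem:::theta_fill(mod, th)
    expect_equal(gcsem_loglik(mod, th, g, Y),
                 dense_loglik(L$LA, L$LE, g$values, Y), tolerance = 1e-10)
  }
})

test_that("with zero genetic loadings the likelihood ignores the GRM", {
  n <- 10
  g1 <- random_grm(n, seed = 1)
  g2 <- random_grm(n, seed = 2)
  Y <- matrix(rnorm(n * 2), n, dimnames = list(g1$ids$IID, NULL))
  mod <- gcsem_model("cholesky", k = 2)
  th <- c(0, 0, 0, 0.9, 0.2, 0.8)          # Lambda_A = 0
  expect_equal(gcsem_loglik(mod, th, g1, Y), gcsem_loglik(mod, th, g2, Y),
               tolerance = 1e-10)
})

test_that("with an identity GRM only the total covariance is identified", {
  n <- 12
  g <- as_grm(diag(n))
  Y <- matrix(rnorm(n * 2), n, dimnames = list(g$ids$IID, NULL))
  mod <- gcsem_model("cholesky", k = 2)
  # two parameterizations with equal Lambda_A Lambda_A' + Lambda_E Lambda_E'
  th1 <- c(0.6, 0.3, 0.5, 0.7, 0.1, 0.6)
  L <- gcsem:::theta_fill(mod, th1)
  tot <- tcrossprod(L$LA) + tcrossprod(L$LE)
  C <- t(chol(tot))
  th2 <- c(0, 0, 0, C[1, 1], C[2, 1], C[2, 2])
  expect_equal(gcsem_loglik(mod, th1, g, Y), gcsem_loglik(mod, th2, g, Y),
               tolerance = 1e-8)
})

test_that("non-positive-definite parameter values return -Inf with a reason", {
  g <- random_grm(6, seed = 5)
  Y <- matrix(rnorm(12), 6, dimnames = list(g$ids$IID, NULL))
  mod <- gcsem_model("cholesky", k = 2)
  ll <- gcsem_loglik(mod, c(0.5, 0.2, 0.4, 0, 0, 0), g, Y)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "reason"), "positive definite")
})

test_that("one-trait Cholesky reproduces univariate GREML", {
  d <- two_factor_data()
  y <- d$pheno[, 1, drop = FALSE]
  gr <- greml(d$pheno[, 1], d$grm)
  f <- gcsem(y, d$grm, gcsem_model("cholesky", k = 1))
  std <- standardize_solution(f)
  expect_equal(std$h2$h2, gr$h2, tolerance = 1e-4)
  expect_equal(f$loglik, gr$loglik, tolerance = 1e-5)
  expect_equal(std$h2$se, gr$h2_se, tolerance = 1e-3)
})

test_that("the saturated model dominates nested IPC fits", {
  d <- two_factor_data()
  ch <- two_factor_cholesky()
  ipc <- gcsem(d$pheno, d$grm, scenario_model(d$scenario))
  expect_gte(ch$loglik, ipc$loglik - 1e-4)
})

test_that("reported solutions are sign-canonicalized", {
  ch <- two_factor_cholesky()
  for (j in 1:6) {
    col <- ch$LA[, j]
    nz <- which(abs(col) > 1e-8)
    if (length(nz)) expect_gt(col[nz[1]], 0)
  }
})

test_that("fits are deterministic given data and options", {
  d <- two_factor_data()
  f1 <- gcsem(d$pheno[, 1:2], d$grm, gcsem_model("cholesky", k = 2))
  f2 <- gcsem(d$pheno[, 1:2], d$grm, gcsem_model("cholesky", k = 2))
  expect_identical(f1$theta, f2$theta)
})

test_that("standardized-solution arithmetic matches the closed forms", {
  # genetic covariance [[0.25, 0.2], [0.2, 0.64]] gives r_g = 0.5
  mod <- gcsem_model("cholesky", k = 2)
  LA <- matrix(c(0.5, 0.4, 0, sqrt(0.64 - 0.16)), 2)
  # residuals complete the variance to 1
  LE <- diag(sqrt(1 - c(0.25, 0.64)))
  th <- c(LA[lower.tri(LA, diag = TRUE)], LE[lower.tri(LE, diag = TRUE)])
  q <- gcsem:::std_quantities(mod, th)
  k <- 2
  rg <- matrix(q[2 * 4 + k + seq_len(4)], 2)
  expect_equal(rg[1, 2], 0.2 / sqrt(0.25 * 0.64), tolerance = 1e-12)
  h2 <- q[2 * 4 + seq_len(k)]
  expect_equal(h2, c(0.25, 0.64), tolerance = 1e-10)

  # trait with standardized genetic loadings 0.3 (shared) and 0.4 (specific):
  # f2 shared = 0.09 / 0.25, f2 specific = 0.16 / 0.25, h2 = 0.25
  modi <- gcsem_model("ipc", k = 3, n_shared = 1)
  LAi <- cbind(rep(0.3, 3), diag(0.4, 3))
  LEi <- diag(sqrt(1 - 0.25), 3)
  thi <- c(LAi[is.na(modi$genetic)], LEi[is.na(modi$residual)])
  qi <- gcsem:::std_quantities(modi, thi)
  npa <- 3 * 4
  f2 <- matrix(qi[npa + 9 + 3 + 9 + seq_len(npa)], 3)
  expect_equal(f2[1, 1], 0.36, tolerance = 1e-10)
  expect_equal(f2[1, 2], 0.64, tolerance = 1e-10)
  h2i <- qi[npa + 9 + seq_len(3)]
  expect_equal(h2i, rep(0.25, 3), tolerance = 1e-10)
})

test_that("per-trait standardized variance decomposition sums to one", {
  ch <- two_factor_cholesky()
  std <- standardize_solution(ch)
  tot <- rowSums(std$lambda_genetic^2) + rowSums(std$lambda_residual^2)
  expect_equal(unname(tot), rep(1, 6), tolerance = 1e-6)
  expect_true(all(std$h2$h2 >= 0 & std$h2$h2 <= 1))
  expect_equal(unname(diag(std$rg)), rep(1, 6), tolerance = 1e-10)
  expect_lte(max(abs(std$rg)), 1 + 1e-8)
  # factorial co-heritabilities per trait sum to 1
  expect_equal(unname(rowSums(std$f2)), rep(1, 6), tolerance = 1e-8)
})

test_that("Delta-method SEs agree with a parametric bootstrap", {
  d <- two_factor_data()
  Y3 <- d$pheno[, 1:3]
  f <- gcsem(Y3, d$grm, gcsem_model("cholesky", k = 3))
  std <- standardize_solution(f)
  set.seed(77)
  ev <- eigen(f$vcov, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  draws <- replicate(300, {
    th <- as.numeric(f$theta) + as.numeric(rt %*% rnorm(f$n_par))
    gcsem:::std_quantities(f$model, th)
  })
  boot_se <- apply(draws, 1, sd)
  # compare on the h2 entries (smooth, well away from boundaries)
  idx <- 2 * 9 + seq_len(3)
  expect_equal(std$h2$se, boot_se[idx], tolerance = 0.15)
})

test_that("mapping extension adds the documented structure", {
  d <- two_factor_data()
  mod <- scenario_model(d$scenario)
  f <- gcsem(d$pheno, d$grm, mod)
  ext <- extend_with_mapping(f, "map")
  expect_identical(ext$n_par, mod$n_par + 2L + 1L + 7L)
  expect_equal(ext$k, 7)
  # base constraints preserved
  expect_identical(ext$genetic[1:6, 1:2], mod$genetic[, 1:2])

  # null mapping: unrelated variable loads on nothing
  set.seed(88)
  null_map <- standardize_traits(rnorm(800))
  Ym <- cbind(d$pheno, map = null_map)
  fm <- gcsem(Ym, d$grm, ext)
  stdm <- standardize_solution(fm)
  lam <- stdm$lambda_genetic[7, 1:2]
  se <- stdm$lambda_se$genetic[7, 1:2]
  expect_true(all(abs(lam) < 2.5 * pmax(se, 0.05)))

  # constructed mapping: 0.6 x genetic factor 1 + noise
  fs <- attr(d$pheno, "factor_scores")$genetic
  set.seed(89)
  built <- standardize_traits(0.6 * fs[, 1] + 0.8 * rnorm(800))
  Yb <- cbind(d$pheno, map = built)
  fb <- gcsem(Yb, d$grm, ext)
  stdb <- standardize_solution(fb)
  expect_lt(abs(stdb$lambda_genetic[7, 1] - 0.6),
            2.5 * max(stdb$lambda_se$genetic[7, 1], 0.05))
  expect_lt(abs(stdb$lambda_genetic[7, 2]),
            2.5 * max(stdb$lambda_se$genetic[7, 2], 0.05))
  expect_error(extend_with_mapping(gcsem_model("cholesky", 3)), "IPC")
})
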
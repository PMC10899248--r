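test_that("the joint Kaiser/optimal-coordinate rule matches hand computations", {
  # line through positions (i+1, k): predictions 2.2, 1.4, 0.575 for i=1..3,
  # all exceeded while eigenvalues stay above 1; position 4 fails Kaiser
  expect_identical(n_factors_scree(c(3.2, 1.8, 1.1, 0.45, 0.25, 0.2))$n_factors,
                   3)
  expect_identical(genetic_pca(diag(6))$n_factors, 0)
  expect_error(genetic_pca(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(genetic_pca(matrix(c(2, 0.5, 0.5, 2), 2)), "unit diagonal")
})

test_that("EFA reproduces an exact two-factor construction", {
  L <- rbind(c(0.7, 0), c(0.6, 0), c(0.5, 0),
             c(0, 0.7), c(0, 0.6), c(0, 0.5))
  S <- tcrossprod(L) + diag(0.4, 6)
  sol <- efa_genetic(S, n_factors = 2, rotation = "varimax")
  expect_lt(sol$discrepancy, 1e-8)
  # congruence with the generating loadings, up to column order/sign
  cong <- abs(crossprod(sol$loadings, L)) /
    outer(sqrt(colSums(sol$loadings^2)), sqrt(colSums(L^2)))
  expect_true(all(apply(cong, 2, max) > 0.999))
  expect_false(sol$heywood)
  expect_identical(sol$interfactor_corr, diag(2))
})

test_that("uniform weights and identity weights give the same solution", {
  L <- rbind(c(0.7, 0), c(0.6, 0.2), c(0.5, 0.1),
             c(0.1, 0.7), c(0, 0.6), c(0.2, 0.5))
  S <- tcrossprod(L) + diag(0.35, 6)
  s_id <- efa_genetic(S, NULL, n_factors = 2, rotation = "varimax")
  s_w <- efa_genetic(S, matrix(0.37, 6, 6), n_factors = 2,
                     rotation = "varimax")
  expect_equal(s_id$loadings, s_w$loadings, tolerance = 1e-5)
})

test_that("EFA agrees with an independent ML implementation", {
  # factanal (ML on a correlation matrix) is an independent minimizer; on a
  # clean structure both recover the same pattern up to rotation details
  set.seed(12)
  L <- rbind(c(0.75, 0), c(0.65, 0), c(0.6, 0.15),
             c(0, 0.7), c(0.1, 0.65), c(0, 0.6))
  S <- tcrossprod(L) + diag(1 - rowSums(L^2))
  ours <- efa_genetic(S, n_factors = 2, rotation = "varimax")
  fa <- stats::factanal(covmat = S, factors = 2, rotation = "varimax")
  Lfa <- unclass(fa$loadings)
  cong <- abs(crossprod(ours$loadings, Lfa)) /
    outer(sqrt(colSums(ours$loadings^2)), sqrt(colSums(Lfa^2)))
  expect_true(all(apply(cong, 2, max) > 0.99))
})

test_that("EFA validates factor count and flags Heywood cases", {
  S <- diag(3)
  expect_error(efa_genetic(S, n_factors = 2), "degrees of freedom")
  # a matrix demanding communality > diagonal forces negative uniqueness
  Sh <- rbind(c(0.5, 0.69, 0.69), c(0.69, 1, 0.4), c(0.69, 0.4, 1))
  sol <- efa_genetic(Sh, n_factors = 1)
  expect_true(sol$heywood)
})

test_that("rotation choice follows the documented rules", {
  fake <- function(Phi, load) {
    structure(list(loadings = load, interfactor_corr = Phi,
                   n_factors = 2, rotation = "x"), class = "genetic_efa")
  }
  Lv <- rbind(c(0.6, 0.05), c(0.05, 0.6))
  # modest oblique correlation: varimax wins
  ch <- choose_rotation(fake(matrix(c(1, .1, .1, 1), 2), Lv),
                        fake(diag(2), Lv))
  expect_match(attr(ch, "decision"), "^varimax")
  # strong correlation, differing patterns: oblimin wins
  Lo <- rbind(c(0.6, 0.3), c(0.05, 0.6))
  ch2 <- choose_rotation(fake(matrix(c(1, .6, .6, 1), 2), Lo),
                         fake(diag(2), Lv))
  expect_match(attr(ch2, "decision"), "^oblimin")
  # strong correlation but identical thresholded patterns: varimax wins
  ch3 <- choose_rotation(fake(matrix(c(1, .6, .6, 1), 2), Lv),
                         fake(diag(2), Lv))
  expect_match(attr(ch3, "decision"), "^varimax")
})

test_that("EFA-to-IPC translation applies the zero-loading rule", {
  L <- rbind(c(0.65, 0.05), c(0.55, 0.02), c(0.15, -0.03),
             c(0.04, 0.6), c(-0.09, 0.5), c(0.02, 0.45))
  sol <- structure(list(loadings = L, interfactor_corr = diag(2),
                        n_factors = 2, rotation = "varimax"),
                   class = "genetic_efa")
  mod <- build_ipc_from_efa(sol)
  expect_identical(mod$family, "ipc")
  expect_identical(mod$genetic[1, 2], 0)    # |0.05| < 0.10 fixed
  expect_true(is.na(mod$genetic[1, 1]))     # |0.65| free
  expect_true(is.na(mod$genetic[3, 1]))     # |0.15| free
  expect_identical(sum(is.na(mod$genetic[, 1:2])), 6L)
  # starting values carry the EFA loadings
  expect_equal(mod$start$genetic[1, 1], 0.65)

  # all loadings above threshold: fully free shared block
  Lbig <- matrix(0.4, 6, 2)
  solb <- structure(list(loadings = Lbig, interfactor_corr = diag(2),
                         n_factors = 2, rotation = "varimax"),
                    class = "genetic_efa")
  expect_identical(sum(is.na(build_ipc_from_efa(solb)$genetic[, 1:2])), 12L)

  # a factor entirely below threshold is dropped with a warning
  Lz <- cbind(c(0.5, 0.6, 0.4, 0.5, 0.6, 0.4), rep(0.05, 6))
  solz <- structure(list(loadings = Lz, interfactor_corr = diag(2),
                         n_factors = 2, rotation = "varimax"),
                    class = "genetic_efa")
  expect_warning(mz <- build_ipc_from_efa(solz), "dropped")
  expect_identical(ncol(mz$genetic), 1L + 6L)
})

test_that("trimming removes near-zero specific loadings and lowers N_par", {
  d <- two_factor_data()
  mod <- scenario_model(d$scenario)
  f <- gcsem(d$pheno, d$grm, mod)
  # default threshold: nothing to trim on data with true specifics of 0.3
  expect_identical(gcsem_trim(f, d$pheno, d$grm)$n_par, f$n_par)
  # a coarse threshold forces trimming and a refit with fewer parameters
  tr <- gcsem_trim(f, d$pheno, d$grm, threshold = 0.5)
  expect_lt(tr$n_par, f$n_par)
  expect_identical(f$n_par - tr$n_par, length(attr(tr, "trimmed")))
  expect_lte(tr$loglik, f$loglik + 1e-4)
})

test_that("information criteria reproduce printed-model arithmetic", {
  fake_fit <- function(ll, np, n, k = 8) {
    structure(list(loglik = ll, n_par = np, n_ind = n,
                   model = list(k = k),
                   pheno_cov = diag(k), SigmaA = diag(0.3, k),
                   SigmaE = diag(0.7, k), SigmaV = diag(k)),
              class = "gcsem")
  }
  fits <- list(saturated = fake_fit(-15248.61, 72, 5279),
               ipc = fake_fit(-15250.96, 53, 5279))
  cmp <- compare_models(fits)
  expect_equal(cmp$table$AIC[2], 30607.92, tolerance = 1e-8)
  expect_equal(cmp$table$AIC[1], 30641.22, tolerance = 1e-8)
  expect_equal(cmp$table$BIC[2], -2 * -15250.96 + 53 * log(5279),
               tolerance = 1e-10)
  expect_identical(cmp$best, "ipc")
  expect_equal(cmp$lrt$df, 19)
  expect_equal(cmp$lrt$chi2, 2 * (15250.96 - 15248.61), tolerance = 1e-8)

  # equal log-likelihoods: chi2 = 0, p > 0.99
  fits2 <- list(a = fake_fit(-100, 25, 1000), b = fake_fit(-100, 6, 1000))
  cmp2 <- compare_models(fits2)
  expect_identical(cmp2$lrt$chi2, 0)
  expect_gt(cmp2$lrt$p, 0.99)

  # AIC/BIC ordering invariant to a constant shift of all log-likelihoods
  fits3 <- list(a = fake_fit(-90, 25, 1000), b = fake_fit(-100, 6, 1000))
  ord1 <- order(compare_models(fits3)$table$AIC)
  fits4 <- list(a = fake_fit(-90 + 55, 25, 1000),
                b = fake_fit(-100 + 55, 6, 1000))
  ord2 <- order(compare_models(fits4)$table$AIC)
  expect_identical(ord1, ord2)
  expect_error(compare_models(list(a = fake_fit(-90, 6, 1000),
                                   b = fake_fit(-80, 6, 1000))),
               "not nested")
})

test_that("SRMR matches its hand example and the saturated-fit property", {
  fake <- structure(list(model = list(k = 2),
                         pheno_cov = matrix(c(1, .5, .5, 1), 2),
                         SigmaV = matrix(c(1, .3, .3, 1), 2)),
                    class = "gcsem")
  expect_equal(srmr(fake), sqrt(0.2^2 / 3), tolerance = 1e-12)
  expect_equal(srmr(fake, observed = matrix(c(1, .3, .3, 1), 2)), 0,
               tolerance = 1e-12)
  expect_error(srmr(fake, observed = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  ch <- two_factor_cholesky()
  expect_lt(srmr(ch), 0.01)
})

test_that("spectral Meff matches its closed forms", {
  expect_equal(meff_spectral(diag(5))$meff, 5)
  expect_equal(meff_spectral(matrix(c(1, 1, 1, 1), 2))$meff, 1)
  m34 <- meff_spectral(diag(34), alpha = 0.05)
  expect_equal(m34$threshold, 0.05 / 34, tolerance = 1e-12)
  expect_error(meff_spectral(matrix(c(1, -2, -2, 1), 2)), "semi-definite")
})
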
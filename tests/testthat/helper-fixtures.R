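# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small random PSD GRM with ids (not genotype-derived; for algebra tests).
random_grm <- function(n, seed = 1, m = n + 10) {
  set.seed(seed)
  Z <- matrix(rnorm(n * m), n, m)
  as_grm(tcrossprod(Z) / m)
}

# Two-trait-per-factor dataset used by several modelling tests:
# six traits, two shared genetic factors, n = 800, m = 600 loci.
two_factor_data <- function() {
  fixture("two_factor_data", function() {
    sc <- two_factor_scenario(n_individuals = 800, n_causal_loci = 600,
                              seed = 71)
    X <- sim_genotypes(800, 600, seed = 72)
    Y <- sim_phenotypes(sc, X, seed = 73)
    grm <- grm_eigen(compute_grm(X))
    list(scenario = sc, genotypes = X, pheno = Y, grm = grm)
  })
}

# Saturated fit on the two-factor data (computed once).
two_factor_cholesky <- function() {
  fixture("two_factor_cholesky", function() {
    d <- two_factor_data()
    gcsem(d$pheno, d$grm, gcsem_model("cholesky", k = 6))
  })
}

# Dense Kronecker-product Gaussian log-density: the independent oracle for
# the rotated likelihood.
dense_loglik <- function(LA, LE, G, Y) {
  n <- nrow(G)
  k <- ncol(Y)
  V <- kronecker(tcrossprod(LA), G) + kronecker(tcrossprod(LE), diag(n))
  y <- as.vector(Y)
  as.numeric(-0.5 * (n * k * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(y) %*% solve(V, y)))
}

# Random admissible theta for a model: keeps residual diagonal away from 0
# so Sigma_E stays positive definite.
random_theta <- function(model, seed) {
  set.seed(seed)
  th <- runif(model$n_par, -0.8, 0.8)
  L <- gcsem:::theta_fill(model, th)
  diag(L$LE) <- pmax(abs(diag(L$LE)), 0.3)
  c(L$LA[is.na(model$genetic)], L$LE[is.na(model$residual)])
}
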
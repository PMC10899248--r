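#' GREML variance-component estimation
#'
#' Univariate and bivariate restricted/maximum-likelihood variance-component
#' estimation from a GRM. The univariate model is
#' \eqn{y \sim N(Xb, \sigma^2_g G + \sigma^2_e I)}; the bivariate model adds
#' genetic and residual cross-trait covariances, from which the genetic
#' correlation \eqn{r_g = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}}
#' follows with a Delta-method SE.
#'
#' Phenotypes prepared with [prepare_phenotypes()] are exactly mean-zero, so
#' by default no fixed effects are estimated and the objective is the plain
#' Gaussian likelihood — identical to a one-trait Cholesky GRM-SEM fit. When
#' `covariates` are supplied, an intercept plus covariates are projected out
#' with the standard REML correction.
#'
#' The univariate fit profiles out the overall scale and maximizes over the
#' heritability ratio on `[0, 1)` by golden-section search, which is
#' deterministic and handles the boundary \eqn{\sigma^2_g = 0} exactly; the
#' evidence against \eqn{\sigma^2_g = 0} uses the boundary likelihood-ratio
#' mixture \eqn{\frac12\chi^2_0 + \frac12\chi^2_1}. The bivariate fit uses
#' quasi-Newton search over the six covariance parameters. Bivariate fits
#' use individuals complete for both traits.
#'
#' @param y numeric trait vector with names, or a single-column matrix with
#'   row names, giving sample IDs.
#' @param grm a [as_grm()] object.
#' @param y2 optional second trait for a bivariate fit.
#' @param covariates optional numeric covariate matrix (IDs as row names);
#'   triggers REML with an intercept.
#' @return object of class `greml` with variance components, `h2` (+SE) per
#'   trait, the LRT against zero genetic variance (univariate), and `rg`
#'   (+SE) for bivariate fits. `rg` is `NA` with a flag when either trait's
#'   genetic variance collapses to the boundary.
#' @export
greml <- function(y, grm, y2 = NULL, covariates = NULL) {
  stopifnot(inherits(grm, "grm"))
  if (is.null(y2)) greml_uni(y, grm, covariates)
  else greml_biv(y, y2, grm)
}

greml_align <- function(y, grm) {
  y <- drop(as.matrix(y))
  ids <- names(y)
  if (is.null(ids)) {
    if (length(y) != nrow(grm$values))
      stop("unnamed trait vector does not match GRM dimension")
    ids <- grm$ids$IID
    names(y) <- ids
  }
  obs <- !is.na(y)
  ids <- intersect(grm$ids$IID, ids[obs])
  if (length(ids) < 3) stop("too few phenotyped individuals overlap the GRM")
  list(y = y[ids], grm = grm_subset(grm, ids))
}

greml_uni <- function(y, grm, covariates = NULL) {
  dat <- greml_align(y, grm)
  grm <- grm_eigen(dat$grm)
  n <- length(dat$y)
  if (n < 100) warning("fewer than 100 individuals; GREML will be unstable")
  if (max(abs(grm$values - diag(n))) < 1e-12)
    stop("GRM is the identity matrix; genetic variance is not identifiable")
  d <- grm$eigen$values
  U <- grm$eigen$vectors
  ys <- crossprod(U, dat$y)
  X <- NULL
  if (!is.null(covariates)) {
    Xr <- cbind(`(Intercept)` = 1, as.matrix(covariates)[names(dat$y), ,
                                                         drop = FALSE])
    X <- crossprod(U, Xr)
  }
  prof <- function(h) profile_ll(h, d, ys, X)
  opt <- stats::optimize(function(h) prof(h)$ll, c(0, 1 - 1e-8),
                         maximum = TRUE, tol = 1e-12)
  # the optimum can sit at the boundary; compare explicitly with h = 0
  cand <- list(opt = prof(opt$maximum), null = prof(0))
  h_hat <- if (cand$null$ll >= cand$opt$ll - 1e-10) 0 else opt$maximum
  best <- prof(h_hat)
  s2 <- best$scale
  sg <- h_hat * s2
  se2 <- (1 - h_hat) * s2
  ll <- best$ll
  ll0 <- cand$null$ll
  lrt <- max(2 * (ll - ll0), 0)
  p <- 0.5 * (lrt <= 1e-12) + 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  # observed information in (sigma2_g, sigma2_e)
  llsig <- function(th) profile_fixed(th[1], th[2], d, ys, X)
  H <- num_hessian(llsig, c(sg, se2))
  vc <- solve_vcov(-H)$vcov
  tot <- sg + se2
  gvec <- c(se2, -sg) / tot^2            # gradient of h2 = sg/(sg+se)
  h2_se <- sqrt(max(drop(t(gvec) %*% vc %*% gvec), 0))
  structure(list(type = "univariate", n_ind = n,
                 components = c(sigma2_g = sg, sigma2_e = se2),
                 vcov = vc, h2 = h_hat, h2_se = h2_se,
                 loglik = ll, loglik_null = ll0, lrt = lrt, p = p,
                 ids = names(dat$y)),
            class = "greml")
}

## Profile log-likelihood at heritability ratio h: V = s * (h d + 1 - h),
## with the scale s maximized in closed form. With a design matrix X the
## REML adjustment (GLS projection, n - p denominator, log det X'WX term)
## is applied.
profile_ll <- function(h, d, ys, X = NULL) {
  v <- h * d + (1 - h)
  if (any(v <= 0)) return(list(ll = -Inf, scale = NA))
  n <- length(ys)
  w <- 1 / v
  if (is.null(X)) {
    s <- sum(w * ys^2) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s) + sum(log(v)) + n)
  } else {
    p <- ncol(X)
    XtWX <- crossprod(X, w * X)
    b <- solve(XtWX, crossprod(X, w * ys))
    r <- ys - X %*% b
    s <- sum(w * r^2) / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  list(ll = as.numeric(ll), scale = s)
}

profile_fixed <- function(sg, se, d, ys, X = NULL) {
  v <- sg * d + se
  if (any(v <= 0)) return(-Inf)
  n <- length(ys)
  w <- 1 / v
  if (is.null(X))
    return(-0.5 * (n * log(2 * pi) + sum(log(v)) + sum(w * ys^2)))
  XtWX <- crossprod(X, w * X)
  b <- solve(XtWX, crossprod(X, w * ys))
  r <- ys - X %*% b
  -0.5 * ((n - ncol(X)) * log(2 * pi) + sum(log(v)) + sum(w * r^2) +
            determinant(XtWX, logarithm = TRUE)$modulus)
}

num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
    xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
    xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
    xmm <- x; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
  }
  H
}

greml_biv <- function(y1, y2, grm) {
  d1 <- greml_align(y1, grm)
  d2 <- greml_align(y2, grm)
  ids <- intersect(names(d1$y), names(d2$y))
  if (length(ids) < 100)
    warning("fewer than 100 individuals complete for both traits")
  grm <- grm_eigen(grm_subset(grm, ids))
  n <- length(ids)
  d <- grm$eigen$values
  U <- grm$eigen$vectors
  Y <- crossprod(U, cbind(d1$y[ids], d2$y[ids]))
  u1 <- greml_uni(d1$y[ids], grm)
  u2 <- greml_uni(d2$y[ids], grm)
  cov12 <- mean(d1$y[ids] * d2$y[ids]) -
    mean(d1$y[ids]) * mean(d2$y[ids])
  th0 <- c(u1$components[1], 0.5 * cov12 *
             sqrt(max(u1$h2 * u2$h2, 1e-4)),
           u2$components[1], u1$components[2],
           cov12 * (1 - 0.5 * sqrt(max(u1$h2 * u2$h2, 1e-4))),
           u2$components[2])
  nll <- function(th) -biv_ll(th, d, Y)
  opt <- stats::optim(th0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  th <- opt$par
  H <- num_hessian(function(t) -nll(t), th)
  vc <- solve_vcov(-H)$vcov
  names(th) <- c("sigma2_g1", "sigma_g12", "sigma2_g2",
                 "sigma2_e1", "sigma_e12", "sigma2_e2")
  dimnames(vc) <- list(names(th), names(th))
  boundary <- th[1] < 1e-6 || th[3] < 1e-6
  if (boundary) {
    rg <- NA_real_; rg_se <- NA_real_
  } else {
    rg <- th[2] / sqrt(th[1] * th[3])
    g <- c(-0.5 * rg / th[1], 1 / sqrt(th[1] * th[3]), -0.5 * rg / th[3],
           0, 0, 0)
    rg_se <- sqrt(max(drop(t(g) %*% vc %*% g), 0))
  }
  h2 <- c(th[1] / (th[1] + th[4]), th[3] / (th[3] + th[6]))
  structure(list(type = "bivariate", n_ind = n, components = th,
                 vcov = vc, h2 = h2, rg = as.numeric(rg),
                 rg_se = as.numeric(rg_se),
                 rg_boundary = boundary,
                 loglik = -opt$value, ids = ids),
            class = "greml")
}

## Bivariate Gaussian log-likelihood in the eigenbasis; the 2 x 2 blocks
## V_i = d_i Sigma_g + Sigma_e are inverted in closed form, vectorized.
biv_ll <- function(th, d, Y) {
  v11 <- th[1] * d + th[4]
  v12 <- th[2] * d + th[5]
  v22 <- th[3] * d + th[6]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(-Inf)
  q <- (v22 * Y[, 1]^2 - 2 * v12 * Y[, 1] * Y[, 2] + v11 * Y[, 2]^2) / det
  -length(d) * log(2 * pi) - 0.5 * sum(log(det)) - 0.5 * sum(q)
}

#' @export
print.greml <- function(x, ...) {
  if (x$type == "univariate") {
    cat(sprintf("GREML univariate fit (n = %d)\n", x$n_ind))
    cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f\n",
                x$components[1], x$components[2]))
    cat(sprintf("  h2_SNP = %.4f (SE %.4f), LRT = %.3f, p = %.3g\n",
                x$h2, x$h2_se, x$lrt, x$p))
  } else {
    cat(sprintf("GREML bivariate fit (n = %d)\n", x$n_ind))
    print(round(x$components, 4))
    if (x$rg_boundary)
      cat("  r_g undefined: genetic variance at the zero boundary\n")
    else
      cat(sprintf("  r_g = %.4f (SE %.4f)\n", x$rg, x$rg_se))
  }
  invisible(x)
}

#' @export
logLik.greml <- function(object, ...) {
  structure(object$loglik,
            df = if (object$type == "univariate") 2 else 6,
            nobs = object$n_ind, class = "logLik")
}

#' Power of a univariate GREML heritability test
#'
#' Closed-form power approximation: the sampling SE of the heritability
#' estimate in unrelated samples is \eqn{\sqrt{2 / (n^2 v)}}, with `v` the
#' variance of the GRM off-diagonal entries (about `2e-5` for genome-wide
#' common-variant GRMs in unrelated Europeans); the test statistic is then
#' non-central chi-square with one degree of freedom and non-centrality
#' \eqn{(h^2 / SE)^2}.
#'
#' @param n sample size (>= 2).
#' @param h2 true SNP heritability in `[0, 1]`.
#' @param var_offdiag variance of GRM off-diagonal entries (> 0).
#' @param alpha type-I error level in (0, 1).
#' @return the power, a number in `[alpha, 1]`.
#' @export
power_greml <- function(n, h2, var_offdiag = 2e-5, alpha = 0.05) {
  stopifnot(n >= 2, h2 >= 0, h2 <= 1, var_offdiag > 0,
            alpha > 0, alpha < 1)
  se <- sqrt(2 / (n^2 * var_offdiag))
  ncp <- (h2 / se)^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
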
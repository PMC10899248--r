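#' Fit a GRM-SEM model by maximum likelihood
#'
#' Estimates the free loadings of a [gcsem_model()] by quasi-Newton (BFGS)
#' maximization of the rotated Gaussian log-likelihood, using analytic
#' gradients. Phenotypes must be Z-standardized (see [prepare_phenotypes()]);
#' individuals with a missing value on any modelled trait are dropped.
#' Standard errors come from the inverse observed information (a central
#' finite difference of the analytic gradient at the optimum); Wald z tests
#' are reported per free parameter on the unstandardised scale.
#'
#' After convergence every factor column whose non-zero cells are all free is
#' sign-canonicalized so its first non-zero loading is positive; the
#' likelihood is invariant under these flips.
#'
#' @param pheno numeric matrix (individuals x traits), row names = IDs.
#' @param grm a [as_grm()] object.
#' @param model a [gcsem_model()]; defaults to a saturated Cholesky model
#'   for `ncol(pheno)` traits.
#' @param start optional starting vector for the free parameters.
#' @param control list: `maxit` (default 2000), `reltol` (default 1e-12),
#'   `restarts` (extra BFGS polishing passes, default 2).
#' @return object of class `gcsem`: estimates `theta`, `vcov`, `loglik`,
#'   implied `SigmaA`/`SigmaE`/`SigmaV`, Wald table, sample size and
#'   convergence information. Methods: [print.gcsem()], [summary.gcsem()],
#'   `coef`, `logLik`, `vcov`, `plot`.
#' @export
gcsem <- function(pheno, grm, model = NULL, start = NULL,
                  control = list()) {
  if (is.null(model))
    model <- gcsem_model("cholesky", k = ncol(as.matrix(pheno)),
                         traits = colnames(pheno))
  stopifnot(inherits(model, "gcsem_model"), inherits(grm, "grm"))
  ctl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12, restarts = 2),
                           control)
  dat <- align_data(model, grm, pheno)
  if (dat$n < 100)
    warning("fewer than 100 individuals; estimates will be unstable")
  k <- model$k
  n <- dat$n
  if (is.null(start)) start <- start_values(model, dat$Y)
  if (length(start) != model$n_par)
    stop("start vector has wrong length")

  negll <- function(th) {
    L <- theta_fill(model, th)
    parts <- lik_parts(L$LA, L$LE, dat$d, dat$Ystar)
    if (is.null(parts)) return(Inf)
    -lik_value(parts, n, k)
  }
  neggr <- function(th) {
    L <- theta_fill(model, th)
    parts <- lik_parts(L$LA, L$LE, dat$d, dat$Ystar)
    if (is.null(parts)) return(rep(0, length(th)))
    g <- lik_grad(parts, dat$d, L$LA, L$LE)
    -grad_pack(model, g$GA, g$GE)
  }

  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  for (i in seq_len(ctl$restarts)) {
    opt2 <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                         control = list(maxit = ctl$maxit,
                                        reltol = ctl$reltol))
    if (opt2$value > opt$value - 1e-10 &&
        max(abs(opt2$par - opt$par)) < 1e-8) {
      opt <- opt2
      break
    }
    opt <- opt2
  }
  gnorm <- sqrt(sum(neggr(opt$par)^2))
  converged <- is.finite(opt$value) && gnorm < 1e-3 * max(1, n / 100)
  if (!is.finite(opt$value))
    stop("GRM-SEM optimization failed: non-finite objective at optimum")

  theta <- canonicalize_signs(model, opt$par)
  H <- grad_hessian(neggr, theta)        # Hessian of the NEGATIVE loglik
  vc <- solve_vcov(H)
  L <- theta_fill(model, theta)
  SigmaA <- tcrossprod(L$LA)
  SigmaE <- tcrossprod(L$LE)
  labels <- theta_labels(model)
  se <- sqrt(pmax(diag(vc$vcov), 0))
  z <- ifelse(se > 0, theta / se, NA_real_)
  wald <- data.frame(parameter = labels, estimate = theta, se = se,
                     z = z, p = 2 * stats::pnorm(-abs(z)),
                     row.names = NULL)
  structure(list(model = model, theta = stats::setNames(theta, labels),
                 vcov = vc$vcov, vcov_flag = vc$flag,
                 loglik = -opt$value, n_par = model$n_par, n_ind = n,
                 LA = L$LA, LE = L$LE,
                 SigmaA = SigmaA, SigmaE = SigmaE,
                 SigmaV = SigmaA + SigmaE,
                 pheno_cov = crossprod(dat$Y) / n,
                 wald = wald, converged = converged,
                 gradient_norm = gnorm,
                 optim = list(counts = opt$counts,
                              convergence = opt$convergence),
                 ids = dat$grm$ids$IID),
            class = "gcsem")
}

## Starting values: Cholesky factors of half the phenotypic covariance for
## saturated parts; modest shared loadings plus variance-splitting specific
## loadings for structured parts. EFA-derived starts in model$start win.
start_values <- function(model, Y) {
  k <- model$k
  n <- nrow(Y)
  S <- crossprod(Y) / n
  half <- t(chol(S / 2 + diag(1e-6, k)))
  part_start <- function(pat, given) {
    st <- matrix(0, nrow(pat), ncol(pat))
    if (ncol(pat) == k && all(is.na(diag(pat))) &&
        !any(is.na(pat[upper.tri(pat)]))) {
      st[] <- half                        # saturated lower-triangular part
    } else {
      nsh <- ncol(pat) - k                # shared (and general) columns
      shared_free <- is.na(pat[, seq_len(nsh), drop = FALSE])
      st[, seq_len(nsh)][shared_free] <- 0.25
      spec <- sqrt(pmax(diag(S) / 2 - rowSums(shared_free) * 0.25^2, 0.04))
      st[cbind(seq_len(k), nsh + seq_len(k))] <- spec
    }
    if (!is.null(given)) {
      ok <- !is.na(given)
      st[ok] <- given[ok]
    }
    st[is.na(pat)]
  }
  c(part_start(model$genetic, model$start$genetic),
    part_start(model$residual, model$start$residual))
}

## Flip factor-column signs so the first non-zero loading of each column is
## positive; only columns whose non-zero cells are all free are flipped.
canonicalize_signs <- function(model, theta) {
  L <- theta_fill(model, theta)
  for (part in c("genetic", "residual")) {
    pat <- model[[part]]
    lam <- if (part == "genetic") L$LA else L$LE
    for (j in seq_len(ncol(pat))) {
      nz <- which(abs(lam[, j]) > 1e-8)
      if (!length(nz)) next
      if (any(!is.na(pat[nz, j]))) next   # fixed non-zero cells: leave alone
      if (lam[nz[1], j] < 0) lam[, j] <- -lam[, j]
    }
    if (part == "genetic") L$LA <- lam else L$LE <- lam
  }
  c(L$LA[is.na(model$genetic)], L$LE[is.na(model$residual)])
}

## Central-difference Hessian from a gradient function.
grad_hessian <- function(gr, theta, h = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  (H + t(H)) / 2
}

solve_vcov <- function(H) {
  vc <- tryCatch(solve(H), error = function(e) NULL)
  flag <- NULL
  if (is.null(vc) || any(diag(vc) < 0)) {
    e <- eigen(H, symmetric = TRUE)
    vals <- pmax(e$values, max(abs(e$values)) * 1e-10)
    vc <- e$vectors %*% (t(e$vectors) / vals)
    flag <- "observed information not positive definite; pseudo-inverse used"
  }
  list(vcov = (vc + t(vc)) / 2, flag = flag)
}

#' @export
print.gcsem <- function(x, ...) {
  cat(sprintf("GRM-SEM fit: family '%s', %d traits, %d individuals\n",
              x$model$family, x$model$k, x$n_ind))
  cat(sprintf("  log-likelihood %.3f, %d free parameters (AIC %.2f, BIC %.2f)\n",
              x$loglik, x$n_par, stats::AIC(x), stats::BIC(x)))
  if (!x$converged) cat("  WARNING: convergence not reached\n")
  if (!is.null(x$vcov_flag)) cat("  NOTE:", x$vcov_flag, "\n")
  invisible(x)
}

#' @export
coef.gcsem <- function(object, ...) object$theta

#' @export
logLik.gcsem <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_ind,
            class = "logLik")
}

#' @export
vcov.gcsem <- function(object, ...) object$vcov

#' Summarize a GRM-SEM fit
#'
#' Returns the standardized solution ([standardize_solution()]) together
#' with the Wald table of unstandardised estimates.
#'
#' @param object a [gcsem()] fit.
#' @param ... unused.
#' @export
summary.gcsem <- function(object, ...) {
  out <- list(fit = object, std = standardize_solution(object))
  class(out) <- "summary.gcsem"
  out
}

#' @export
print.summary.gcsem <- function(x, ...) {
  print(x$fit)
  cat("\nUnstandardised estimates (Wald tests):\n")
  print(x$fit$wald, digits = 3, row.names = FALSE)
  cat("\n")
  print(x$std)
  invisible(x)
}

#' @export
plot.gcsem <- function(x, ...) {
  std <- standardize_solution(x)
  h2 <- std$h2$h2
  lam <- std$lambda_genetic
  shared <- seq_len(ncol(lam) - x$model$k)
  contrib <- if (length(shared)) lam[, shared, drop = FALSE]^2 else
    matrix(0, x$model$k, 0)
  spec <- h2 - rowSums(contrib)
  m <- t(cbind(contrib, specific = pmax(spec, 0)))
  graphics::barplot(m, names.arg = x$model$traits, las = 2,
                    ylab = expression(h[SNP]^2),
                    legend.text = rownames(m), ...)
  invisible(x)
}
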
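#' Predict the number of shared genetic factors from a correlation matrix
#'
#' Spectral decomposition of a (genetic) correlation matrix with an
#' automatic scree rule: component i is retained iff its eigenvalue exceeds
#' 1 (Kaiser) AND exceeds the optimal-coordinate prediction — the value
#' extrapolated at position i by the straight line through eigenvalues
#' (i + 1) and k. Counting stops at the first failure, and the last two
#' positions (where no extrapolation line exists) are never retained.
#'
#' @param rg_matrix symmetric correlation matrix with unit diagonal
#'   (typically Cholesky-model-derived genetic trait correlations).
#' @return object of class `genetic_pca`: `eigenvalues` (non-increasing),
#'   `n_factors`, and the optimal-coordinate predictions `oc_pred` (for the
#'   scree plot). `n_factors = 0` signals no shared structure.
#' @export
genetic_pca <- function(rg_matrix) {
  C <- as.matrix(rg_matrix)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("input must be a symmetric correlation matrix")
  if (max(abs(diag(C) - 1)) > 1e-6)
    stop("input must have unit diagonal")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sc <- n_factors_scree(ev)
  structure(list(eigenvalues = ev, n_factors = sc$n_factors,
                 oc_pred = sc$oc_pred),
            class = "genetic_pca")
}

#' Joint Kaiser / optimal-coordinate factor-count rule
#'
#' Applies the automatic scree rule of [genetic_pca()] to a non-increasing
#' eigenvalue series: position i is retained iff its eigenvalue exceeds 1
#' and exceeds the straight-line extrapolation through eigenvalues (i + 1)
#' and k; counting stops at the first failure.
#'
#' @param eigenvalues numeric vector, sorted non-increasing.
#' @return list with `n_factors` and the per-position optimal-coordinate
#'   predictions `oc_pred` (`NA` for the last two positions).
#' @export
n_factors_scree <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (is.unsorted(rev(ev), strictly = FALSE))
    stop("eigenvalues must be sorted in non-increasing order")
  k <- length(ev)
  oc <- rep(NA_real_, k)
  for (i in seq_len(max(k - 2, 0))) {
    slope <- (ev[k] - ev[i + 1]) / (k - (i + 1))
    oc[i] <- ev[i + 1] + slope * (i - (i + 1))
  }
  nf <- 0
  for (i in seq_len(max(k - 2, 0))) {
    if (ev[i] > 1 && ev[i] > oc[i]) nf <- nf + 1 else break
  }
  list(n_factors = nf, oc_pred = oc)
}

#' @export
print.genetic_pca <- function(x, ...) {
  cat("Genetic PCA:", x$n_factors, "shared factor(s) predicted\n")
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
                              collapse = " "), "\n")
  if (x$n_factors == 0)
    cat("  no shared structure detected (no eigenvalue passes both rules)\n")
  invisible(x)
}

#' @export
plot.genetic_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  graphics::plot(seq_len(k), x$eigenvalues, type = "b",
                 xlab = "component", ylab = "eigenvalue", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::lines(seq_len(k), x$oc_pred, lty = 2, col = "grey40")
  invisible(x)
}

#' Weighted least-squares exploratory factor analysis of a genetic
#' covariance matrix
#'
#' Fits the common-factor model \eqn{\Sigma(\theta) = \Lambda\Lambda^T +
#' \mathrm{diag}(\psi)} to a model-predicted genetic covariance matrix by
#' minimizing the diagonally weighted least-squares discrepancy over the
#' unique elements,
#' \deqn{F(\theta) = \tfrac12 \sum_l w_l^{-1} (s_l - \sigma_l(\theta))^2,}
#' with weights \eqn{w_l} the element-wise sampling variances of the input
#' matrix (identity weights give ULS). Because the input is itself an
#' estimate, negative uniquenesses (Heywood cases) are flagged rather than
#' forbidden. The unrotated solution is identified by an echelon pattern
#' (upper-triangular zeros) and then rotated on request.
#'
#' @param VA symmetric genetic covariance matrix (k x k).
#' @param VA_var optional matrix of element-wise sampling variances of `VA`
#'   (see [va_sampling_variance()]); `NULL` gives unweighted (ULS)
#'   estimation.
#' @param n_factors number of factors (>= 1).
#' @param rotation `"varimax"`, `"oblimin"` or `"none"`.
#' @return object of class `genetic_efa`: `loadings` (k x n_factors),
#'   `uniquenesses`, `interfactor_corr`, `rotation`, `discrepancy`,
#'   `heywood`, `weights_used`.
#' @export
efa_genetic <- function(VA, VA_var = NULL, n_factors,
                        rotation = c("varimax", "oblimin", "none")) {
  rotation <- match.arg(rotation)
  S <- as.matrix(VA)
  k <- nrow(S)
  if (max(abs(S - t(S))) > 1e-8) stop("VA must be symmetric")
  q <- n_factors
  if (q < 1) stop("n_factors must be >= 1")
  df <- k * (k + 1) / 2 - (k * q - q * (q - 1) / 2 + k)
  if (df < 0)
    stop("too many factors for ", k, " traits (negative degrees of freedom)")
  lt <- lower.tri(S, diag = TRUE)
  s <- S[lt]
  w <- if (is.null(VA_var)) rep(1, sum(lt)) else {
    W <- as.matrix(VA_var)
    if (any(W[lt] <= 0)) stop("VA_var must be positive where used")
    W[lt]
  }
  free_lam <- matrix(TRUE, k, q)
  free_lam[upper.tri(free_lam)] <- FALSE  # echelon identification
  nlam <- sum(free_lam)
  obj <- function(th) {
    L <- matrix(0, k, q)
    L[free_lam] <- th[seq_len(nlam)]
    psi <- th[nlam + seq_len(k)]
    Sig <- tcrossprod(L) + diag(psi, k)
    0.5 * sum((s - Sig[lt])^2 / w)
  }
  e <- eigen(S, symmetric = TRUE)
  L0 <- e$vectors[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(q)], 1e-4)), q)
  L0[upper.tri(L0)] <- 0
  psi0 <- pmax(diag(S) - rowSums(L0^2), 0.05 * pmax(diag(S), 0.01))
  th0 <- c(L0[free_lam], psi0)
  opt <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  L <- matrix(0, k, q)
  L[free_lam] <- opt$par[seq_len(nlam)]
  psi <- opt$par[nlam + seq_len(k)]
  Phi <- diag(q)
  if (q > 1 && rotation == "varimax") {
    L <- stats::varimax(L)$loadings[, , drop = FALSE]
    L <- align_factors(L)$loadings
  } else if (q > 1 && rotation == "oblimin") {
    rot <- rotate_oblimin(L)
    al <- align_factors(rot$loadings, rot$Phi)
    L <- al$loadings
    Phi <- al$Phi
  } else {
    L <- align_factors(L)$loadings
  }
  dimnames(L) <- list(rownames(S) %||% paste0("trait", seq_len(k)),
                      paste0("F", seq_len(q)))
  structure(list(loadings = L, uniquenesses = psi,
                 interfactor_corr = Phi, rotation = rotation,
                 n_factors = q, discrepancy = opt$value,
                 weights_used = if (is.null(VA_var)) NULL else w,
                 heywood = any(psi < 0)),
            class = "genetic_efa")
}

#' @export
print.genetic_efa <- function(x, ...) {
  cat(sprintf("Genetic EFA: %d factor(s), %s rotation, discrepancy %.3g\n",
              x$n_factors, x$rotation, x$discrepancy))
  print(round(x$loadings, 3))
  if (x$n_factors > 1 && x$rotation == "oblimin") {
    cat("Inter-factor correlations:\n")
    print(round(x$interfactor_corr, 3))
  }
  if (x$heywood) cat("NOTE: negative uniqueness (Heywood case)\n")
  invisible(x)
}

#' Element-wise sampling variances of the implied genetic covariance
#'
#' Delta-method variances of each entry of the model-implied genetic
#' covariance matrix \eqn{\Sigma_A(\theta)} of a fitted model, used as the
#' diagonal weight matrix of the DWLS genetic EFA.
#'
#' @param fit a [gcsem()] fit.
#' @return k x k matrix of sampling variances.
#' @export
va_sampling_variance <- function(fit) {
  stopifnot(inherits(fit, "gcsem"))
  model <- fit$model
  f <- function(th) {
    L <- theta_fill(model, th)
    as.numeric(tcrossprod(L$LA))
  }
  J <- num_jacobian(f, as.numeric(fit$theta))
  v <- rowSums((J %*% fit$vcov) * J)
  matrix(pmax(v, 1e-12), model$k, model$k,
         dimnames = list(model$traits, model$traits))
}

#' Choose between varimax and oblimin EFA solutions
#'
#' The orthogonal (varimax) solution is preferred when the oblique solution
#' offers nothing beyond it: either every inter-factor correlation of the
#' oblimin solution is modest (|r| <= `r_cut`, default 0.32, i.e. under 10%
#' shared variance between factors) or the two solutions have the same
#' zero/non-zero loading pattern at threshold `pattern_cut`.
#'
#' @param oblimin_sol,varimax_sol [efa_genetic()] solutions on the same
#'   matrix with the same factor count.
#' @param r_cut inter-factor correlation threshold.
#' @param pattern_cut loading threshold for pattern comparison.
#' @return the chosen solution, with attribute `"decision"` describing the
#'   applied rule.
#' @export
choose_rotation <- function(oblimin_sol, varimax_sol, r_cut = 0.32,
                            pattern_cut = 0.10) {
  stopifnot(inherits(oblimin_sol, "genetic_efa"),
            inherits(varimax_sol, "genetic_efa"),
            oblimin_sol$n_factors == varimax_sol$n_factors,
            nrow(oblimin_sol$loadings) == nrow(varimax_sol$loadings))
  Phi <- oblimin_sol$interfactor_corr
  max_r <- max(abs(Phi[upper.tri(Phi)]), 0)
  same_pattern <- identical(abs(oblimin_sol$loadings) >= pattern_cut,
                            abs(varimax_sol$loadings) >= pattern_cut)
  if (max_r <= r_cut) {
    out <- varimax_sol
    attr(out, "decision") <- sprintf(
      "varimax: max inter-factor |r| = %.3f <= %.2f", max_r, r_cut)
  } else if (same_pattern) {
    out <- varimax_sol
    attr(out, "decision") <- sprintf(
      "varimax: oblimin pattern identical at threshold %.2f despite |r| = %.3f",
      pattern_cut, max_r)
  } else {
    out <- oblimin_sol
    attr(out, "decision") <- sprintf(
      "oblimin: max inter-factor |r| = %.3f > %.2f and patterns differ",
      max_r, r_cut)
  }
  out
}

#' Build a constrained IPC model from a genetic EFA solution
#'
#' Translates an EFA factor pattern into a hybrid independent-pathway /
#' Cholesky (IPC) model specification: shared genetic cells with EFA
#' loadings below `zero_threshold` in absolute value are fixed to zero, the
#' remaining shared cells are freed with the EFA loadings as starting
#' values; one free specific genetic loading per trait and a saturated
#' residual Cholesky complete the model. A factor whose loadings are all
#' constrained is dropped with a warning.
#'
#' @param efa an [efa_genetic()] solution.
#' @param zero_threshold absolute-loading threshold below which shared cells
#'   are constrained to zero (default 0.10).
#' @return a [gcsem_model()] of family `"ipc"`.
#' @export
build_ipc_from_efa <- function(efa, zero_threshold = 0.10) {
  stopifnot(inherits(efa, "genetic_efa"))
  L <- efa$loadings
  k <- nrow(L)
  keep <- colSums(abs(L) >= zero_threshold) > 0
  if (!all(keep)) {
    warning("factor(s) with all loadings constrained dropped: ",
            paste(which(!keep), collapse = ", "))
    L <- L[, keep, drop = FALSE]
  }
  q <- ncol(L)
  if (q == 0) stop("no factor survives the zero-loading rule")
  cons <- which(abs(L) < zero_threshold, arr.ind = TRUE)
  constraints <- if (nrow(cons)) data.frame(part = "genetic",
                                            row = cons[, 1],
                                            col = cons[, 2], value = 0)
  else NULL
  stg <- matrix(NA_real_, k, q + k)
  free_sh <- abs(L) >= zero_threshold
  stg[, seq_len(q)][free_sh] <- L[free_sh]
  gcsem_model("ipc", k = k, n_shared = q, constraints = constraints,
              start = list(genetic = stg),
              traits = rownames(L))
}

#' Trim near-zero specific genetic loadings and refit
#'
#' Post-fit trimming pass for IPC-type models: specific genetic loadings
#' whose fitted standardized magnitude falls below `threshold` (default
#' 0.01) are fixed to zero and the model refitted. Returns the refitted
#' model, or the input fit unchanged when nothing is trimmed.
#'
#' @param fit a [gcsem()] fit of an `ipc`/`bifactor` model.
#' @param pheno,grm the data the fit used.
#' @param threshold standardized-loading magnitude below which a specific
#'   loading is removed.
#' @return a [gcsem()] fit (attribute `"trimmed"` lists removed cells).
#' @export
gcsem_trim <- function(fit, pheno, grm, threshold = 0.01) {
  stopifnot(inherits(fit, "gcsem"))
  model <- fit$model
  k <- model$k
  nsh <- ncol(model$genetic) - k
  std <- standardize_solution(fit)
  spec_cols <- nsh + seq_len(k)
  lam <- std$lambda_genetic[, spec_cols, drop = FALSE]
  small <- which(abs(diag(lam)) < threshold &
                   is.na(diag(model$genetic[, spec_cols, drop = FALSE])))
  if (!length(small)) return(fit)
  constraints <- data.frame(part = "genetic", row = small,
                            col = nsh + small, value = 0)
  model2 <- apply_constraints(model, constraints)
  model2$n_par <- n_par(model2)
  refit <- gcsem(pheno, grm, model2)
  attr(refit, "trimmed") <- sprintf("A[%d,%d]", small, nsh + small)
  refit
}

#' Compare GRM-SEM model fits
#'
#' Information criteria and nested likelihood-ratio tests for a set of fits
#' of the same traits on the same individuals:
#' `AIC = -2 loglik + 2 N_par`, `BIC = -2 loglik + N_par log(n_ind)`,
#' LRT \eqn{\Delta\chi^2 = 2(\ell_{general} - \ell_{restricted})} on
#' `N_par` difference degrees of freedom. The best model is the lowest AIC,
#' BIC breaking ties.
#'
#' @param fits named list of [gcsem()] fits.
#' @param nesting optional data frame with columns `general`, `restricted`
#'   naming nested pairs to test; defaults to testing every other model
#'   against the first (assumed saturated) fit.
#' @return object of class `gcsem_comparison`: `table` (model, loglik,
#'   n_par, AIC, BIC, SRMR), `lrt` and `best`.
#' @export
compare_models <- function(fits, nesting = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("'fits' must be a named list")
  n_ind <- vapply(fits, function(f) f$n_ind, numeric(1))
  if (length(unique(n_ind)) != 1)
    stop("fits were not computed on the same individuals")
  ks <- vapply(fits, function(f) f$model$k, numeric(1))
  if (length(unique(ks)) != 1) stop("fits model different trait sets")
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n_par = vapply(fits, function(f) f$n_par, numeric(1)),
    row.names = NULL)
  tab$AIC <- -2 * tab$loglik + 2 * tab$n_par
  tab$BIC <- -2 * tab$loglik + tab$n_par * log(n_ind[1])
  tab$SRMR <- vapply(fits, function(f) srmr(f), numeric(1))
  if (is.null(nesting) && length(fits) > 1)
    nesting <- data.frame(general = names(fits)[1],
                          restricted = names(fits)[-1])
  lrt <- NULL
  if (!is.null(nesting) && nrow(nesting)) {
    lrt <- do.call(rbind, lapply(seq_len(nrow(nesting)), function(i) {
      g <- fits[[nesting$general[i]]]
      r <- fits[[nesting$restricted[i]]]
      ddf <- g$n_par - r$n_par
      if (ddf <= 0)
        stop("LRT pair not nested: ", nesting$general[i], " vs ",
             nesting$restricted[i])
      chi2 <- max(2 * (g$loglik - r$loglik), 0)
      data.frame(general = nesting$general[i],
                 restricted = nesting$restricted[i],
                 chi2 = chi2, df = ddf,
                 p = stats::pchisq(chi2, ddf, lower.tail = FALSE))
    }))
  }
  ord <- order(tab$AIC, tab$BIC)
  structure(list(table = tab, lrt = lrt, best = tab$model[ord[1]]),
            class = "gcsem_comparison")
}

#' @export
print.gcsem_comparison <- function(x, ...) {
  cat("Model comparison (best by AIC:", x$best, ")\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("\nLikelihood ratio tests:\n")
    lt <- x$lrt
    lt$chi2 <- round(lt$chi2, 3)
    lt$p <- signif(lt$p, 3)
    print(lt, row.names = FALSE)
  }
  invisible(x)
}

#' Standardized root mean square residual
#'
#' Absolute model fit: the root of the mean squared difference between the
#' observed and model-implied correlations over the `k (k + 1) / 2` unique
#' elements. Values below 0.08 conventionally indicate good fit.
#'
#' @param fit a [gcsem()] fit.
#' @param observed observed phenotypic covariance of the modelled sample;
#'   defaults to the covariance stored on the fit.
#' @return the SRMR value.
#' @export
srmr <- function(fit, observed = NULL) {
  stopifnot(inherits(fit, "gcsem"))
  S <- observed %||% fit$pheno_cov
  S <- as.matrix(S)
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("observed covariance matrix is not positive definite")
  if (nrow(S) != fit$model$k) stop("dimension mismatch")
  Robs <- stats::cov2cor(S)
  Rimp <- stats::cov2cor(fit$SigmaV)
  lt <- lower.tri(Robs, diag = TRUE)
  sqrt(mean((Robs[lt] - Rimp[lt])^2))
}

#' Effective number of independent tests by spectral decomposition
#'
#' Estimates the effective number of independent measures underlying a set
#' of correlated phenotypes from the eigenvalue dispersion of their
#' correlation matrix,
#' \deqn{M_{eff} = 1 + (M - 1) (1 - \mathrm{Var}(\lambda) / M),}
#' and the corresponding experiment-wide significance threshold
#' `alpha / Meff`.
#'
#' @param cor_matrix phenotypic correlation matrix.
#' @param alpha family-wise error level.
#' @return list with `meff`, `threshold` and the `eigenvalues`.
#' @export
meff_spectral <- function(cor_matrix, alpha = 0.05) {
  C <- as.matrix(cor_matrix)
  if (max(abs(C - t(C))) > 1e-8) stop("correlation matrix must be symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  M <- length(ev)
  meff <- 1 + (M - 1) * (1 - stats::var(ev) / M)
  list(meff = meff, threshold = alpha / meff, eigenvalues = ev)
}
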
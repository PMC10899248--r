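## GRM-SEM Gaussian likelihood in the GRM eigenbasis.
##
## With G = U diag(d) U', the nk x nk covariance
##   Sigma_A (x) G + Sigma_E (x) I
## block-diagonalizes after rotating each trait vector by U': rotated
## individual i contributes a k-variate Gaussian with covariance
##   V_i = d_i Sigma_A + Sigma_E.
## A second simultaneous diagonalization (Sigma_E = L L', eigen of
## L^-1 Sigma_A L^-T = Q Phi Q') reduces every V_i to a diagonal matrix,
## so the whole likelihood and its gradient are O(n k^2) after one k x k
## eigendecomposition per evaluation.

## Build the per-evaluation structure shared by loglik and gradient.
## Returns NULL when Sigma_E is not positive definite.
lik_parts <- function(LA, LE, d, Ystar) {
  SigmaA <- tcrossprod(LA)
  SigmaE <- tcrossprod(LE)
  R <- tryCatch(chol(SigmaE), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  # B = L^-1 Sigma_A L^-T with L = t(R)
  M1 <- forwardsolve(t(R), SigmaA)
  B <- t(forwardsolve(t(R), t(M1)))
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  phi <- pmax(eB$values, 0)
  K <- backsolve(R, eB$vectors)          # K = L^-T Q
  TT <- Ystar %*% K                      # row i = t_i' = y_i' L^-T Q
  D <- outer(d, phi) + 1                 # n x k, entries d_i phi_j + 1
  if (any(D <= 0)) return(NULL)
  list(SigmaA = SigmaA, SigmaE = SigmaE, R = R, phi = phi, K = K,
       TT = TT, D = D)
}

lik_value <- function(parts, n, k) {
  logdetE <- 2 * sum(log(diag(parts$R)))
  -0.5 * n * k * log(2 * pi) - 0.5 * n * logdetE -
    0.5 * sum(log(parts$D)) - 0.5 * sum(parts$TT^2 / parts$D)
}

## Gradient of the log-likelihood with respect to the free cells of
## Lambda_A, Lambda_E. Uses dl/dSigma = -1/2 (sum_i w_i V_i^-1 -
## sum_i w_i V_i^-1 y_i y_i' V_i^-1) with w_i = d_i (genetic) or 1
## (residual), then dl/dLambda = 2 * (dl/dSigma) Lambda.
lik_grad <- function(parts, d, LA, LE) {
  U <- parts$TT / parts$D                # row i = u_i' = (D_i^-1 t_i)'
  a <- colSums(d / parts$D)
  e <- colSums(1 / parts$D)
  CA <- crossprod(U, d * U)
  CE <- crossprod(U)
  K <- parts$K
  MA <- -0.5 * K %*% (diag(a, length(a)) - CA) %*% t(K)
  ME <- -0.5 * K %*% (diag(e, length(e)) - CE) %*% t(K)
  list(GA = 2 * MA %*% LA, GE = 2 * ME %*% LE)
}

#' Evaluate the GRM-SEM log-likelihood
#'
#' Computes the n*k-dimensional Gaussian log-density of the (Z-standardized,
#' mean-zero) trait matrix under the model-implied covariance
#' \eqn{\Sigma_A \otimes G + \Sigma_E \otimes I}, by rotating the phenotypes
#' into the GRM eigenbasis (see source comments). The value is exactly the
#' dense Kronecker-product Gaussian log-density; the rotation only changes
#' the cost, not the result. Individuals with a missing value on any
#' modelled trait are dropped (complete-case policy).
#'
#' @param model a [gcsem_model()].
#' @param theta free-parameter vector (free cells of the genetic part,
#'   column-major, followed by the residual part).
#' @param grm a [as_grm()] object (eigendecomposition computed if absent).
#' @param pheno numeric matrix (individuals x k) with sample IDs as row
#'   names matching the GRM.
#' @return the log-likelihood; `-Inf` (with attribute `"reason"`) when the
#'   implied per-individual covariance is not positive definite.
#' @export
gcsem_loglik <- function(model, theta, grm, pheno) {
  dat <- align_data(model, grm, pheno)
  L <- theta_fill(model, theta)
  parts <- lik_parts(L$LA, L$LE, dat$d, dat$Ystar)
  if (is.null(parts))
    return(structure(-Inf, reason = "implied covariance not positive definite"))
  lik_value(parts, dat$n, model$k)
}

## Align phenotypes with the GRM, apply complete-case filtering, rotate.
align_data <- function(model, grm, pheno) {
  Y <- as.matrix(pheno)
  if (ncol(Y) != model$k)
    stop("phenotype matrix has ", ncol(Y), " traits; model expects ", model$k)
  ids <- rownames(Y)
  if (!is.null(ids) && !is.null(grm$ids)) {
    common <- intersect(grm$ids$IID, ids)
    if (length(common) < 2) stop("no overlapping IDs between GRM and phenotypes")
    if (length(common) < nrow(grm$values) || length(common) < nrow(Y)) {
      grm <- grm_subset(grm, common)
      Y <- Y[common, , drop = FALSE]
    } else {
      Y <- Y[grm$ids$IID, , drop = FALSE]
    }
  } else if (nrow(Y) != nrow(grm$values)) {
    stop("phenotype rows do not match GRM dimension and IDs are unavailable")
  }
  cc <- stats::complete.cases(Y)
  if (!all(cc)) {
    grm <- grm_subset(grm, grm$ids$IID[cc])
    Y <- Y[cc, , drop = FALSE]
  }
  grm <- grm_eigen(grm)
  Ustar <- grm$eigen$vectors
  list(n = nrow(Y), d = grm$eigen$values,
       Ystar = crossprod(Ustar, Y), Y = Y, grm = grm)
}
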
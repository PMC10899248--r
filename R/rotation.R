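## Factor rotation utilities.
##
## varimax comes from stats; the oblique quartimin rotation (oblimin with
## gamma = 0) is implemented with the standard gradient-projection algorithm
## (Jennrich 2002): minimize the quartimin criterion
##   Q(L) = sum_{j != l} sum_t L[t,j]^2 L[t,l]^2 / 4-ish scaling
## over oblique rotation matrices T (columns scaled so diag(T'T) = 1),
## with pattern matrix L = A (T')^-1 for the unrotated loadings A.

quartimin_criterion <- function(L) {
  L2 <- L^2
  N <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

#' Oblique quartimin (oblimin) rotation
#'
#' Gradient-projection rotation of an unrotated loading matrix to the
#' quartimin criterion, returning the oblique pattern matrix and the
#' inter-factor correlation matrix.
#'
#' @param A unrotated k x q loading matrix (q >= 2).
#' @param maxit,eps iteration cap and convergence tolerance on the
#'   projected gradient.
#' @return list with `loadings` (pattern matrix), `Phi` (factor
#'   correlations) and `converged`.
#' @export
rotate_oblimin <- function(A, maxit = 1000, eps = 1e-6) {
  q <- ncol(A)
  if (q < 2) return(list(loadings = A, Phi = diag(q), converged = TRUE))
  Tm <- diag(q)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- quartimin_criterion(L)
  G <- -t(crossprod(L, vg$Gq) %*% Ti)   # gradient wrt T
  converged <- FALSE
  for (it in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))   # project: columns tangent
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 0:20) {
      X <- Tm - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)))  # rescale columns
      Ti2 <- tryCatch(solve(X), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2 <- A %*% t(Ti2)
        vg2 <- quartimin_criterion(L2)
        if (vg2$f < vg$f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    Tm <- X; Ti <- Ti2; L <- L2; vg <- vg2
    G <- -t(crossprod(L, vg$Gq) %*% Ti)
  }
  Phi <- crossprod(Tm)
  list(loadings = L, Phi = Phi, converged = converged)
}

## Align factor order and signs of a rotated solution: order columns by
## decreasing sum of squared loadings, flip each so its largest-|.|
## loading is positive.
align_factors <- function(L, Phi = NULL) {
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  if (!is.null(Phi)) Phi <- Phi[ord, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      if (!is.null(Phi)) {
        Phi[j, ] <- -Phi[j, ]
        Phi[, j] <- -Phi[, j]
      }
    }
  }
  list(loadings = L, Phi = Phi)
}
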
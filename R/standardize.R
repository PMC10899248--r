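#' Standardized solution of a GRM-SEM fit
#'
#' Converts the unstandardised loadings to the unit-phenotypic-variance
#' scale and derives the derived quantities of interest, each with a
#' Delta-method standard error propagated from the parameter covariance:
#' \itemize{
#'   \item standardized loadings
#'     \eqn{\lambda_{tj} = \Lambda_{tj} / \sqrt{\Sigma_{V,tt}}};
#'   \item SNP heritability per trait,
#'     \eqn{h^2_{SNP,t} = \Sigma_{A,tt} / \Sigma_{V,tt}};
#'   \item genetic correlations
#'     \eqn{r_g = \sigma_{g12} / \sqrt{\sigma^2_{g1}\sigma^2_{g2}}};
#'   \item factorial co-heritabilities
#'     \eqn{f^2_g = \sigma^2_{g_{jt}} / \sigma^2_{g_t}}, the share of trait
#'     t's genetic variance carried by genetic factor j.
#' }
#' Gradients for the Delta method are computed by central finite differences
#' of the (smooth) transformation at the estimate.
#'
#' @param fit a converged [gcsem()] fit with a parameter covariance.
#' @return object of class `gcsem_std` with components `lambda_genetic`,
#'   `lambda_residual` (matrices), `lambda_se` (same shapes), `h2` (data
#'   frame), `rg`/`rg_se` (k x k), `f2`/`f2_se` (trait x genetic factor) and
#'   a `heywood` flag marking standardized loadings exceeding 1 in absolute
#'   value.
#' @export
standardize_solution <- function(fit) {
  stopifnot(inherits(fit, "gcsem"))
  model <- fit$model
  k <- model$k
  if (any(diag(fit$SigmaV) <= 0))
    stop("trait with zero implied total variance; cannot standardize")

  fun_all <- function(theta) std_quantities(model, theta)
  est <- fun_all(fit$theta)
  J <- num_jacobian(fun_all, as.numeric(fit$theta))
  se <- sqrt(pmax(rowSums((J %*% fit$vcov) * J), 0))

  unpack <- function(vals) {
    pa <- ncol(model$genetic)
    pe <- ncol(model$residual)
    i <- 0
    take <- function(m) {
      out <- matrix(vals[i + seq_len(m)], nrow = k)
      i <<- i + m
      out
    }
    lamA <- take(k * pa)
    lamE <- take(k * pe)
    h2 <- vals[i + seq_len(k)]; i <- i + k
    rg <- matrix(vals[i + seq_len(k * k)], k); i <- i + k * k
    f2 <- take(k * pa)
    list(lamA = lamA, lamE = lamE, h2 = h2, rg = rg, f2 = f2)
  }
  E <- unpack(est)
  S <- unpack(se)
  factor_names <- function(pat, tag) paste0(tag, seq_len(ncol(pat)))
  dimnames(E$lamA) <- dimnames(S$lamA) <- dimnames(E$f2) <-
    dimnames(S$f2) <- list(model$traits, factor_names(model$genetic, "A"))
  dimnames(E$lamE) <- dimnames(S$lamE) <-
    list(model$traits, factor_names(model$residual, "E"))
  dimnames(E$rg) <- dimnames(S$rg) <- list(model$traits, model$traits)
  structure(list(
    lambda_genetic = E$lamA, lambda_residual = E$lamE,
    lambda_se = list(genetic = S$lamA, residual = S$lamE),
    h2 = data.frame(trait = model$traits, h2 = E$h2, se = S$h2,
                    row.names = NULL),
    rg = E$rg, rg_se = S$rg, f2 = E$f2, f2_se = S$f2,
    heywood = any(abs(E$lamA) > 1 + 1e-6) || any(abs(E$lamE) > 1 + 1e-6)),
    class = "gcsem_std")
}

## All standardized quantities as one vector of smooth functions of theta,
## so a single Jacobian serves every Delta-method SE.
std_quantities <- function(model, theta) {
  L <- theta_fill(model, theta)
  SigmaA <- tcrossprod(L$LA)
  SigmaE <- tcrossprod(L$LE)
  sv <- sqrt(diag(SigmaA + SigmaE))
  lamA <- L$LA / sv
  lamE <- L$LE / sv
  h2 <- diag(SigmaA) / sv^2
  sg <- sqrt(pmax(diag(SigmaA), 1e-300))
  rg <- SigmaA / outer(sg, sg)
  gvar <- L$LA^2
  denom <- rowSums(gvar)
  f2 <- gvar / ifelse(denom > 0, denom, NA_real_)
  c(lamA, lamE, h2, rg, f2)
}

num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.gcsem_std <- function(x, ...) {
  cat("Standardized GRM-SEM solution\n")
  cat("\nGenetic loadings (SE):\n")
  print(fmt_mat(x$lambda_genetic, x$lambda_se$genetic), quote = FALSE)
  cat("\nSNP heritability:\n")
  print(transform(x$h2, h2 = round(h2, 3), se = round(se, 3)),
        row.names = FALSE)
  cat("\nGenetic correlations:\n")
  print(round(x$rg, 3))
  if (isTRUE(x$heywood))
    cat("\nNOTE: standardized loading(s) exceed 1 (Heywood-like solution)\n")
  invisible(x)
}

fmt_mat <- function(m, s) {
  out <- matrix(sprintf("%6.3f (%5.3f)", m, s), nrow(m),
                dimnames = dimnames(m))
  out[m == 0 & s == 0] <- "  --  "
  out
}
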
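#' Specify a genetic covariance structural model
#'
#' Builds the loading-pattern matrices for the genetic and residual parts of
#' a GRM-SEM model. The phenotypic covariance is modelled as
#' \deqn{\Sigma_V = \Lambda_A \Lambda_A^T \otimes G +
#'       \Lambda_E \Lambda_E^T \otimes I,}
#' with factor variances fixed to the identity, so a model family is fully
#' described by which cells of \eqn{\Lambda_A} (k x p_a) and \eqn{\Lambda_E}
#' (k x p_e) are free and which are fixed.
#'
#' Families:
#' \describe{
#'   \item{`cholesky`}{saturated: both parts lower-triangular k x k, all
#'     free; `k (k + 1)` free parameters in total.}
#'   \item{`ip`}{independent pathway: `n_shared` shared columns loading on
#'     all traits plus one specific factor per trait (diagonal block), in
#'     both parts.}
#'   \item{`ipc`}{hybrid: independent-pathway genetic part, Cholesky
#'     residual part.}
#'   \item{`bifactor`}{IPC-like genetic part with one extra general factor
#'     column loading on every trait, ahead of `n_shared` grouping columns
#'     and the specific block; Cholesky residual part. Grouping columns are
#'     normally restricted via `constraints`.}
#' }
#'
#' @param family model family, one of `"cholesky"`, `"ip"`, `"ipc"`,
#'   `"bifactor"`.
#' @param k number of traits.
#' @param n_shared number of shared genetic factors (`ip`, `ipc`: the
#'   genetic shared block; `bifactor`: the grouping columns).
#' @param n_shared_residual number of shared residual factors (`ip` only).
#' @param constraints optional data frame with columns `part`
#'   (`"genetic"`/`"residual"`), `row`, `col`, `value`, fixing individual
#'   structurally-free cells (typically to 0).
#' @param start optional list with matrices `genetic` and/or `residual`
#'   supplying starting values for free cells.
#' @param traits optional trait labels.
#' @return object of class `gcsem_model` with the pattern matrices (`NA` =
#'   free cell), starting values, and the free parameter count `n_par`.
#' @export
gcsem_model <- function(family = c("cholesky", "ip", "ipc", "bifactor"),
                        k, n_shared = 1, n_shared_residual = n_shared,
                        constraints = NULL, start = NULL, traits = NULL) {
  family <- match.arg(family)
  if (k < 1) stop("k must be >= 1")
  free_lower <- function() {
    m <- matrix(0, k, k)
    m[lower.tri(m, diag = TRUE)] <- NA
    m
  }
  free_block <- function(q) matrix(NA_real_, k, q)
  free_diag <- function() {
    m <- matrix(0, k, k)
    diag(m) <- NA
    m
  }
  genetic <- switch(family,
    cholesky = free_lower(),
    ip = ,
    ipc = {
      if (n_shared < 1) stop("n_shared must be >= 1 for this family")
      cbind(free_block(n_shared), free_diag())
    },
    bifactor = {
      if (n_shared < 1) stop("bifactor needs at least one grouping factor")
      cbind(free_block(1), free_block(n_shared), free_diag())
    })
  residual <- switch(family,
    cholesky = ,
    ipc = ,
    bifactor = free_lower(),
    ip = {
      if (n_shared_residual < 1) stop("n_shared_residual must be >= 1")
      cbind(free_block(n_shared_residual), free_diag())
    })
  mod <- structure(list(family = family, k = k, n_shared = n_shared,
                        n_shared_residual =
                          if (family == "ip") n_shared_residual else NULL,
                        genetic = genetic, residual = residual,
                        start = list(genetic = NULL, residual = NULL),
                        traits = traits %||% paste0("trait", seq_len(k))),
                   class = "gcsem_model")
  if (!is.null(constraints)) mod <- apply_constraints(mod, constraints)
  if (!is.null(start)) {
    if (!is.null(start$genetic)) mod$start$genetic <- as.matrix(start$genetic)
    if (!is.null(start$residual))
      mod$start$residual <- as.matrix(start$residual)
  }
  mod$n_par <- n_par(mod)
  if (mod$n_par > k * (k + 1))
    stop(sprintf(
      "model has %d free parameters but only %d covariance moments: unidentified",
      mod$n_par, k * (k + 1)))
  mod
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_constraints <- function(mod, constraints) {
  constraints <- as.data.frame(constraints)
  need <- c("part", "row", "col")
  if (!all(need %in% names(constraints)))
    stop("constraints need columns part, row, col (and optionally value)")
  if (is.null(constraints$value)) constraints$value <- 0
  for (i in seq_len(nrow(constraints))) {
    part <- match.arg(constraints$part[i], c("genetic", "residual"))
    r <- constraints$row[i]; c_ <- constraints$col[i]
    pat <- mod[[part]]
    if (r < 1 || r > nrow(pat) || c_ < 1 || c_ > ncol(pat) ||
        !is.na(pat[r, c_]))
      stop(sprintf("constraint targets a structurally absent cell: %s[%d, %d]",
                   part, r, c_))
    mod[[part]][r, c_] <- constraints$value[i]
  }
  mod
}

n_par <- function(mod) sum(is.na(mod$genetic)) + sum(is.na(mod$residual))

#' @export
print.gcsem_model <- function(x, ...) {
  cat(sprintf("GRM-SEM model spec: family '%s', %d traits, %d free parameters\n",
              x$family, x$k, x$n_par))
  cat(sprintf("  genetic part: %d x %d (%d free), residual part: %d x %d (%d free)\n",
              nrow(x$genetic), ncol(x$genetic), sum(is.na(x$genetic)),
              nrow(x$residual), ncol(x$residual), sum(is.na(x$residual))))
  invisible(x)
}

## --- theta packing -------------------------------------------------------

## Free cells in column-major order, genetic part first.
theta_fill <- function(mod, theta) {
  ng <- sum(is.na(mod$genetic))
  LA <- mod$genetic
  LA[is.na(mod$genetic)] <- theta[seq_len(ng)]
  LE <- mod$residual
  LE[is.na(mod$residual)] <- theta[ng + seq_len(sum(is.na(mod$residual)))]
  list(LA = LA, LE = LE)
}

theta_labels <- function(mod) {
  lab <- function(pat, tag) {
    idx <- which(is.na(pat), arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    sprintf("%s[%d,%d]", tag, idx[, 1], idx[, 2])
  }
  c(lab(mod$genetic, "A"), lab(mod$residual, "E"))
}

## Extract free-cell entries of gradient matrices into theta order.
grad_pack <- function(mod, GA, GE) {
  c(GA[is.na(mod$genetic)], GE[is.na(mod$residual)])
}
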
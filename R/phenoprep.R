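#' Deviance residuals for a binary phenotype
#'
#' Fits a binary logistic regression of the trait on the covariates and
#' returns per-individual deviance residuals,
#' \deqn{d_i = \mathrm{sign}(y_i - \hat p_i)
#'   \sqrt{-2 [ y_i \log \hat p_i + (1 - y_i) \log(1 - \hat p_i) ]},}
#' the signed square root of each observation's contribution to the model
#' deviance. These are the transformed scores used for categorical traits in
#' downstream variance-component models: they carry the covariate-adjusted
#' liability information of a 0/1 trait on a continuous scale.
#'
#' @param y binary 0/1 vector (`NA` allowed, propagated to the output).
#' @param covariates data frame or matrix of numeric covariates; rows used
#'   for fitting must be complete.
#' @param trait label used in error messages.
#' @param min_prevalence warn when the within-sample prevalence of the rarer
#'   class falls below this fraction (default 5%).
#' @return numeric vector of deviance residuals, `NA` where `y` is missing.
#' @export
adjust_categorical <- function(y, covariates = NULL, trait = "trait",
                               min_prevalence = 0.05) {
  y <- as.numeric(y)
  obs <- !is.na(y)
  if (!all(y[obs] %in% c(0, 1)))
    stop("trait '", trait, "' is not binary 0/1")
  if (length(unique(y[obs])) < 2)
    stop("trait '", trait, "' has only one class present")
  prev <- mean(y[obs])
  if (min(prev, 1 - prev) < min_prevalence)
    warning("trait '", trait, "' has within-sample prevalence below ",
            format(100 * min_prevalence), "%")
  X <- prep_covariates(covariates, length(y))
  dat <- data.frame(.y = y, X)
  fit <- tryCatch(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               na.action = stats::na.exclude),
    error = function(e) stop("logistic fit failed for trait '", trait, "': ",
                             conditionMessage(e)))
  if (!fit$converged)
    stop("logistic fit did not converge for trait '", trait, "'")
  p <- stats::fitted(fit)
  if (any(p[!is.na(p)] < 1e-10 | p[!is.na(p)] > 1 - 1e-10))
    stop("separation detected in logistic fit for trait '", trait, "'")
  as.numeric(stats::residuals(fit, type = "deviance"))
}

#' Fully-adjusted two-stage rank normalisation of a continuous phenotype
#'
#' Three-step transform for continuous traits: (1) residualize the trait on
#' the covariates by ordinary least squares; (2) map the residual ranks to
#' normal quantiles using the Blom offset,
#' \eqn{\Phi^{-1}((r - 3/8)/(n + 1/4))}, with ties receiving average ranks;
#' (3) residualize the normalized scores on the same covariates again, so
#' that the rank transform cannot re-introduce covariate effects. The result
#' is standardized (population-SD convention, see [standardize_traits()]).
#' The output is invariant to any monotone transform of the input.
#'
#' @inheritParams adjust_categorical
#' @param y numeric vector (`NA` allowed, propagated).
#' @return numeric vector of covariate-adjusted, rank-normalized scores.
#' @export
adjust_continuous <- function(y, covariates = NULL, trait = "trait") {
  y <- as.numeric(y)
  obs <- !is.na(y)
  if (sum(obs) < 10)
    stop("trait '", trait, "' has fewer than 10 non-missing values")
  if (stats::var(y[obs]) == 0) stop("trait '", trait, "' is constant")
  X <- prep_covariates(covariates, length(y))
  dat <- data.frame(.y = y, X)
  r1 <- stats::resid(stats::lm(.y ~ ., data = dat,
                               na.action = stats::na.exclude))
  z <- rank_inverse_normal(as.numeric(r1))
  dat$.y <- z
  r2 <- stats::resid(stats::lm(.y ~ ., data = dat,
                               na.action = stats::na.exclude))
  out <- as.numeric(r2)
  obs2 <- !is.na(out)
  out[obs2] <- out[obs2] / pop_sd(out[obs2])
  out
}

#' Rank-based inverse normal transform (Blom offset)
#'
#' @param x numeric vector; `NA` propagated.
#' @param offset rank offset `c` in \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))};
#'   the default 3/8 is the Blom convention.
#' @return normal scores.
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  out <- rep(NA_real_, length(x))
  obs <- !is.na(x)
  n <- sum(obs)
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Z-standardize phenotype columns
#'
#' Centres and scales each column to mean 0 and variance 1 over its
#' non-missing entries. The population-SD convention (denominator `n`) is
#' used so that a standardized column has exactly unit second moment; this is
#' the "deviation from the mean" contract that lets the variance-component
#' models omit mean estimation. Missing entries stay missing.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape, standardized column-wise.
#' @export
standardize_traits <- function(x) {
  if (is.null(dim(x))) return(standardize_one(x))
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[, j] <- standardize_one(x[, j])
  x
}

standardize_one <- function(v) {
  obs <- !is.na(v)
  if (sum(obs) < 2 || length(unique(v[obs])) < 2)
    stop("cannot standardize a constant column")
  v[obs] <- (v[obs] - mean(v[obs])) / pop_sd(v[obs])
  v
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Prepare a phenotype table for genetic covariance modelling
#'
#' Applies the per-trait transformation ([adjust_categorical()] for binary
#' traits, [adjust_continuous()] for continuous ones) followed by
#' Z-standardization, returning the trait matrix the modelling functions
#' consume.
#'
#' @param pheno data frame or matrix of raw traits (one column per trait);
#'   row names or `ids` give the sample identifiers.
#' @param covariates covariate table used for adjustment (optional).
#' @param types character vector, one of `"continuous"` or `"categorical"`
#'   per trait; defaults to treating 0/1 columns as categorical.
#' @param ids optional sample identifiers.
#' @return numeric matrix (individuals x traits) of standardized scores with
#'   IDs as row names.
#' @export
prepare_phenotypes <- function(pheno, covariates = NULL, types = NULL,
                               ids = NULL) {
  pheno <- as.data.frame(pheno)
  if (is.null(ids)) ids <- rownames(pheno)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(pheno)))
  if (is.null(types)) {
    types <- vapply(pheno, function(col) {
      u <- unique(col[!is.na(col)])
      if (all(u %in% c(0, 1))) "categorical" else "continuous"
    }, character(1))
  }
  types <- match.arg(types, c("continuous", "categorical"),
                     several.ok = TRUE)
  if (length(types) != ncol(pheno))
    stop("'types' must name one kind per trait")
  out <- matrix(NA_real_, nrow(pheno), ncol(pheno),
                dimnames = list(ids, colnames(pheno)))
  for (j in seq_len(ncol(pheno))) {
    tr <- colnames(pheno)[j]
    out[, j] <- if (types[j] == "categorical")
      adjust_categorical(pheno[[j]], covariates, trait = tr)
    else
      adjust_continuous(pheno[[j]], covariates, trait = tr)
  }
  standardize_traits(out)
}

prep_covariates <- function(covariates, n) {
  if (is.null(covariates))
    return(data.frame(row.names = seq_len(n)))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    stop("covariate table does not match phenotype length")
  if (!all(vapply(covariates, is.numeric, logical(1))))
    stop("covariates must be numeric")
  covariates
}
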
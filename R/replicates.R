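#' IPC model matching a simulation scenario's generative topology
#'
#' Builds the fitted-model counterpart of a [sim_scenario()]: an IPC model
#' whose shared genetic cells are free exactly where the scenario's true
#' shared loadings are non-zero (fixed to zero elsewhere), with one free
#' specific genetic loading per trait and a saturated residual Cholesky.
#'
#' @param scenario a [sim_scenario()] object.
#' @return a [gcsem_model()] of family `"ipc"`.
#' @export
scenario_model <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sh <- scenario$genetic_loadings[, seq_len(scenario$n_shared),
                                  drop = FALSE]
  zero <- which(sh == 0, arr.ind = TRUE)
  constraints <- if (nrow(zero))
    data.frame(part = "genetic", row = zero[, 1], col = zero[, 2],
               value = 0) else NULL
  gcsem_model("ipc", k = scenario$k, n_shared = scenario$n_shared,
              constraints = constraints, traits = scenario$traits)
}

## True standardized values of the free genetic parameters of a model,
## given the generating scenario (residual Cholesky truths are not defined
## parameter-by-parameter and are excluded from scoring).
scenario_truth <- function(scenario, model) {
  G <- scenario$genetic_loadings
  truth <- matrix(NA_real_, nrow(G), ncol(model$genetic))
  truth[, seq_len(scenario$n_shared)] <- G[, seq_len(scenario$n_shared)]
  truth[, scenario$n_shared + seq_len(scenario$k)] <-
    G[, scenario$n_shared + seq_len(scenario$k)]
  lab <- theta_labels(model)
  vals <- truth[is.na(model$genetic)]
  stats::setNames(vals, lab[seq_along(vals)])
}

#' Run a replicated simulation study
#'
#' For each replicate a fresh genotype matrix and phenotype set are drawn
#' from the scenario (child seeds are spawned deterministically from the
#' scenario seed), a GRM is computed and eigendecomposed, the model is
#' fitted and its standardized genetic loadings with Delta-method SEs are
#' collected. Replicates whose fit does not converge are flagged and
#' excluded from the performance summary, with the count disclosed.
#'
#' @param scenario a [sim_scenario()] object.
#' @param model a [gcsem_model()]; defaults to [scenario_model()].
#' @param n_causal_loci optional override of the scenario locus count (the
#'   GRM and causal sets always use the same loci).
#' @param progress print one line per replicate?
#' @return object of class `sim_study`: `performance` (a
#'   [summarize_performance()] table over the shared genetic loadings and
#'   specific loadings), `estimates`/`ses` (replicate x parameter),
#'   `truth`, `n_converged`, `n_replicates`.
#' @export
run_replicates <- function(scenario, model = scenario_model(scenario),
                           n_causal_loci = NULL, progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"),
            inherits(model, "gcsem_model"))
  if (model$k != scenario$k) stop("model trait count does not match scenario")
  m <- n_causal_loci %||% scenario$n_causal_loci
  R <- scenario$n_replicates
  withr_seed(scenario$seed)
  child <- matrix(sample.int(.Machine$integer.max - 1, 2 * R), R, 2)
  truth <- scenario_truth(scenario, model)
  keep <- !is.na(truth)
  est <- se <- matrix(NA_real_, R, sum(keep),
                      dimnames = list(NULL, names(truth)[keep]))
  ok <- logical(R)
  for (r in seq_len(R)) {
    X <- sim_genotypes(scenario$n_individuals, m, scenario$maf_range,
                       seed = child[r, 1])
    sc <- scenario
    sc$n_causal_loci <- m
    Y <- sim_phenotypes(sc, X, seed = child[r, 2])
    grm <- grm_eigen(compute_grm(X))
    fit <- tryCatch(gcsem(Y, grm, model), error = function(e) NULL)
    ok[r] <- !is.null(fit) && fit$converged
    if (ok[r]) {
      std <- standardize_solution(fit)
      lam <- std$lambda_genetic
      lse <- std$lambda_se$genetic
      free <- is.na(model$genetic)
      est[r, ] <- lam[free][keep]
      se[r, ] <- lse[free][keep]
    }
    if (progress)
      cat(sprintf("replicate %d/%d %s\n", r, R,
                  if (ok[r]) "converged" else "FAILED"))
  }
  perf <- summarize_performance(est[ok, , drop = FALSE],
                                se[ok, , drop = FALSE], truth[keep])
  structure(list(performance = perf, estimates = est, ses = se,
                 truth = truth[keep], converged = ok,
                 n_converged = sum(ok), n_replicates = R,
                 scenario = scenario, model = model),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d/%d replicate(s) converged\n",
              x$n_converged, x$n_replicates))
  print(x$performance)
  invisible(x)
}

#' Summarize simulation performance across replicates
#'
#' Per parameter: the median estimate, median bias (median of estimate minus
#' truth), empirical SE (sample SD of estimates) and coverage (fraction of
#' replicates whose 95% Wald interval, estimate +/- 1.96 SE, contains the
#' truth), each with its Monte-Carlo SE: `1.2533 * empSE / sqrt(R)` for the
#' median bias (asymptotic SE of a median), `empSE / sqrt(2 (R - 1))` for
#' the empirical SE, and the binomial `sqrt(c (1 - c) / R)` for coverage.
#'
#' @param estimates replicate x parameter matrix of estimates.
#' @param ses matching matrix of standard errors.
#' @param truth named vector of true parameter values (names must match the
#'   estimate columns).
#' @return data frame of class `performance_table`.
#' @export
summarize_performance <- function(estimates, ses, truth) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  if (!is.null(colnames(estimates)) && !is.null(names(truth)) &&
      !identical(colnames(estimates), names(truth)))
    stop("parameter labels of estimates and truth do not match")
  R <- nrow(estimates)
  if (R < 2) stop("need at least two replicates")
  out <- do.call(rbind, lapply(seq_along(truth), function(j) {
    e <- estimates[, j]
    s <- ses[, j]
    empse <- stats::sd(e)
    cover <- mean(truth[j] >= e - 1.96 * s & truth[j] <= e + 1.96 * s)
    data.frame(
      parameter = names(truth)[j] %||% paste0("par", j),
      truth = as.numeric(truth[j]),
      median_est = stats::median(e),
      median_bias = stats::median(e - truth[j]),
      empse = empse,
      coverage = cover,
      mcse_bias = 1.2533 * empse / sqrt(R),
      mcse_empse = empse / sqrt(2 * (R - 1)),
      mcse_coverage = sqrt(cover * (1 - cover) / R),
      row.names = NULL)
  }))
  class(out) <- c("performance_table", "data.frame")
  out
}

#' @export
print.performance_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write / read a performance table as delimited text
#'
#' @param x a [summarize_performance()] table.
#' @param path output file.
#' @export
write_performance <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
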
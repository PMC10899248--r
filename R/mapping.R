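#' Extend a fitted model structure with a mapping variable
#'
#' Characterises an identified genetic factor structure by loading an
#' additional standardized measure (e.g. a polygenic score or a liability
#' score) onto it: the mapping trait loads freely on every shared genetic
#' factor, gains its own specific genetic factor, and extends the residual
#' Cholesky by one row, while all constraints of the base structure are
#' preserved. Exactly `n_shared + 1 + (k + 1)` free parameters are added
#' relative to the base specification.
#'
#' @param base a fitted [gcsem()] object or a [gcsem_model()] of the
#'   `ipc`/`bifactor` family (independent-pathway genetic part, Cholesky
#'   residual part).
#' @param mapping_name label for the mapping variable.
#' @return a [gcsem_model()] for `k + 1` traits; fit it with [gcsem()] on a
#'   phenotype matrix whose last column holds the standardized mapping
#'   variable.
#' @export
extend_with_mapping <- function(base, mapping_name = "mapping") {
  model <- if (inherits(base, "gcsem")) base$model else base
  stopifnot(inherits(model, "gcsem_model"))
  if (!model$family %in% c("ipc", "bifactor"))
    stop("mapping extension is defined for IPC-type structures")
  k <- model$k
  nsh <- ncol(model$genetic) - k          # shared (and general) columns
  # genetic part: new row free on shared columns, specific block grows
  shared <- rbind(model$genetic[, seq_len(nsh), drop = FALSE],
                  rep(NA_real_, nsh))
  spec_old <- model$genetic[, nsh + seq_len(k), drop = FALSE]
  spec <- matrix(0, k + 1, k + 1)
  spec[seq_len(k), seq_len(k)] <- spec_old
  spec[k + 1, k + 1] <- NA
  genetic <- cbind(shared, spec)
  # residual part: Cholesky one trait larger, preserving existing fixings
  residual <- matrix(0, k + 1, k + 1)
  residual[lower.tri(residual, diag = TRUE)] <- NA
  residual[seq_len(k), seq_len(k)] <- model$residual
  new <- model
  new$k <- k + 1
  new$genetic <- genetic
  new$residual <- residual
  new$traits <- c(model$traits, mapping_name)
  new$start <- list(genetic = NULL, residual = NULL)
  if (inherits(base, "gcsem")) {
    stg <- matrix(NA_real_, k + 1, ncol(genetic))
    stg[seq_len(k), seq_len(nsh)] <- base$LA[, seq_len(nsh), drop = FALSE]
    stg[seq_len(k), nsh + seq_len(k)] <- base$LA[, nsh + seq_len(k),
                                                 drop = FALSE]
    stg[k + 1, seq_len(nsh)] <- 0.1
    stg[k + 1, ncol(genetic)] <- 0.3
    ste <- matrix(NA_real_, k + 1, k + 1)
    ste[seq_len(k), seq_len(k)] <- base$LE
    ste[k + 1, ] <- c(rep(0.05, k), 0.8)
    new$start <- list(genetic = stg, residual = ste)
  }
  new$n_par <- n_par(new)
  if (new$n_par != model$n_par + nsh + 1 + (k + 1))
    stop("internal error: unexpected parameter count after extension")
  new
}
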
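#' Genetic relationship matrices
#'
#' A `grm` object holds a symmetric n x n genetic relationship matrix (GRM)
#' together with the sample identifiers and, for GRMs estimated from genotype
#' data, the per-pair count of SNPs that entered each entry. An
#' eigendecomposition can be cached on the object (see [grm_eigen()]); the
#' model-fitting functions use the cache to rotate phenotypes into the GRM
#' eigenbasis.
#'
#' @param values symmetric numeric matrix of relationships.
#' @param ids sample identifiers: either a character vector (used for both
#'   family and individual ID) or a two-column data frame with columns
#'   `FID`, `IID`.
#' @param counts optional matrix of per-pair SNP counts (same dimension as
#'   `values`).
#' @return an object of class `grm` with elements `values`, `counts`, `ids`
#'   and (possibly `NULL`) `eigen`.
#' @export
as_grm <- function(values, ids = NULL, counts = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("'values' must be square")
  if (any(!is.finite(values))) stop("GRM contains non-finite entries")
  if (max(abs(values - t(values))) > 1e-8)
    stop("GRM is not symmetric")
  values <- (values + t(values)) / 2
  if (is.null(ids)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("id", seq_len(n))
  }
  ids <- normalize_grm_ids(ids, n)
  dimnames(values) <- list(ids$IID, ids$IID)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == dim(values)))
  }
  structure(list(values = values, counts = counts, ids = ids, eigen = NULL),
            class = "grm")
}

normalize_grm_ids <- function(ids, n) {
  if (is.data.frame(ids)) {
    if (ncol(ids) < 2) ids <- data.frame(FID = ids[[1]], IID = ids[[1]])
    ids <- data.frame(FID = as.character(ids[[1]]), IID = as.character(ids[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    ids <- data.frame(FID = as.character(ids), IID = as.character(ids),
                      stringsAsFactors = FALSE)
  }
  if (nrow(ids) != n) stop("number of IDs does not match GRM dimension")
  if (anyDuplicated(ids$IID)) stop("duplicated individual IDs in GRM")
  ids
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  cat("Genetic relationship matrix:", n, "individuals\n")
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  mean diagonal %.4f, off-diagonal range [%.4f, %.4f]\n",
              mean(diag(x$values)), min(off), max(off)))
  if (!is.null(x$eigen)) cat("  eigendecomposition cached\n")
  invisible(x)
}

#' Estimate a GRM from genotype dosages
#'
#' Computes the standard allele-frequency-standardized relationship estimator
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' over the SNPs that are non-missing in both members of each pair
#' (\eqn{M_{jk}} is that pairwise count). Allele frequencies are estimated
#' from the sample. Monomorphic SNPs carry no relationship information and
#' are excluded (a message reports how many).
#'
#' @param genotypes integer/numeric matrix of dosages in `{0, 1, 2}`
#'   (individuals x SNPs), `NA` for missing. Row names, when present, are
#'   used as sample IDs.
#' @param ids optional sample identifiers overriding the row names.
#' @return a [as_grm()] object with pairwise SNP counts.
#' @export
compute_grm <- function(genotypes, ids = NULL) {
  X <- as.matrix(genotypes)
  if (nrow(X) < 2) stop("need at least two individuals")
  bad <- !(X %in% c(0, 1, 2) | is.na(X))
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing")
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("id", seq_len(nrow(X)))
  all_missing <- rowSums(!is.na(X)) == 0
  if (any(all_missing))
    stop("individual(s) with no genotype data: ",
         paste(as.character(ids)[all_missing], collapse = ", "))
  p <- colMeans(X, na.rm = TRUE) / 2
  v <- apply(X, 2, function(col) stats::var(col, na.rm = TRUE))
  poly <- p > 0 & p < 1 & !is.na(v) & v > 0
  if (!any(poly)) stop("all SNPs are monomorphic")
  if (any(!poly))
    message(sum(!poly), " monomorphic SNP(s) excluded from GRM estimation")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(W)
  W[miss] <- 0
  A <- tcrossprod(W)
  if (any(miss)) {
    obs <- matrix(1, nrow(X), ncol(X))
    obs[miss] <- 0
    M <- tcrossprod(obs)
    if (any(M == 0)) stop("individual pair(s) with no mutually observed SNPs")
  } else {
    M <- matrix(ncol(X), nrow(X), nrow(X))
  }
  as_grm(A / M, ids = ids, counts = M)
}

#' Write a GRM in the GCTA binary format
#'
#' Writes the lower triangle (diagonal included, row-major order) of the
#' relationship matrix as 4-byte little-endian floats to `<prefix>.grm.bin`,
#' the matching per-pair SNP counts to `<prefix>.grm.N.bin`, and a
#' two-column (FID IID) ID table to `<prefix>.grm.id`.
#'
#' @param grm a [as_grm()] object.
#' @param prefix path prefix for the three companion files.
#' @return the prefix, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  if (any(!is.finite(grm$values))) stop("GRM contains non-finite values")
  n <- nrow(grm$values)
  idx <- lower_tri_index(n)
  vals <- grm$values[idx]
  counts <- if (is.null(grm$counts)) rep(1, length(vals)) else grm$counts[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(counts), con, size = 4, endian = "little")
  close(con)
  utils::write.table(grm$ids, paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

lower_tri_index <- function(n) {
  i <- unlist(lapply(seq_len(n), function(r) seq_len(r)))
  j <- rep(seq_len(n), seq_len(n))
  cbind(j, i)
}

#' Read a GRM in the GCTA binary format
#'
#' @param prefix path prefix; `<prefix>.grm.bin`, `<prefix>.grm.N.bin` and
#'   `<prefix>.grm.id` must exist. The `.grm.bin` byte length must equal
#'   `4 * n * (n + 1) / 2` for the `n` inferred from the ID file.
#' @return a [as_grm()] object.
#' @export
read_grm <- function(prefix) {
  idfile <- paste0(prefix, ".grm.id")
  binfile <- paste0(prefix, ".grm.bin")
  nfile <- paste0(prefix, ".grm.N.bin")
  if (!file.exists(idfile) || !file.exists(binfile))
    stop("GRM companion files not found for prefix: ", prefix)
  ids <- utils::read.table(idfile, header = FALSE,
                           colClasses = "character")[, 1:2]
  names(ids) <- c("FID", "IID")
  n <- nrow(ids)
  nvals <- n * (n + 1) / 2
  if (file.size(binfile) != 4 * nvals)
    stop(sprintf(".grm.bin has %d bytes; expected %d for n = %d",
                 file.size(binfile), 4 * nvals, n))
  con <- file(binfile, "rb")
  vals <- readBin(con, "numeric", n = nvals, size = 4, endian = "little")
  close(con)
  idx <- lower_tri_index(n)
  A <- matrix(0, n, n)
  A[idx] <- vals
  A[idx[, c(2, 1)]] <- vals
  counts <- NULL
  if (file.exists(nfile)) {
    if (file.size(nfile) != 4 * nvals)
      stop(".grm.N.bin size inconsistent with ID count")
    con <- file(nfile, "rb")
    nv <- readBin(con, "numeric", n = nvals, size = 4, endian = "little")
    close(con)
    counts <- matrix(0, n, n)
    counts[idx] <- nv
    counts[idx[, c(2, 1)]] <- nv
  }
  as_grm(A, ids = ids, counts = counts)
}

#' Remove related individuals from a GRM
#'
#' Greedy pruning: while any pair exceeds the relatedness cutoff, the
#' individual with the largest number of above-cutoff partners is removed
#' (ties broken by input order). The returned set contains no pair with an
#' off-diagonal relationship above the cutoff. The default cutoff of 0.05 is
#' the conventional threshold for "unrelated" samples in GREML-type analyses.
#'
#' @param grm a [as_grm()] object.
#' @param cutoff positive relatedness threshold.
#' @return character vector of retained individual IDs (input order).
#' @export
prune_related <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"), cutoff > 0)
  A <- abs(grm$values)
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  repeat {
    over <- A > cutoff & outer(keep, keep)
    deg <- rowSums(over)
    if (all(deg == 0)) break
    drop <- which.max(deg)   # first index among ties
    keep[drop] <- FALSE
  }
  grm$ids$IID[keep]
}

#' Cache the eigendecomposition of a GRM
#'
#' Computes eigenvalues (non-increasing) and eigenvectors of the relationship
#' matrix and attaches them to the object. Eigenvalues below `1e-10` are
#' clamped to zero (with a warning when clearly negative), as near-singular
#' GRMs otherwise propagate noise into the rotated likelihood.
#'
#' @param grm a [as_grm()] object.
#' @return the `grm` with `$eigen` set to `list(values, vectors)`.
#' @export
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (!is.null(grm$eigen)) return(grm)
  if (any(!is.finite(grm$values))) stop("GRM contains non-finite entries")
  e <- eigen(grm$values, symmetric = TRUE)
  if (any(e$values < 1e-10)) {
    # rank-deficient GRMs (fewer SNPs than individuals) legitimately carry
    # zero eigenvalues; only clearly negative values deserve a warning
    if (any(e$values < -1e-6))
      warning("GRM has negative eigenvalues; clamped to zero")
    e$values <- pmax(e$values, 0)
  }
  grm$eigen <- list(values = e$values, vectors = e$vectors)
  grm
}

## Subset a GRM to a set of IIDs (internal); drops any cached eigen.
grm_subset <- function(grm, iids) {
  idx <- match(iids, grm$ids$IID)
  if (anyNA(idx)) stop("IDs not present in GRM: ",
                       paste(iids[is.na(idx)], collapse = ", "))
  as_grm(grm$values[idx, idx, drop = FALSE],
         ids = grm$ids[idx, , drop = FALSE],
         counts = if (is.null(grm$counts)) NULL else
           grm$counts[idx, idx, drop = FALSE])
}
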
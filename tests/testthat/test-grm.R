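test_that("GRM estimator matches hand arithmetic on a two-individual example", {
  # dosages [0,2] and [2,0] at two SNPs, sample frequency 0.5 at both:
  # standardized dosages are +/- sqrt(2), so A11 = A22 = 2, A12 = -2
  g <- compute_grm(rbind(c(0, 2), c(2, 0)))
  expect_equal(unname(diag(g$values)), c(2, 2), tolerance = 1e-12)
  expect_equal(g$values[1, 2], -2, tolerance = 1e-12)
})

test_that("identical dosage rows give off-diagonal equal to the diagonal", {
  set.seed(5)
  x <- rbinom(30, 2, 0.4)
  X <- rbind(x, x, rbinom(30, 2, 0.4))
  rownames(X) <- NULL
  g <- compute_grm(X)
  expect_equal(g$values[1, 2], g$values[1, 1], tolerance = 1e-12)
})

test_that("GRM estimator agrees with a double-loop brute-force oracle", {
  set.seed(11)
  X <- matrix(rbinom(20 * 50, 2, runif(50, 0.1, 0.5)), 20, 50,
              byrow = FALSE)
  X[sample(length(X), 25)] <- NA            # exercise pairwise counts
  g <- compute_grm(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  A <- matrix(0, 20, 20)
  for (j in 1:20) for (l in 1:20) {
    num <- 0; cnt <- 0
    for (i in which(poly)) {
      if (!is.na(X[j, i]) && !is.na(X[l, i])) {
        num <- num + (X[j, i] - 2 * p[i]) * (X[l, i] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1
      }
    }
    A[j, l] <- num / cnt
  }
  expect_lt(max(abs(g$values - A)), 1e-10)
})

test_that("monomorphic handling and degenerate inputs error or log", {
  X <- rbind(c(0, 0, 1), c(0, 2, 1))
  expect_message(compute_grm(X), "monomorphic")
  expect_error(compute_grm(rbind(c(1, 1), c(1, 1))), "monomorphic")
  X2 <- rbind(c(NA, NA), c(0, 2))
  expect_error(compute_grm(X2, ids = c("a", "b")), "a")
})

test_that("mean GRM diagonal is near 1 for HWE-simulated unrelateds", {
  X <- sim_genotypes(300, 500, seed = 9)
  g <- compute_grm(X)
  expect_equal(mean(diag(g$values)), 1, tolerance = 0.05)
})

test_that("GCTA binary round-trip is lossless at float32 and sized correctly", {
  g <- random_grm(7, seed = 3)
  g$counts <- matrix(100, 7, 7)
  prefix <- tempfile()
  write_grm(g, prefix)
  expect_identical(file.size(paste0(prefix, ".grm.bin")), 4 * 7 * 8 / 2)
  g2 <- read_grm(prefix)
  # float32 rounding is the only permitted loss
  lt <- lower.tri(g$values, diag = TRUE)
  f32 <- readBin(writeBin(as.numeric(g$values[lt]), raw(), size = 4,
                          endian = "little"),
                 "numeric", n = sum(lt), size = 4, endian = "little")
  expect_identical(g2$values[lt], f32)
  expect_identical(g2$ids$IID, g$ids$IID)
})

test_that("hand-written GRM files parse to independently decoded bytes", {
  prefix <- tempfile()
  vals <- c(1.02, -0.03, 0.98)              # (1,1), (2,1), (2,2)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(vals, con, size = 4, endian = "little"); close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(c(10, 10, 10), con, size = 4, endian = "little"); close(con)
  writeLines(c("f1\ti1", "f2\ti2"), paste0(prefix, ".grm.id"))
  g <- read_grm(prefix)
  dec <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = 3, size = 4,
                 endian = "little")
  expect_identical(c(g$values[1, 1], g$values[2, 1], g$values[2, 2]), dec)
  expect_identical(g$ids$FID, c("f1", "f2"))
})

test_that("malformed GRM files raise format errors", {
  prefix <- tempfile()
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(c(1, 2), con, size = 4, endian = "little"); close(con)
  writeLines(c("a\ta", "b\tb"), paste0(prefix, ".grm.id"))
  expect_error(read_grm(prefix), "bytes")
})

test_that("pruning removes nothing when all pairs are below the cutoff", {
  g <- as_grm(diag(4) + 0.01)
  expect_identical(prune_related(g, 0.05), g$ids$IID)
})

test_that("pruning one related pair keeps exactly one of the two", {
  A <- diag(5)
  A[1, 2] <- A[2, 1] <- 0.9
  g <- as_grm(A)
  kept <- prune_related(g, 0.05)
  expect_length(kept, 4)
  expect_length(intersect(kept, c("id1", "id2")), 1)
})

test_that("greedy pruning matches the exhaustive maximum retained set on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 7
    A <- diag(n)
    pairs <- which(upper.tri(A), arr.ind = TRUE)
    rel <- pairs[sample(nrow(pairs), 5), , drop = FALSE]
    A[rel] <- 0.5
    A[rel[, c(2, 1)]] <- 0.5
    g <- as_grm(A)
    kept <- prune_related(g, 0.05)
    # brute force: largest subset with no related pair
    best <- 0
    for (size in n:0) {
      combos <- utils::combn(n, size)
      ok_any <- any(apply(combos, 2, function(s) {
        sub <- A[s, s, drop = FALSE]; diag(sub) <- 0
        all(sub <= 0.05)
      }))
      if (ok_any) { best <- size; break }
    }
    # greedy is valid and at least matches the optimum on these instances
    sub <- A[match(kept, g$ids$IID), match(kept, g$ids$IID)]
    diag(sub) <- 0
    expect_true(all(sub <= 0.05))
    expect_identical(length(kept), best)
  }
})

test_that("eigendecomposition cache reconstructs the GRM", {
  gI <- grm_eigen(as_grm(diag(5)))
  expect_equal(gI$eigen$values, rep(1, 5))
  v <- c(1, 2, 3)
  g1 <- suppressWarnings(grm_eigen(as_grm(outer(v, v))))
  expect_equal(g1$eigen$values[1], sum(v^2), tolerance = 1e-10)
  expect_lt(max(abs(g1$eigen$values[-1])), 1e-8)
  g <- grm_eigen(random_grm(12, seed = 8))
  rec <- g$eigen$vectors %*% (g$eigen$values * t(g$eigen$vectors))
  expect_lt(max(abs(rec - g$values)), 1e-8)
})
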
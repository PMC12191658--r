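test_that("COO loading symmetrizes by summing duplicate entries", {
  f <- tempfile()
  writeLines(c("1\t2\t5", "2\t1\t3", "0\t0\t7"), f)
  cm <- load_contacts(f, "coo_tsv", resolution = 100, chrom_len = 500)
  expect_equal(cm$n_bins, 5L)
  expect_equal(cm$mat[2, 3], 8)   # (1,2) + (2,1) summed
  expect_equal(cm$mat[3, 2], 8)
  expect_equal(cm$mat[1, 1], 7)   # diagonal retained at load
  expect_equal(cm$stage, "raw")
})

test_that("COO loading rejects negative counts and bad indices", {
  f <- tempfile()
  writeLines(c("0\t1\t4", "1\t2\t-1"), f)
  expect_error(load_contacts(f, "coo_tsv", 100, 500), "row 2")
  writeLines(c("0\t9\t4"), f)
  expect_error(load_contacts(f, "coo_tsv", 100, 500), "out of range")
})

test_that("empty contact file yields an all-zero matrix with a warning", {
  f <- tempfile(); file.create(f)
  expect_warning(cm <- load_contacts(f, "coo_tsv", 100, 500), "empty")
  expect_equal(sum(cm$mat), 0)
})

test_that("contact matrices round-trip through COO TSV", {
  fx <- biased_poisson_matrix(30, seed = 5)
  f <- tempfile()
  write_contacts(fx$cm, f)
  cm2 <- load_contacts(f, "coo_tsv", resolution = fx$cm$resolution,
                       chrom_len = 30 * fx$cm$resolution,
                       chrom = fx$cm$chrom)
  expect_equal(as.matrix(cm2$mat), as.matrix(fx$cm$mat))
})

test_that("KR balancing handles simple closed-form cases", {
  cm <- contact_matrix(matrix(c(0, 2, 2, 0), 2), "c", 1)
  bal <- kr_balance(cm)
  expect_equal(as.matrix(bal$mat), matrix(c(0, 2, 2, 0), 2),
               tolerance = 1e-6)   # mass-preserving rescale of [[0,1],[1,0]]
  expect_equal(bal$bias[1], bal$bias[2], tolerance = 1e-6)
  # an already doubly stochastic matrix is a fixed point
  ds <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  bal2 <- kr_balance(contact_matrix(ds, "c", 1))
  expect_equal(as.matrix(bal2$mat), ds, tolerance = 1e-5)
  expect_error(kr_balance(contact_matrix(matrix(0, 3, 3), "c", 1)),
               "all-zero")
})

test_that("KR recovers planted multiplicative biases on a rank-1 matrix", {
  b <- c(1, 2, 4, 1, 3, 2)
  cm <- contact_matrix(outer(b, b) * 2, "c", 1)
  bal <- kr_balance(cm)
  expect_lt(max(abs(bal$bias / (b / mean(b)) - 1)), 1e-4)
})

test_that("KR masks empty bins and meets the row-sum contract under noise", {
  fx <- biased_poisson_matrix(120, seed = 11)
  A <- as.matrix(fx$cm$mat)
  A[40, ] <- 0; A[, 40] <- 0               # knock out one bin
  bal <- kr_balance(contact_matrix(A, "c", 1))
  expect_true(bal$mask[40])
  expect_true(is.na(bal$bias[40]))
  expect_lt(bal$residual, 1e-6)
  keep <- !bal$mask
  rs <- Matrix::rowSums(bal$mat)[keep]
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-5)
  expect_equal(sum(bal$mat), sum(A))        # total mass preserved
})

test_that("distance expectation counts all positional pairs", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2
  m[2, 3] <- m[3, 2] <- 4
  m[3, 4] <- m[4, 3] <- 6
  m[1, 4] <- m[4, 1] <- 10
  expd <- distance_expectation(contact_matrix(m, "c", 1,
                                              stage = "balanced"))
  expect_equal(expd$n, c(3, 2, 1))
  expect_equal(expd$N[1], 12)
  expect_equal(expd$E[1], 4)                # E_1 = N/n = 12/3
  expect_equal(expd$E[3], 10)               # corner value, n = 1
  zero <- distance_expectation(contact_matrix(matrix(0, 4, 4), "c", 1))
  expect_equal(zero$E, rep(0, 3))
  expect_error(distance_expectation(contact_matrix(matrix(1, 1, 1), "c", 1)),
               "2 bins")
})

test_that("distance normalization divides by E_d and drops the diagonal", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2
  m[2, 3] <- m[3, 2] <- 4
  m[3, 4] <- m[4, 3] <- 6
  diag(m) <- 5
  cm <- contact_matrix(m, "c", 1, stage = "balanced")
  nn <- normalize_by_distance(cm)
  expect_equal(nn$mat[1, 2], 0.5)
  expect_equal(nn$mat[2, 3], 1.0)
  expect_equal(nn$mat[3, 4], 1.5)
  expect_equal(Matrix::diag(nn$mat), rep(0, 4))
  # constant-by-distance matrix -> everything exactly 1
  cb <- outer(1:6, 1:6, function(i, j) abs(i - j) * 10)
  nn2 <- normalize_by_distance(contact_matrix(cb, "c", 1,
                                              stage = "balanced"))
  offd <- as.matrix(nn2$mat)[upper.tri(cb)]
  expect_true(all(offd == 1))
})

test_that("per-distance stratum mean of normalized entries is exactly 1", {
  fx <- biased_poisson_matrix(80, seed = 3)
  bal <- kr_balance(fx$cm)
  nn <- normalize_by_distance(bal)
  expd <- distance_expectation(nn)
  nonzero <- distance_expectation(bal)$E > 0
  expect_lt(max(abs(expd$E[nonzero] - 1)), 1e-9)
})

test_that("balancing + normalization shrinks per-stratum dispersion on
           planted-bias power-law matrices", {
  par <- small_params()
  sc <- simulate_scenario(par)
  bal <- kr_balance(sc$cm)
  expect_gt(cor(bal$bias, sc$truth$bias, use = "complete.obs"), 0.95)
  nn <- normalize_by_distance(bal)
  cv <- function(cm, d_max = 30) {
    M <- as.matrix(cm$mat)
    vapply(1:d_max, function(d) {
      v <- M[cbind(seq_len(nrow(M) - d), seq_len(nrow(M) - d) + d)]
      stats::sd(v) / mean(v)
    }, numeric(1))
  }
  expect_lt(mean(cv(nn)), mean(cv(sc$cm)))
})
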
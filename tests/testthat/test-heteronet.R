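test_that("bi-directional correlations are similarity-weighted association sums", {
  ids_d <- c("d1", "d2"); ids_m <- c("m1", "m2")
  A <- diag(2); dimnames(A) <- list(ids_d, ids_m)
  I2 <- diag(2)
  SD <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids_d, ids_d))
  SM <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(ids_m, ids_m))

  expect_equal(unname(bidirectional_correlations(
    `dimnames<-`(I2, list(ids_d, ids_d)), SM, A)$A_sd), unname(A))
  expect_equal(unname(bidirectional_correlations(
    SD, `dimnames<-`(I2, list(ids_m, ids_m)), A)$A_sm), unname(A))
  expect_equal(unname(bidirectional_correlations(SD, SM, A)$A_sd),
               matrix(c(1, 0.5, 0.5, 1), 2))
  expect_error(bidirectional_correlations(SD, SM, A[, 1, drop = FALSE]),
               "shape")
})

test_that("correlations match the triple-loop oracle", {
  for (seed in 1:4) {
    n_d <- sample(2:15, 1); n_m <- sample(2:15, 1)
    A <- random_assoc(n_d, n_m, seed = seed)
    SD <- random_similarity(n_d, rownames(A), seed = seed)
    SM <- random_similarity(n_m, colnames(A), seed = seed + 50)
    got <- bidirectional_correlations(SD, SM, A)
    want <- oracle_bidirectional(SD, SM, A)
    expect_equal(unname(got$A_sd), want$A_sd, tolerance = 1e-10)
    expect_equal(unname(got$A_sm), want$A_sm, tolerance = 1e-10)
    expect_true(all(got$A_sd >= 0) && all(got$A_sm >= 0))
  }
})

test_that("the heterogeneous adjacency stacks blocks diseases-first", {
  ids_d <- "d1"; ids_m <- "m1"
  SD <- matrix(1, 1, 1, dimnames = list(ids_d, ids_d))
  SM <- matrix(1, 1, 1, dimnames = list(ids_m, ids_m))
  A_sd <- matrix(0.7, 1, 1); A_sm <- matrix(0.3, 1, 1)
  A_all <- assemble_hetero_adjacency(SD, SM, A_sd, A_sm)
  expect_equal(unname(A_all), matrix(c(1, 0.3, 0.7, 1), 2))

  # zero associations: block-diagonal
  ids_d <- c("d1", "d2"); ids_m <- c("m1", "m2")
  SD <- random_similarity(2, ids_d, 1); SM <- random_similarity(2, ids_m, 2)
  Z <- matrix(0, 2, 2)
  A_all <- assemble_hetero_adjacency(SD, SM, Z, Z)
  expect_equal(unname(A_all[1:2, 3:4]), Z)
  expect_equal(unname(A_all[3:4, 1:2]), Z)

  # 4x4 hand layout for the worked 2x2 example
  A <- diag(2); dimnames(A) <- list(ids_d, ids_m)
  SDx <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids_d, ids_d))
  corr <- bidirectional_correlations(SDx, SM, A)
  A_all <- assemble_hetero_adjacency(SDx, SM, corr$A_sd, corr$A_sm)
  expect_equal(unname(A_all[1:2, 3:4]), unname(SDx %*% A))
  expect_equal(unname(A_all[3:4, 1:2]), unname(t(A %*% SM)))
})

test_that("the transition matrix is row-stochastic with the specified block masses", {
  ids_d <- "d"; ids_m <- "m"
  one <- function(ids) matrix(1, 1, 1, dimnames = list(ids, ids))
  A <- matrix(1, 1, 1, dimnames = list(ids_d, ids_m))
  for (phi in c(0.25, 0.5, 0.8)) {
    tr <- transition_matrix(one(ids_d), one(ids_m), A, phi = phi)
    expect_equal(unname(tr$W), matrix(c(1 - phi, phi, phi, 1 - phi), 2),
                 tolerance = 1e-12)
  }

  for (seed in 1:5) {
    n_d <- sample(2:8, 1); n_m <- sample(2:8, 1)
    A <- random_assoc(n_d, n_m, p = 0.3, seed = seed)
    SD <- random_similarity(n_d, rownames(A), seed)
    SM <- random_similarity(n_m, colnames(A), seed + 9)
    tr <- transition_matrix(SD, SM, A, phi = 0.4)
    expect_lt(max(abs(rowSums(tr$W) - 1)), 1e-10)
    expect_true(all(tr$W >= 0))
    # cross rows are supported only on associated partners
    expect_true(all(A[tr$W_dm > 0] == 1))
    expect_true(all(t(A)[tr$W_md > 0] == 1))
    # row masses split phi / 1-phi exactly for associated nodes
    has <- rowSums(A) > 0
    expect_equal(unname(rowSums(tr$W_dm)[has]), rep(0.4, sum(has)),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(tr$W_d)[has]), rep(0.6, sum(has)),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(tr$W_d)[!has]), rep(1, sum(!has)),
                 tolerance = 1e-12)
  }
})

test_that("zero-association networks walk within type only", {
  ids_d <- c("d1", "d2"); ids_m <- c("m1", "m2", "m3")
  SD <- random_similarity(2, ids_d, 1); SM <- random_similarity(3, ids_m, 2)
  A <- matrix(0, 2, 3, dimnames = list(ids_d, ids_m))
  tr <- transition_matrix(SD, SM, A)
  expect_equal(unname(tr$W_dm), matrix(0, 2, 3))
  expect_equal(unname(tr$W_md), matrix(0, 3, 2))
  expect_lt(max(abs(rowSums(tr$W) - 1)), 1e-10)
})

test_that("degenerate rows are rejected or guarded as contracted", {
  ids_d <- c("d1", "d2"); ids_m <- "m1"
  SD <- matrix(c(1, 0, 0, 0), 2, dimnames = list(ids_d, ids_d))
  SM <- matrix(1, 1, 1, dimnames = list(ids_m, ids_m))
  A <- matrix(c(1, 0), 2, 1, dimnames = list(ids_d, ids_m))
  expect_error(transition_matrix(SD, SM, A), "zero similarity row sum.*d2")

  # association present but zero correlation weight: warn, stay stochastic
  SD2 <- random_similarity(2, ids_d, 4)
  corr <- list(A_sd = matrix(c(1, 1), 2, 1), A_sm = matrix(0, 2, 1))
  expect_warning(tr <- transition_matrix(SD2, SM, A, correlations = corr),
                 "zero cross-correlation")
  expect_lt(max(abs(rowSums(tr$W) - 1)), 1e-10)
})
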
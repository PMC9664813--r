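test_that("graph convolution reduces to the attributes on an empty graph", {
  n <- 4
  A_all <- matrix(0, n, n)
  X <- matrix(rnorm(n * n), n)
  H <- gcn_aggregate(A_all, X, n_d = 2, mode = "full", L = 1, d = n,
                     projection = diag(n))
  expect_equal(unname(H), X, tolerance = 1e-12,
               ignore_attr = TRUE)  # A~=0 => A_norm = I
})

test_that("intervention is a no-op on block-diagonal networks and zeroes the effect", {
  set.seed(4)
  n_d <- 3; n_m <- 5; n <- n_d + n_m
  ids <- c(paste0("d", 1:n_d), paste0("m", 1:n_m))
  Sd <- random_similarity(n_d, ids[1:n_d], 1)
  Sm <- random_similarity(n_m, ids[n_d + 1:n_m], 2)
  A_all <- assemble_hetero_adjacency(Sd, Sm, matrix(0, n_d, n_m),
                                     matrix(0, n_d, n_m))
  X <- matrix(runif(n * n), n)
  H_full <- gcn_aggregate(A_all, X, n_d, "full", L = 2, d = 6, seed = 13)
  H_int <- gcn_aggregate(A_all, X, n_d, "intervened", L = 2, d = 6, seed = 13)
  expect_equal(H_full, H_int, tolerance = 1e-12)

  A <- matrix(rbinom(n_d * n_m, 1, 0.5), n_d, n_m,
              dimnames = list(ids[1:n_d], ids[n_d + 1:n_m]))
  y1 <- pair_scores(H_full, A)
  y2 <- pair_scores(H_int, A)
  sc <- select_scores(y1, y2)
  expect_true(all(sc$effect == 0))
})

test_that("node permutation permutes embeddings identically", {
  set.seed(8)
  n_d <- 3; n_m <- 4; n <- n_d + n_m
  ids <- c(paste0("d", 1:n_d), paste0("m", 1:n_m))
  A <- random_assoc(n_d, n_m, seed = 8)
  Sd <- random_similarity(n_d, rownames(A), 3)
  Sm <- random_similarity(n_m, colnames(A), 4)
  corr <- bidirectional_correlations(Sd, Sm, A)
  A_all <- assemble_hetero_adjacency(Sd, Sm, corr$A_sd, corr$A_sm)
  X <- matrix(runif(n * n), n)
  R <- matrix(rnorm(n * 5), n, 5)
  H <- gcn_aggregate(A_all, X, n_d, "full", L = 2, projection = R)
  # permute within types (the disease block must stay leading)
  pd <- sample(n_d); pm <- n_d + sample(n_m)
  perm <- c(pd, pm)
  H_perm <- gcn_aggregate(A_all[perm, perm], X[perm, , drop = FALSE], n_d,
                          "full", L = 2, projection = R)
  expect_equal(unname(H_perm), unname(H[perm, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pair scores follow the similarity-weighted profile formula", {
  ids_d <- c("d1", "d2"); ids_m <- c("m1", "m2")
  A <- diag(2); dimnames(A) <- list(ids_d, ids_m)
  H_same <- matrix(1, 4, 3)          # identical embeddings: Sim == 1
  y <- pair_scores(H_same, A)
  expect_equal(y["d1", "m1"], 0.5, tolerance = 1e-12)

  A1 <- matrix(1, 2, 2, dimnames = dimnames(A))
  expect_true(all(pair_scores(H_same, A1) == 1))
  A0 <- matrix(0, 2, 2, dimnames = dimnames(A))
  expect_true(all(pair_scores(H_same, A0) == 0))
})

test_that("pair scores agree with the double-loop oracle", {
  for (seed in 1:4) {
    n_d <- sample(2:10, 1); n_m <- sample(2:10, 1)
    A <- random_assoc(n_d, n_m, seed = seed + 30)
    set.seed(seed)
    H <- matrix(rnorm((n_d + n_m) * 6), n_d + n_m)
    for (center in c(FALSE, TRUE)) {
      expect_equal(pair_scores(H, A, center = center),
                   oracle_pair_scores(H, A, center = center),
                   tolerance = 1e-10)
    }
    expect_true(all(pair_scores(H, A) >= 0 & pair_scores(H, A) <= 1))
  }
})

test_that("branch selection is exact and threshold-faithful", {
  dn <- list("d1", c("m1", "m2", "m3"))
  y <- matrix(c(0.8, 0.4, 0.6), 1, dimnames = dn)
  ys <- matrix(c(0.5, 0.7, 0.6), 1, dimnames = dn)
  sc <- select_scores(y, ys, m = 0)
  expect_identical(sc$effect, y - ys)
  expect_equal(unname(sc$y_bar), matrix(c(0.8, 0.7, 0.6), 1))
  expect_equal(unname(sc$branch), matrix(c("full", "intervened", "full"), 1))

  # bitwise: every selected entry is one of the two branch entries
  set.seed(2)
  y <- matrix(runif(60), 6); ys <- matrix(runif(60), 6)
  for (m in c(-0.2, 0, 0.15)) {
    sc <- select_scores(y, ys, m = m)
    expect_true(all(sc$y_bar == y | sc$y_bar == ys))
    expect_identical(sc$y_bar[sc$effect >= m], y[sc$effect >= m])
    expect_identical(sc$y_bar[sc$effect < m], ys[sc$effect < m])
  }
  expect_error(select_scores(y, ys[1:3, ]), "shape")
})

test_that("identical seeds give identical fits end to end", {
  ds <- tiny_dataset(seed = 5)
  f1 <- bdhns(ds$A, ds$annotations)
  f2 <- bdhns(ds$A, ds$annotations)
  expect_identical(f1$scores$y_bar, f2$scores$y_bar)
  expect_identical(f1$embeddings$H, f2$embeddings$H)
  # a different projection seed changes the embeddings
  f3 <- bdhns(ds$A, ds$annotations, bdhns_control(projection_seed = 99L))
  expect_false(identical(f1$embeddings$H, f3$embeddings$H))
})
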
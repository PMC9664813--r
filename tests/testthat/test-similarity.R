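test_that("GIP kernel matches its definition and the brute-force oracle", {
  A <- diag(2)
  dimnames(A) <- list(c("d1", "d2"), c("m1", "m2"))
  GM <- gip_similarity(A, "microbe")
  expect_equal(diag(GM), c(m1 = 1, m2 = 1))
  expect_equal(GM[1, 2], exp(-2), tolerance = 1e-12)

  # identical profiles are maximally similar whatever the bandwidth
  A2 <- cbind(A, m3 = A[, 1])
  expect_equal(gip_similarity(A2, "microbe", bandwidth_scale = 3)["m1", "m3"], 1)

  A0 <- matrix(0, 2, 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
  expect_error(gip_similarity(A0, "disease"), "zero bandwidth")

  for (seed in 1:4) {
    A <- random_assoc(sample(3:20, 1), sample(3:20, 1), seed = seed)
    for (axis in c("microbe", "disease")) {
      S <- gip_similarity(A, axis)
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_true(all(S > 0 & S <= 1))
      expect_equal(unname(S), oracle_gip(A, axis), tolerance = 1e-10)
    }
  }
})

test_that("min-max normalisation maps endpoints and handles degeneracy by mode", {
  M <- matrix(c(2, 6, 4, 8), 2)
  N <- minmax_normalize(M)
  expect_equal(min(N), 0)
  expect_equal(max(N), 1)
  expect_equal(N[1, 2], 1 / 3, tolerance = 1e-12)
  C <- matrix(5, 2, 2)
  expect_equal(minmax_normalize(C, "zeros"), matrix(0, 2, 2))
  expect_equal(minmax_normalize(C, "ones"), matrix(1, 2, 2))
  expect_error(minmax_normalize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("microbial functional similarity counts shared organ-disease pairs", {
  ids <- c("m1", "m2", "m3")
  none <- mda_annotations(organs = data.frame(
    microbe = c("m1", "m2"), organ = c("gut", "skin"),
    disease = c("d1", "d1"), stringsAsFactors = FALSE))
  expect_equal(unname(microbe_functional_similarity(none, c("m1", "m2"))),
               matrix(0, 2, 2))

  one <- mda_annotations(organs = data.frame(
    microbe = c("m1", "m2"), organ = "gut", disease = "d1",
    stringsAsFactors = FALSE))
  FM <- microbe_functional_similarity(one, c("m1", "m2"))
  expect_equal(FM["m1", "m2"], 1)

  ann <- mda_annotations(organs = data.frame(
    microbe = c("m1", "m2", "m1", "m2", "m3"),
    organ = "gut",
    disease = c("d1", "d1", "d2", "d2", "d1"),
    stringsAsFactors = FALSE))
  FM <- microbe_functional_similarity(ann, ids)
  expect_equal(FM["m1", "m2"], 1)          # raw count 2 -> max
  expect_equal(FM["m1", "m3"], 0.5)        # raw count 1
  expect_equal(FM, t(FM))
})

test_that("microbe similarity fusion follows the zero-functional branch", {
  ids <- c("m1", "m2")
  GM <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(ids, ids))
  FM0 <- matrix(0, 2, 2, dimnames = list(ids, ids))
  expect_identical(fuse_microbe_similarity(GM, FM0), GM)
  FM <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(ids, ids))
  expect_equal(fuse_microbe_similarity(GM, FM)[1, 2], 0.5)
  expect_error(fuse_microbe_similarity(GM, FM0[, 2:1]), "labels")
})

test_that("semantic similarity reproduces hand-computed DAG values", {
  chain <- data.frame(child = c("D", "P"), parent = c("P", "G"))
  dv <- disease_semantic_values(chain, c("D", "P", "G"))
  expect_equal(dv[["D"]], 1.75, tolerance = 1e-12)
  expect_equal(dv[["G"]], 1)

  sibs <- data.frame(child = c("X", "Y"), parent = "P")
  DSS <- disease_semantic_similarity(sibs, c("X", "Y"))
  expect_equal(diag(DSS), c(X = 1, Y = 1))
  expect_equal(DSS["X", "Y"], 1 / 3, tolerance = 1e-12)

  # disease missing from the DAG gets an identity-like row
  DSS <- disease_semantic_similarity(sibs, c("X", "Y", "Z"))
  expect_equal(unname(DSS["Z", ]), c(0, 0, 1))
})

test_that("semantic similarity matches the relation-expansion oracle on random DAGs", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    n <- sample(5:30, 1)
    nodes <- paste0("n", seq_len(n))
    # random DAG: edges only from later to earlier nodes (guaranteed acyclic)
    edges <- do.call(rbind, lapply(2:n, function(i) {
      k <- sample(0:min(2, i - 1), 1)
      if (k == 0) return(NULL)
      data.frame(child = nodes[i], parent = nodes[sample(i - 1, k)],
                 stringsAsFactors = FALSE)
    }))
    ids <- sample(nodes, sample(3:n, 1))
    DSS <- disease_semantic_similarity(edges, ids, delta = 0.5)
    expect_equal(DSS, oracle_semantic(edges, ids, delta = 0.5),
                 tolerance = 1e-10)
  }
})

test_that("functional similarity follows the gene-set/LLS definition", {
  ids <- c("dA", "dB")
  DF <- disease_functional_similarity(list(dA = c("g1", "g2"),
                                           dB = c("g1", "g2")),
                                      NULL, ids)
  expect_equal(DF["dA", "dB"], 1)

  DF <- disease_functional_similarity(list(dA = "g1", dB = "g2"), NULL, ids)
  expect_equal(DF["dA", "dB"], 0)

  edges <- data.frame(gene1 = c("a", "c"), gene2 = c("b", "d"), lls = c(2, 4))
  DF <- disease_functional_similarity(list(dA = "c", dB = "d"), edges, ids)
  expect_equal(DF["dA", "dB"], 1)           # normalised LLS 1 both ways
  DF <- disease_functional_similarity(list(dA = "a", dB = "b"), edges, ids)
  expect_equal(DF["dA", "dB"], 0)           # normalised LLS 0
  # single-edge network: degenerate normalisation keeps the evidence
  one <- data.frame(gene1 = "a", gene2 = "b", lls = 3)
  DF <- disease_functional_similarity(list(dA = "a", dB = "b"), one, ids)
  expect_equal(DF["dA", "dB"], 1)
  # empty gene set: identity-like row
  DF <- disease_functional_similarity(list(dA = "a"), one, c("dA", "dC"))
  expect_equal(unname(DF["dC", ]), c(0, 1))
})

test_that("symptom similarity is cosine with zero-profile fallback", {
  S <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"), c("s1", "s2", "s3")))
  TD <- symptom_similarity(S)
  expect_equal(TD["d1", "d2"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(TD["d3", "d1"], 0)
  expect_equal(TD["d3", "d3"], 1)
  V <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("s1", "s2")))
  expect_equal(symptom_similarity(V)["x", "y"], 0)
  W <- rbind(a = c(2, 4), b = c(1, 2))
  expect_equal(symptom_similarity(W)["a", "b"], 1)
})

test_that("disease similarity fusion is the four-channel mean", {
  ids <- c("d1", "d2")
  mk <- function(v) matrix(c(1, v, v, 1), 2, dimnames = list(ids, ids))
  expect_equal(fuse_disease_similarity(mk(0.3), mk(0.3), mk(0.3), mk(0.3)),
               mk(0.3))
  SD <- fuse_disease_similarity(mk(1), mk(1 / 3), mk(0), mk(1))
  expect_equal(SD[1, 2], 7 / 12, tolerance = 1e-12)
  expect_equal(diag(SD), c(d1 = 1, d2 = 1))
  expect_error(fuse_disease_similarity(mk(1), mk(1), mk(1), mk(1)[2:1, ]),
               "labels")
})

test_that("all similarity channels are symmetric, bounded and permutation-equivariant", {
  ds <- tiny_dataset(seed = 3)
  ctrl <- bdhns_control()
  fit <- bdhns(ds$A, ds$annotations, ctrl)
  for (nm in names(fit$similarities)) {
    S <- fit$similarities[[nm]]
    expect_lt(max(abs(S - t(S))), 1e-12)
    expect_true(all(S >= 0 & S <= 1 + 1e-12), label = paste(nm, "in [0,1]"))
  }
  expect_true(all(fit$similarities$GM > 0))
  expect_true(all(fit$similarities$GD > 0))

  # relabeling diseases permutes DSS and DF rows/columns consistently
  ids <- rownames(ds$A)
  perm <- rev(ids)
  DSS1 <- disease_semantic_similarity(ds$annotations$dag_edges, ids)
  DSS2 <- disease_semantic_similarity(ds$annotations$dag_edges, perm)
  expect_equal(DSS2[ids, ids], DSS1, tolerance = 1e-12)
  DF1 <- disease_functional_similarity(ds$annotations$gene_sets,
                                       ds$annotations$gene_edges, ids)
  DF2 <- disease_functional_similarity(ds$annotations$gene_sets,
                                       ds$annotations$gene_edges, perm)
  expect_equal(DF2[ids, ids], DF1, tolerance = 1e-12)
})
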
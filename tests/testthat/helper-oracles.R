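# Brute-force oracles, kept deliberately naive and independent of the
# vectorised implementation paths they check.

oracle_gip <- function(A, axis, scale = 1) {
  X <- if (axis == "microbe") t(A) else A
  n <- nrow(X)
  r <- scale / mean(apply(X, 1, function(x) sum(x^2)))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- exp(-r * sum((X[i, ] - X[j, ])^2))
  S
}

oracle_bidirectional <- function(SD, SM, A) {
  n_d <- nrow(SD); n_m <- nrow(SM)
  A_sd <- matrix(0, n_d, n_m); A_sm <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) for (j in seq_len(n_m)) {
    for (k in seq_len(n_d)) A_sd[i, j] <- A_sd[i, j] + SD[i, k] * A[k, j]
    for (k in seq_len(n_m)) A_sm[i, j] <- A_sm[i, j] + A[i, k] * SM[k, j]
  }
  list(A_sd = A_sd, A_sm = A_sm)
}

# cosine clamped to [0,1]; zero vectors similar only to themselves
oracle_cos01 <- function(u, v, self = FALSE) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(if (self) 1 else 0)
  min(1, max(0, sum(u * v) / (nu * nv)))
}

oracle_pair_scores <- function(H, A, center = FALSE) {
  n_d <- nrow(A); n_m <- ncol(A)
  H_d <- H[seq_len(n_d), , drop = FALSE]
  H_m <- H[n_d + seq_len(n_m), , drop = FALSE]
  if (center) {
    H_d <- sweep(H_d, 2, colMeans(H_d))
    H_m <- sweep(H_m, 2, colMeans(H_m))
  }
  Y <- matrix(0, n_d, n_m)
  for (j in seq_len(n_d)) for (i in seq_len(n_m)) {
    num <- 0; den <- 0
    for (k in seq_len(n_m)) {
      s <- oracle_cos01(H_m[i, ], H_m[k, ], self = (i == k))
      num <- num + s * A[j, k]; den <- den + s
    }
    for (k in seq_len(n_d)) {
      s <- oracle_cos01(H_d[j, ], H_d[k, ], self = (j == k))
      num <- num + s * A[k, i]; den <- den + s
    }
    Y[j, i] <- if (den > 0) num / den else 0
  }
  dimnames(Y) <- dimnames(A)
  Y
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# ancestor-set / contribution oracle by explicit relation expansion (no graph
# library): repeatedly follow child->parent edges from each disease
oracle_semantic <- function(dag_edges, disease_ids, delta = 0.5) {
  n_nodes <- length(unique(c(dag_edges$child, dag_edges$parent)))
  contrib_for <- function(d) {
    contrib <- stats::setNames(1, d)
    # fixed-point sweep: enough passes to propagate along any ancestor path
    for (pass in seq_len(n_nodes)) {
      for (e in seq_len(nrow(dag_edges))) {
        child <- dag_edges$child[e]; parent <- dag_edges$parent[e]
        if (child %in% names(contrib)) {
          cand <- delta * contrib[[child]]
          if (!(parent %in% names(contrib)) || contrib[[parent]] < cand)
            contrib[parent] <- cand
        }
      }
    }
    contrib
  }
  in_dag <- unique(c(dag_edges$child, dag_edges$parent))
  out <- matrix(0, length(disease_ids), length(disease_ids),
                dimnames = list(disease_ids, disease_ids))
  contribs <- lapply(disease_ids, function(d)
    if (d %in% in_dag) contrib_for(d) else stats::setNames(1, d))
  names(contribs) <- disease_ids
  dv <- vapply(contribs, sum, 0)
  for (a in seq_along(disease_ids)) for (b in seq_along(disease_ids)) {
    if (!(disease_ids[a] %in% in_dag) || !(disease_ids[b] %in% in_dag)) {
      out[a, b] <- as.numeric(a == b)
      next
    }
    ca <- contribs[[a]]; cb <- contribs[[b]]
    shared <- intersect(names(ca), names(cb))
    out[a, b] <- if (length(shared))
      sum(ca[shared] + cb[shared]) / (dv[a] + dv[b]) else 0
  }
  diag(out) <- 1
  out
}

# random labelled association matrix with at least one association per axis
random_assoc <- function(n_d, n_m, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(rbinom(n_d * n_m, 1, p), n_d, n_m,
                dimnames = list(paste0("d", seq_len(n_d)),
                                paste0("m", seq_len(n_m))))
    if (any(A == 1)) return(A)
  }
}

random_similarity <- function(n, ids, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(n * n, 0.05, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

tiny_dataset <- function(seed = 1) {
  generate_mda_dataset(mda_params(n_d = 6, n_m = 12, blocks = 2, p_in = 0.6,
                                  p_out = 0.05, genes_per_pool = 5,
                                  genes_per_disease = 3, symptom_dims = 6,
                                  seed = seed))
}
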
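#' Graph-convolution neighbour aggregation
#'
#' Parameter-free propagation over the symmetrically normalised adjacency
#' with self-loops, `A_norm = D^{-1/2} (A + I) D^{-1/2}`, applied `L` times
#' to the node attribute matrix and followed by a fixed, seeded Gaussian
#' random projection to `d` dimensions: `H = A_norm^L X R`. Two modes share
#' the same projection: `"full"` aggregates every neighbour in the
#' heterogeneous network; `"intervened"` zeroes the disease-microbe cross
#' blocks first, so only same-type neighbours are aggregated (the causal
#' intervention that replaces the cross-type neighbourhood by the empty set).
#' Self-loops keep isolated nodes well-defined after intervention.
#'
#' @param A_all heterogeneous adjacency from [assemble_hetero_adjacency()].
#' @param X node attribute matrix, one row per node (default choice upstream
#'   is the restart-walk profile).
#' @param n_d number of disease nodes (leading block).
#' @param mode `"full"` or `"intervened"`.
#' @param L number of propagation layers, default 2.
#' @param d embedding dimension, default 64.
#' @param seed seed for the random projection, default 13.
#' @param projection optional explicit projection matrix (ncol(X) x d),
#'   overriding the seeded draw; pass the same matrix to both modes.
#' @return matrix `H` (one embedding row per node) with attribute
#'   `"projection"` carrying the projection used.
#' @export
gcn_aggregate <- function(A_all, X, n_d, mode = c("full", "intervened"),
                          L = 2L, d = 64L, seed = 13L, projection = NULL) {
  mode <- match.arg(mode)
  n <- nrow(A_all)
  stopifnot(is.matrix(A_all), ncol(A_all) == n, is.matrix(X), nrow(X) == n,
            n_d >= 1L, n_d < n, L >= 1L, d >= 1L)
  At <- A_all
  if (mode == "intervened") {
    At[seq_len(n_d), (n_d + 1L):n] <- 0
    At[(n_d + 1L):n, seq_len(n_d)] <- 0
  }
  At <- At + diag(1, n)
  deg <- rowSums(At)
  inv_sqrt <- 1 / sqrt(deg)   # positive: self-loops guarantee deg >= 1
  A_norm <- At * outer(inv_sqrt, inv_sqrt)
  if (is.null(projection)) {
    projection <- gcn_projection(ncol(X), d, seed)
  } else if (nrow(projection) != ncol(X)) {
    stop("projection must have one row per attribute column")
  }
  H <- X %*% projection
  for (k in seq_len(L)) H <- A_norm %*% H
  rownames(H) <- rownames(A_all)
  attr(H, "projection") <- projection
  H
}

# Seeded Gaussian projection, scaled so squared row norms are preserved in
# expectation; drawn under a restored RNG state.
gcn_projection <- function(p, d, seed) {
  with_seed(seed, matrix(stats::rnorm(p * d), p, d) / sqrt(d))
}

#' Pairwise association probabilities from node embeddings
#'
#' Scores a (disease, microbe) pair by how strongly the training associations
#' of similar nodes support it: the cosine-similarity-weighted count of
#' associations between the microbe's similar microbes and the disease, plus
#' the disease's similar diseases and the microbe, normalised by the total
#' similarity mass. Cosine similarity is clamped to `[0, 1]`, so scores lie
#' in `[0, 1]`; a zero denominator yields 0.
#'
#' @param H embedding matrix, disease rows first.
#' @param A_train binary training association matrix (n_d x n_m).
#' @param center centre embedding columns before the cosine (clamped Pearson
#'   correlation). Off by default; the fitted model turns it on because
#'   propagation over the dense similarity graph drives plain cosines of the
#'   non-negative embeddings towards 1 for every pair, which collapses the
#'   similarity weighting into a degree count.
#' @return score matrix, diseases x microbes, same dimnames as `A_train`.
#' @export
pair_scores <- function(H, A_train, center = FALSE) {
  n_d <- nrow(A_train); n_m <- ncol(A_train)
  if (nrow(H) != n_d + n_m)
    stop("H must have one row per disease followed by one per microbe")
  H_d <- H[seq_len(n_d), , drop = FALSE]
  H_m <- H[n_d + seq_len(n_m), , drop = FALSE]
  if (center) {
    H_d <- sweep(H_d, 2L, colMeans(H_d))
    H_m <- sweep(H_m, 2L, colMeans(H_m))
  }
  S_m <- clamped_cosine(H_m)          # n_m x n_m
  S_d <- clamped_cosine(H_d)          # n_d x n_d
  # numerator(i=microbe, j=disease): sum_k S_m(i,k) A(j,k) + sum_k S_d(j,k) A(k,i)
  N_md <- S_m %*% t(A_train) + t(S_d %*% A_train)   # n_m x n_d
  denom <- outer(rowSums(S_m), rowSums(S_d), "+")   # n_m x n_d
  Y_md <- ifelse(denom > 0, N_md / denom, 0)
  Y <- t(Y_md)
  dimnames(Y) <- dimnames(A_train)
  Y
}

#' Select between full and intervened aggregation scores per pair
#'
#' The causal effect factor is the elementwise difference
#' `e = y_hat - y_hat_s` between the full-neighbourhood score and the
#' same-type-only score. Pairs with `e >= m` keep the full score; others take
#' the intervened score (the tie `e == m` resolves to the full branch).
#'
#' @param y_hat,y_hat_s conforming score matrices.
#' @param m selection threshold, default 0.
#' @return list of class `bdhns_scores` with `y_hat`, `y_hat_s`, `effect`,
#'   `branch` (`"full"`/`"intervened"`), `threshold` and the selected `y_bar`.
#' @export
select_scores <- function(y_hat, y_hat_s, m = 0) {
  if (!identical(dim(y_hat), dim(y_hat_s)))
    stop("y_hat and y_hat_s must have identical shape")
  effect <- y_hat - y_hat_s
  take_full <- effect >= m
  y_bar <- ifelse(take_full, y_hat, y_hat_s)
  branch <- ifelse(take_full, "full", "intervened")
  dim(branch) <- dim(y_hat)
  dimnames(y_bar) <- dimnames(effect) <- dimnames(branch) <- dimnames(y_hat)
  structure(list(y_hat = y_hat, y_hat_s = y_hat_s, effect = effect,
                 branch = branch, threshold = m, y_bar = y_bar),
            class = "bdhns_scores")
}

#' @export
print.bdhns_scores <- function(x, ...) {
  cat(sprintf("Selected association scores: %d diseases x %d microbes\n",
              nrow(x$y_bar), ncol(x$y_bar)))
  cat(sprintf("  threshold m = %g; full branch chosen for %.1f%% of pairs\n",
              x$threshold, 100 * mean(x$branch == "full")))
  invisible(x)
}
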
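#' Bi-directional correlation matrices between diseases and microbes
#'
#' Weights each association edge by similarity topology on the opposite side:
#' the disease-to-microbe correlation sums similarity-weighted associations
#' over diseases, `A'_SD = SD %*% A`, and the microbe-to-disease correlation
#' over microbes, `A'_SM = A %*% SM`. Both are diseases x microbes and
#' non-negative.
#'
#' @param SD disease similarity matrix (n_d x n_d).
#' @param SM microbe similarity matrix (n_m x n_m).
#' @param A binary association matrix (n_d x n_m).
#' @return list with `A_sd` and `A_sm`.
#' @export
bidirectional_correlations <- function(SD, SM, A) {
  if (nrow(SD) != ncol(SD) || nrow(SM) != ncol(SM))
    stop("SD and SM must be square")
  if (nrow(A) != nrow(SD) || ncol(A) != nrow(SM))
    stop("shape mismatch: A must be nrow(SD) x nrow(SM)")
  list(A_sd = SD %*% A, A_sm = A %*% SM)
}

#' Assemble the heterogeneous network adjacency
#'
#' Stacks the intra-type similarity blocks and the direction-specific cross
#' blocks into the (n_d + n_m) square adjacency, diseases first:
#' top-left `SD`, top-right `A'_SD`, bottom-left `t(A'_SM)`, bottom-right
#' `SM`. Both cross matrices are diseases x microbes, so the microbe-row
#' block stores the transpose.
#'
#' @param SD,SM intra-type similarity matrices.
#' @param A_sd,A_sm cross-correlation matrices from
#'   [bidirectional_correlations()].
#' @return square matrix of size n_d + n_m with combined labels.
#' @export
assemble_hetero_adjacency <- function(SD, SM, A_sd, A_sm) {
  n_d <- nrow(SD); n_m <- nrow(SM)
  if (!all(dim(A_sd) == c(n_d, n_m)) || !all(dim(A_sm) == c(n_d, n_m)))
    stop("cross blocks must be n_d x n_m")
  A_all <- rbind(cbind(SD, A_sd), cbind(t(A_sm), SM))
  labs <- c(rownames(SD), rownames(SM))
  dimnames(A_all) <- list(labs, labs)
  A_all
}

#' Transition probability matrix of the bi-directional heterogeneous network
#'
#' Builds the row-stochastic block matrix `W` driving the random walk. For a
#' disease `i` with at least one association, a walker jumps across types
#' with probability `phi`, distributed over its associated microbes in
#' proportion to the microbe-side correlation `A'_SM(i, .)`, and stays in the
#' disease network with probability `1 - phi`, distributed by row-normalised
#' `SD`; a disease with no associations walks entirely within its own network.
#' Microbe rows are built symmetrically from `A'_SD`. Every row sums to 1.
#'
#' If a node has associations but their correlation weights sum to zero, its
#' cross row is zeroed with a warning and its intra-type row falls back to
#' the no-association branch so the row remains stochastic.
#'
#' @param SD,SM intra-type similarity matrices with positive row sums.
#' @param A binary association matrix.
#' @param phi jump probability in (0, 1), default 0.5.
#' @param correlations optional precomputed [bidirectional_correlations()]
#'   result.
#' @return list of class `bdhns_transition` with `W`, the four blocks and
#'   `phi`.
#' @export
transition_matrix <- function(SD, SM, A, phi = 0.5, correlations = NULL) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
    stop("phi must lie in (0, 1)")
  n_d <- nrow(SD); n_m <- nrow(SM)
  rs_d <- rowSums(SD); rs_m <- rowSums(SM)
  if (any(rs_d <= 0))
    stop("zero similarity row sum for disease '",
         rownames(SD)[which(rs_d <= 0)[1L]], "'")
  if (any(rs_m <= 0))
    stop("zero similarity row sum for microbe '",
         rownames(SM)[which(rs_m <= 0)[1L]], "'")
  if (is.null(correlations)) correlations <- bidirectional_correlations(SD, SM, A)
  A_sd <- correlations$A_sd; A_sm <- correlations$A_sm

  W_d <- matrix(0, n_d, n_d, dimnames = dimnames(SD))
  W_dm <- matrix(0, n_d, n_m, dimnames = list(rownames(SD), rownames(SM)))
  for (i in seq_len(n_d)) {
    cross_w <- A[i, ] * A_sm[i, ]
    denom <- sum(cross_w)
    if (sum(A[i, ]) > 0 && denom > 0) {
      W_dm[i, ] <- phi * cross_w / denom
      W_d[i, ] <- (1 - phi) * SD[i, ] / rs_d[i]
    } else {
      if (sum(A[i, ]) > 0)
        warning("disease '", rownames(SD)[i],
                "' has associations but zero cross-correlation weight; ",
                "walking within the disease network only")
      W_d[i, ] <- SD[i, ] / rs_d[i]
    }
  }

  W_m <- matrix(0, n_m, n_m, dimnames = dimnames(SM))
  W_md <- matrix(0, n_m, n_d, dimnames = list(rownames(SM), rownames(SD)))
  for (i in seq_len(n_m)) {
    cross_w <- A[, i] * A_sd[, i]
    denom <- sum(cross_w)
    if (sum(A[, i]) > 0 && denom > 0) {
      W_md[i, ] <- phi * cross_w / denom
      W_m[i, ] <- (1 - phi) * SM[i, ] / rs_m[i]
    } else {
      if (sum(A[, i]) > 0)
        warning("microbe '", rownames(SM)[i],
                "' has associations but zero cross-correlation weight; ",
                "walking within the microbe network only")
      W_m[i, ] <- SM[i, ] / rs_m[i]
    }
  }

  W <- rbind(cbind(W_d, W_dm), cbind(W_md, W_m))
  structure(list(W = W, W_d = W_d, W_dm = W_dm, W_md = W_md, W_m = W_m,
                 phi = phi, n_d = n_d, n_m = n_m),
            class = "bdhns_transition")
}

#' @export
print.bdhns_transition <- function(x, ...) {
  cat(sprintf("Bi-directional transition matrix: %d diseases + %d microbes, phi = %g\n",
              x$n_d, x$n_m, x$phi))
  dev <- max(abs(rowSums(x$W) - 1))
  cat(sprintf("  max |row sum - 1| = %.2e\n", dev))
  invisible(x)
}
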
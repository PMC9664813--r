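#' Enhanced random walk with restart on the heterogeneous network
#'
#' Iterates `P(t+1) = (1 - r) * t(W) %*% P(t) + r * P(0)` for a fixed number
#' of steps. `W` is row-stochastic (rows are source nodes), while columns of
#' `P` are per-seed probability distributions, so the iteration uses the
#' transpose; this conserves column mass exactly. The default seed matrix
#' `P0 = I` starts one walker on every node, giving a per-node neighbour
#' topology profile.
#'
#' @param W row-stochastic transition matrix, or a `bdhns_transition`.
#' @param r restart probability in (0, 1], default 0.1.
#' @param t number of steps, default 20.
#' @param P0 seed matrix with non-negative columns summing to 1; default
#'   identity.
#' @param early_stop_tol optional tolerance; when the max-abs change of an
#'   iteration falls below it the walk stops early. Off (`NULL`) by default
#'   for reproducibility of the fixed-step profile.
#' @return list of class `bdhns_walk` with `P`, `r`, `steps` (performed),
#'   `residual` (max-abs change at the last step) and `converged`.
#' @export
enhanced_rwr <- function(W, r = 0.1, t = 20L, P0 = NULL,
                         early_stop_tol = NULL) {
  if (inherits(W, "bdhns_transition")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("restart probability r must lie in (0, 1]")
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != round(t))
    stop("step count t must be a non-negative integer")
  n <- nrow(W)
  if (is.null(P0)) {
    P0 <- diag(1, n)
    dimnames(P0) <- dimnames(W)
  }
  if (!all(dim(P0) == c(n, ncol(P0))) || nrow(P0) != n)
    stop("P0 must have one row per network node")
  if (any(P0 < 0) || any(abs(colSums(P0) - 1) > 1e-8))
    stop("P0 columns must be non-negative distributions summing to 1")

  Wt <- t(W)
  P <- P0
  residual <- if (t == 0L) 0 else NA_real_
  steps <- 0L
  for (k in seq_len(t)) {
    P_new <- (1 - r) * (Wt %*% P) + r * P0
    residual <- max(abs(P_new - P))
    P <- P_new
    steps <- k
    if (!is.null(early_stop_tol) && residual < early_stop_tol) break
  }
  structure(list(P = P, r = r, steps = steps, residual = residual,
                 converged = is.null(early_stop_tol) ||
                   (is.finite(residual) && residual < early_stop_tol)),
            class = "bdhns_walk")
}

#' Closed-form fixed point of the restart walk
#'
#' Solves `(I - (1 - r) * t(W)) P = r * P0` directly; the system is
#' non-singular because the spectral radius of `(1 - r) * t(W)` is below 1
#' for a (sub)stochastic `W` and `r > 0`. Serves as the analytic limit of
#' [enhanced_rwr()] as the step count grows.
#'
#' @inheritParams enhanced_rwr
#' @return matrix of stationary seed profiles, one column per seed.
#' @export
rwr_closed_form <- function(W, r = 0.1, P0 = NULL) {
  if (inherits(W, "bdhns_transition")) W <- W$W
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1)
    stop("restart probability r must lie in (0, 1) for the closed form")
  n <- nrow(W)
  if (is.null(P0)) {
    P0 <- diag(1, n)
    dimnames(P0) <- dimnames(W)
  }
  M <- diag(1, n) - (1 - r) * t(W)
  P <- tryCatch(solve(M, r * P0),
                error = function(e) stop("restart-walk system is singular: ",
                                         conditionMessage(e)))
  dimnames(P) <- dimnames(P0)
  P
}

#' @export
print.bdhns_walk <- function(x, ...) {
  cat(sprintf("Restart walk profile: %d nodes, r = %g, %d step(s), residual = %.3e\n",
              nrow(x$P), x$r, x$steps, x$residual))
  invisible(x)
}
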
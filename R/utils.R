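# Internal helpers shared across modules.

# Evaluate `code` under a temporary seed, restoring the caller's RNG state so
# model fits and generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce anything association-like (labeled binary matrix, or a two-column
# data.frame of (disease, microbe) pairs) to a validated association matrix.
as_association_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("association data.frame needs >= 2 columns (disease, microbe)")
    return(pairs_to_matrix(as.character(x[[1L]]), as.character(x[[2L]])))
  }
  if (!is.matrix(x)) stop("associations must be a matrix or a two-column data.frame")
  validate_association_matrix(x)
  x
}

validate_association_matrix <- function(A) {
  if (nrow(A) < 1L || ncol(A) < 1L) stop("association matrix must be at least 1x1")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("association matrix must carry disease row names and microbe column names")
  if (anyDuplicated(rownames(A))) stop("duplicate disease labels in association matrix")
  if (anyDuplicated(colnames(A))) stop("duplicate microbe labels in association matrix")
  if (!all(A %in% c(0, 1))) stop("association matrix entries must be 0 or 1")
  invisible(A)
}

# Build the binary disease x microbe matrix from de-duplicated pairs,
# labelling axes in first-appearance order.
pairs_to_matrix <- function(diseases, microbes) {
  keep <- !duplicated(paste(diseases, microbes, sep = "\r"))
  diseases <- diseases[keep]
  microbes <- microbes[keep]
  d_ids <- unique(diseases)
  m_ids <- unique(microbes)
  A <- matrix(0, nrow = length(d_ids), ncol = length(m_ids),
              dimnames = list(d_ids, m_ids))
  A[cbind(match(diseases, d_ids), match(microbes, m_ids))] <- 1
  A
}

check_square_labels <- function(M, ids, what) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("%s must be a square matrix", what))
  if (!is.null(ids) && (nrow(M) != length(ids) ||
      !identical(rownames(M), ids) || !identical(colnames(M), ids)))
    stop(sprintf("%s labels do not match the expected entity ids", what))
  invisible(M)
}

# Row-wise clamped cosine similarity of a matrix of vectors; zero vectors get
# similarity 0 off-diagonal and 1 on the diagonal.
clamped_cosine <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  G <- tcrossprod(X)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, G / denom, 0)
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 1
  S
}
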
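#' Rank-based ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic with mid-ranks for ties: the probability
#' that a uniformly chosen positive outranks a uniformly chosen negative,
#' ties counting one half. ROC points are the cumulative true/false positive
#' rates over decreasing score thresholds (one step per distinct score),
#' anchored at (0, 0) and (1, 1).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @return list with `roc` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc requires both positive and negative examples")
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- cumsum(l)[last_of_tie] / n_pos
  fpr <- cumsum(1L - l)[last_of_tie] / n_neg
  list(roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)), auc = auc)
}

#' Leave-one-out cross-validation of the association predictor
#'
#' Masks each known association in turn, refits the association-dependent
#' stages (GIP kernels, fused similarities, cross correlations, transition
#' matrix, walk, embeddings, scores) with the masked matrix, and records the
#' selected score of the held-out pair alongside the scores of every pair
#' unobserved in the full data. The association-independent similarity
#' channels (functional, semantic, gene-set, symptom) are computed once and
#' cached across folds, since they never read the association matrix.
#'
#' AUC pools the within-fold comparisons: over all folds, the fraction of
#' (held-out positive, unobserved negative) score pairs won by the positive,
#' ties counting one half. A masked positive is never scored as a negative.
#'
#' @param associations association matrix or pair data.frame (see [bdhns()]).
#' @param annotations an [mda_annotations] bundle or `NULL`.
#' @param control a [bdhns_control()] list.
#' @param progress print a dot every 25 folds.
#' @return object of class `bdhns_cv` with `protocol = "loocv"`, per-fold
#'   records, pooled `(score, label)` vectors, `roc` points and `auc`.
#' @export
bdhns_loocv <- function(associations, annotations = NULL,
                        control = bdhns_control(), progress = FALSE) {
  A_full <- as_association_matrix(associations)
  pos <- which(A_full == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("leave-one-out needs at least 2 known associations")
  static <- static_similarities(annotations, rownames(A_full),
                                colnames(A_full), control)
  neg_idx <- which(A_full == 0)

  folds <- vector("list", nrow(pos))
  wins <- 0; total <- 0
  pooled_scores <- c(); pooled_labels <- c()
  for (f in seq_len(nrow(pos))) {
    A_train <- A_full
    A_train[pos[f, 1L], pos[f, 2L]] <- 0
    fit <- fit_bdhns_core(A_train, static, control)
    y <- fit$scores$y_bar
    s_pos <- y[pos[f, 1L], pos[f, 2L]]
    s_neg <- y[neg_idx]
    wins <- wins + sum(s_neg < s_pos) + 0.5 * sum(s_neg == s_pos)
    total <- total + length(s_neg)
    folds[[f]] <- list(disease = rownames(A_full)[pos[f, 1L]],
                       microbe = colnames(A_full)[pos[f, 2L]],
                       score = s_pos)
    pooled_scores <- c(pooled_scores, s_pos)
    pooled_labels <- c(pooled_labels, 1L)
    if (f == 1L) {  # negatives barely move between folds; pool one snapshot
      pooled_scores <- c(pooled_scores, s_neg)
      pooled_labels <- c(pooled_labels, rep(0L, length(s_neg)))
    }
    if (progress && f %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  roc <- roc_auc(pooled_scores, pooled_labels)$roc
  structure(list(protocol = "loocv", folds = folds,
                 scores = pooled_scores, labels = pooled_labels,
                 roc = roc, auc = wins / total, seed = NA_integer_,
                 n_pos = nrow(pos), n_neg = length(neg_idx)),
            class = "bdhns_cv")
}

#' Five-fold cross-validation of the association predictor
#'
#' Known associations (positives) are shuffled by `seed` into `folds` groups.
#' In each round, one group is masked out of the association matrix and held
#' for testing while the remaining groups train. From the unobserved pairs,
#' as many negatives as there are training positives are sampled (without
#' replacement) to be excluded from testing, mirroring a balanced training
#' draw; all remaining unobserved pairs are the test negatives. Each round's
#' AUC comes from [roc_auc()] on test positives vs test negatives; the
#' summary AUC is the mean over rounds.
#'
#' @inheritParams bdhns_loocv
#' @param seed integer seed driving the fold split and negative sampling.
#' @param folds number of groups, default 5.
#' @return object of class `bdhns_cv` with `protocol = "fivefold"`, per-fold
#'   AUCs, pooled scores/labels, `roc` and mean `auc`.
#' @export
bdhns_cv <- function(associations, annotations = NULL,
                     control = bdhns_control(), seed = 1L, folds = 5L) {
  A_full <- as_association_matrix(associations)
  pos <- which(A_full == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < folds) stop("need at least ", folds, " known associations")
  static <- static_similarities(annotations, rownames(A_full),
                                colnames(A_full), control)
  neg_lin <- which(A_full == 0)

  assignment <- with_seed(seed, sample(rep_len(seq_len(folds), n_pos)))
  fold_records <- vector("list", folds)
  pooled_scores <- c(); pooled_labels <- c()
  for (f in seq_len(folds)) {
    test_rows <- which(assignment == f)
    A_train <- A_full
    A_train[pos[test_rows, , drop = FALSE]] <- 0
    n_train_pos <- n_pos - length(test_rows)
    train_neg <- with_seed(seed + 1000L * f,
                           sample(neg_lin, min(n_train_pos, length(neg_lin))))
    test_neg <- setdiff(neg_lin, train_neg)
    if (length(test_neg) == 0L)
      stop("no test negatives remain; dataset too dense for this protocol")
    fit <- fit_bdhns_core(A_train, static, control)
    y <- fit$scores$y_bar
    s_pos <- y[pos[test_rows, , drop = FALSE]]
    s_neg <- y[test_neg]
    ra <- roc_auc(c(s_pos, s_neg),
                  c(rep(1L, length(s_pos)), rep(0L, length(s_neg))))
    fold_records[[f]] <- list(fold = f, n_test_pos = length(s_pos),
                              n_test_neg = length(s_neg), auc = ra$auc)
    pooled_scores <- c(pooled_scores, s_pos, s_neg)
    pooled_labels <- c(pooled_labels, rep(1L, length(s_pos)),
                       rep(0L, length(s_neg)))
  }
  fold_auc <- vapply(fold_records, `[[`, 0, "auc")
  roc <- roc_auc(pooled_scores, pooled_labels)$roc
  structure(list(protocol = "fivefold", folds = fold_records,
                 fold_auc = fold_auc, scores = pooled_scores,
                 labels = pooled_labels, roc = roc, auc = mean(fold_auc),
                 seed = seed, n_pos = n_pos, n_neg = length(neg_lin)),
            class = "bdhns_cv")
}

#' @export
print.bdhns_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d positives, %d candidate negatives\n",
              if (x$protocol == "loocv") "Leave-one-out" else "Five-fold",
              x$n_pos, x$n_neg))
  if (!is.null(x$fold_auc))
    cat("  per-fold AUC:", paste(sprintf("%.3f", x$fold_auc), collapse = " "),
        "\n")
  cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' ROC curve of a cross-validation result
#' @param x a `bdhns_cv` object. @param ... forwarded to plot.
#' @export
plot.bdhns_cv <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (%s), AUC = %.3f", x$protocol, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
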
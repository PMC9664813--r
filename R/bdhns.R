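#' Control parameters for a heterogeneous-network selection fit
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the tuned operating point of the method: restart probability 0.1, 20 walk
#' steps, embedding dimension 64; the jump probability `phi` (0.5), semantic
#' attenuation `delta` (0.5), GIP bandwidth scales (1) and selection
#' threshold `m` (0) complete the configuration.
#'
#' @param restart_r restart probability of the random walk, in (0, 1].
#' @param walk_steps number of walk iterations.
#' @param early_stop_tol optional early-stop tolerance for the walk.
#' @param phi cross-network jump probability in (0, 1).
#' @param delta semantic attenuation factor in (0, 1).
#' @param bandwidth_scale_m,bandwidth_scale_d GIP bandwidth scales.
#' @param gcn_layers propagation depth of the neighbour aggregation.
#' @param embed_dim embedding dimension of the random projection.
#' @param projection_seed seed for the shared projection matrix.
#' @param select_threshold_m causal-effect selection threshold.
#' @param attributes node attribute source: `"walk_profile"` (the restart
#'   walk's profile, default) or `"transition_matrix"` (use `W` directly;
#'   this is also the walk-disabled ablation).
#' @param center_embeddings centre embedding columns before the pair-scoring
#'   cosine (default `TRUE`); see [pair_scores()] for why plain cosines
#'   saturate after propagation.
#' @param selector logical; `FALSE` scores with the full-aggregation branch
#'   only (the selection-disabled ablation).
#' @return a list of class `bdhns_control`.
#' @export
bdhns_control <- function(restart_r = 0.1, walk_steps = 20L,
                          early_stop_tol = NULL, phi = 0.5, delta = 0.5,
                          bandwidth_scale_m = 1, bandwidth_scale_d = 1,
                          gcn_layers = 2L, embed_dim = 64L,
                          projection_seed = 13L, select_threshold_m = 0,
                          attributes = c("walk_profile", "transition_matrix"),
                          center_embeddings = TRUE, selector = TRUE) {
  attributes <- match.arg(attributes)
  stopifnot(restart_r > 0, restart_r <= 1, walk_steps >= 0,
            phi > 0, phi < 1, delta > 0, delta < 1,
            bandwidth_scale_m > 0, bandwidth_scale_d > 0,
            gcn_layers >= 1, embed_dim >= 1, is.logical(selector))
  structure(list(restart_r = restart_r, walk_steps = as.integer(walk_steps),
                 early_stop_tol = early_stop_tol, phi = phi, delta = delta,
                 bandwidth_scale_m = bandwidth_scale_m,
                 bandwidth_scale_d = bandwidth_scale_d,
                 gcn_layers = as.integer(gcn_layers),
                 embed_dim = as.integer(embed_dim),
                 projection_seed = as.integer(projection_seed),
                 select_threshold_m = select_threshold_m,
                 attributes = attributes,
                 center_embeddings = isTRUE(center_embeddings),
                 selector = selector),
            class = "bdhns_control")
}

#' Fit the bi-directional heterogeneous network selection model
#'
#' Runs the full association-prediction pipeline on a binary disease x
#' microbe association matrix and (optionally) its annotation bundle:
#'
#' 1. similarity fusion — GIP kernels on both axes, microbial functional
#'    similarity from organ/disease co-annotation, disease semantic
#'    (DAG-based), functional (gene-set) and symptom (cosine) similarities,
#'    fused into `SM` and `SD`;
#' 2. network construction — similarity-weighted bi-directional cross
#'    correlations, the heterogeneous adjacency and the row-stochastic
#'    transition matrix `W`;
#' 3. neighbour topology — an enhanced random walk with restart seeded at
#'    every node;
#' 4. scoring — graph-convolution aggregation of the walk profiles in full
#'    and same-type-only modes, cosine-weighted pair scores for both, and
#'    per-pair branch selection by the causal effect factor.
#'
#' Annotation channels that are absent fall back to neutral defaults (zero
#' functional similarity, identity semantic/functional/symptom similarity),
#' so the model also runs from associations alone.
#'
#' @param associations binary disease x microbe matrix with dimnames, or a
#'   two-column (disease, microbe) data.frame of known associations.
#' @param annotations an [mda_annotations] bundle or `NULL`.
#' @param control a [bdhns_control()] list.
#' @return an object of class `bdhns` with components `A`, `similarities`
#'   (GM, FM, SM, GD, DSS, DF, TD, SD), `network` (`A_sd`, `A_sm`, `A_all`,
#'   `transition`), `walk`, `embeddings` (`H`, `H_s`), `scores` (a
#'   `bdhns_scores` list) and `control`.
#' @examples
#' sim <- generate_mda_dataset(mda_params(n_d = 6, n_m = 12, seed = 1))
#' fit <- bdhns(sim$A, sim$annotations)
#' head(predict(fit))
#' @export
bdhns <- function(associations, annotations = NULL,
                  control = bdhns_control()) {
  A <- as_association_matrix(associations)
  stopifnot(inherits(control, "bdhns_control"))
  if (!is.null(annotations) && !inherits(annotations, "mda_annotations"))
    stop("annotations must be an 'mda_annotations' bundle (see mda_annotations())")
  static <- static_similarities(annotations, rownames(A), colnames(A), control)
  fit <- fit_bdhns_core(A, static, control)
  fit$call <- match.call()
  fit
}

# Association-independent similarity channels (FM, DSS, DF, TD): computed
# once per dataset and reused across cross-validation folds.
static_similarities <- function(annotations, disease_ids, microbe_ids,
                                control) {
  n_d <- length(disease_ids)
  ident <- function() {
    M <- diag(1, n_d); dimnames(M) <- list(disease_ids, disease_ids); M
  }
  if (is.null(annotations)) {
    FM <- matrix(0, length(microbe_ids), length(microbe_ids),
                 dimnames = list(microbe_ids, microbe_ids))
    return(list(FM = FM, DSS = ident(), DF = ident(), TD = ident()))
  }
  list(
    FM = microbe_functional_similarity(annotations, microbe_ids),
    DSS = disease_semantic_similarity(annotations$dag_edges, disease_ids,
                                      delta = control$delta),
    DF = disease_functional_similarity(annotations$gene_sets,
                                       annotations$gene_edges, disease_ids),
    TD = symptom_similarity(annotations$symptoms, disease_ids))
}

# One full pipeline pass for a given (possibly masked) association matrix.
fit_bdhns_core <- function(A, static, control) {
  GM <- gip_similarity(A, "microbe", control$bandwidth_scale_m)
  GD <- gip_similarity(A, "disease", control$bandwidth_scale_d)
  SM <- fuse_microbe_similarity(GM, static$FM)
  SD <- fuse_disease_similarity(GD, static$DSS, static$TD, static$DF)

  corr <- bidirectional_correlations(SD, SM, A)
  A_all <- assemble_hetero_adjacency(SD, SM, corr$A_sd, corr$A_sm)
  trans <- transition_matrix(SD, SM, A, phi = control$phi,
                             correlations = corr)

  walk <- NULL
  if (control$attributes == "walk_profile") {
    walk <- enhanced_rwr(trans, r = control$restart_r, t = control$walk_steps,
                         early_stop_tol = control$early_stop_tol)
    # node i's attribute row is its own seeded distribution (column i of P):
    # t(P(1)) = (1-r) W + r I, so this orientation reduces to the plain
    # transition-matrix attributes in the one-step limit
    X <- t(walk$P)
  } else {
    X <- trans$W
  }

  n_d <- nrow(A)
  proj <- gcn_projection(ncol(X), control$embed_dim, control$projection_seed)
  H <- gcn_aggregate(A_all, X, n_d, mode = "full", L = control$gcn_layers,
                     d = control$embed_dim, projection = proj)
  y_hat <- pair_scores(H, A, center = control$center_embeddings)

  if (control$selector) {
    H_s <- gcn_aggregate(A_all, X, n_d, mode = "intervened",
                         L = control$gcn_layers, d = control$embed_dim,
                         projection = proj)
    y_hat_s <- pair_scores(H_s, A, center = control$center_embeddings)
    scores <- select_scores(y_hat, y_hat_s, m = control$select_threshold_m)
  } else {
    H_s <- NULL
    scores <- structure(list(y_hat = y_hat, y_hat_s = NULL, effect = NULL,
                             branch = NULL, threshold = NA_real_,
                             y_bar = y_hat),
                        class = "bdhns_scores")
  }

  structure(list(A = A,
                 similarities = list(GM = GM, FM = static$FM, SM = SM,
                                     GD = GD, DSS = static$DSS, DF = static$DF,
                                     TD = static$TD, SD = SD),
                 network = list(A_sd = corr$A_sd, A_sm = corr$A_sm,
                                A_all = A_all, transition = trans),
                 walk = walk,
                 embeddings = list(H = H, H_s = H_s),
                 scores = scores,
                 control = control),
            class = "bdhns")
}

#' @export
print.bdhns <- function(x, ...) {
  cat("Bi-directional heterogeneous network selection model\n")
  cat(sprintf("  %d diseases x %d microbes, %d known associations\n",
              nrow(x$A), ncol(x$A), sum(x$A)))
  cat(sprintf("  walk: r = %g, t = %d (%s attributes); phi = %g; embed dim %d, %d layer(s)\n",
              x$control$restart_r, x$control$walk_steps, x$control$attributes,
              x$control$phi, x$control$embed_dim, x$control$gcn_layers))
  if (x$control$selector)
    cat(sprintf("  selection: threshold m = %g, full branch for %.1f%% of pairs\n",
                x$scores$threshold, 100 * mean(x$scores$branch == "full")))
  else
    cat("  selection disabled: full-aggregation scores only\n")
  cat(sprintf("  selected scores in [%.3f, %.3f]\n",
              min(x$scores$y_bar), max(x$scores$y_bar)))
  invisible(x)
}

#' @export
summary.bdhns <- function(object, n_top = 10L, ...) {
  tab <- prediction_table(object)
  novel <- tab[object$A[cbind(match(tab$disease, rownames(object$A)),
                              match(tab$microbe, colnames(object$A)))] == 0, ]
  novel <- novel[order(-novel$y_bar), ]
  structure(list(dims = dim(object$A), n_assoc = sum(object$A),
                 score_quartiles = stats::quantile(tab$y_bar),
                 branch_full = if (is.null(object$scores$branch)) NA_real_
                               else mean(object$scores$branch == "full"),
                 top_novel = utils::head(novel, n_top),
                 control = object$control),
            class = "summary.bdhns")
}

#' @export
print.summary.bdhns <- function(x, ...) {
  cat(sprintf("BDHNS fit: %d diseases x %d microbes, %d known associations\n",
              x$dims[1L], x$dims[2L], x$n_assoc))
  cat("Selected score quartiles:\n")
  print(round(x$score_quartiles, 4))
  if (!is.na(x$branch_full))
    cat(sprintf("Full-aggregation branch chosen for %.1f%% of pairs\n",
                100 * x$branch_full))
  cat("Top novel candidate pairs (unobserved in training):\n")
  print(x$top_novel[, c("disease", "microbe", "y_bar")], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' Predicted association scores of a fitted model
#'
#' @param object a fitted [bdhns] model.
#' @param type which surface to return: the selected score `"selected"`
#'   (default), the full-aggregation `"full"`, the same-type-only
#'   `"intervened"`, or the causal `"effect"`.
#' @param format `"pairs"` (disease-major data.frame, default) or
#'   `"matrix"`.
#' @param ... unused.
#' @export
predict.bdhns <- function(object,
                          type = c("selected", "full", "intervened", "effect"),
                          format = c("pairs", "matrix"), ...) {
  type <- match.arg(type); format <- match.arg(format)
  M <- switch(type, selected = object$scores$y_bar,
              full = object$scores$y_hat,
              intervened = object$scores$y_hat_s,
              effect = object$scores$effect)
  if (is.null(M))
    stop("surface '", type, "' is unavailable (selector disabled in this fit)")
  if (format == "matrix") return(M)
  tab <- prediction_table(object)
  tab$score <- M[cbind(match(tab$disease, rownames(M)),
                       match(tab$microbe, colnames(M)))]
  tab[, c("disease", "microbe", "score")]
}

#' Heatmap of the selected association score surface
#'
#' @param x a fitted [bdhns] model.
#' @param ... forwarded to [graphics::image()].
#' @export
plot.bdhns <- function(x, ...) {
  M <- x$scores$y_bar
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
                  xlab = "microbe index", ylab = "disease index",
                  main = "Selected association scores", ...)
  invisible(x)
}
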
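#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes the GIP kernel over association profiles: for entities `i`, `j`
#' with binary profiles `x_i`, `x_j` (a column of `A` for microbes, a row for
#' diseases), similarity is `exp(-r * ||x_i - x_j||^2)` where the bandwidth
#' `r = bandwidth_scale / mean(||x||^2)` is normalised by the mean squared
#' profile norm over that axis.
#'
#' @param A binary association matrix (diseases x microbes) with dimnames.
#' @param axis `"microbe"` (profiles are columns of `A`) or `"disease"`
#'   (profiles are rows).
#' @param bandwidth_scale positive scale on the normalised bandwidth
#'   (default 1).
#' @return symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
gip_similarity <- function(A, axis = c("microbe", "disease"),
                           bandwidth_scale = 1) {
  axis <- match.arg(axis)
  A <- as_association_matrix(A)
  if (!is.numeric(bandwidth_scale) || length(bandwidth_scale) != 1L ||
      bandwidth_scale <= 0)
    stop("bandwidth_scale must be a positive scalar")
  X <- if (axis == "microbe") t(A) else A
  sq <- rowSums(X^2)
  if (all(sq == 0))
    stop("GIP bandwidth undefined: all ", axis,
         " association profiles are zero (zero bandwidth)")
  r <- bandwidth_scale / mean(sq)
  # squared Euclidean distances via the Gram matrix
  G <- tcrossprod(X)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  S <- exp(-r * D2)
  diag(S) <- 1
  (S + t(S)) / 2
}

#' Min-max normalise a matrix to [0, 1]
#'
#' Elementwise `(M - min) / (max - min)`. The degenerate case `max == min`
#' is resolved by mode: `"zeros"` (no evidence anywhere, used for the raw
#' microbial functional counts) or `"ones"` (a single weight is still
#' evidence of linkage, used for gene log-likelihood scores).
#'
#' @param M finite numeric matrix.
#' @param degenerate one of `"zeros"`, `"ones"`.
#' @export
minmax_normalize <- function(M, degenerate = c("zeros", "ones")) {
  degenerate <- match.arg(degenerate)
  if (length(M) == 0L) stop("cannot min-max normalise an empty matrix")
  if (any(!is.finite(M))) stop("min-max normalisation requires finite entries")
  lo <- min(M); hi <- max(M)
  if (hi == lo) {
    fill <- if (degenerate == "zeros") 0 else 1
    M[] <- fill
    return(M)
  }
  (M - lo) / (hi - lo)
}

#' Microbial functional similarity from organ/disease co-annotation
#'
#' Two microbes residing in the same organ and affecting the same disease
#' contribute one unit of similarity; raw similarity accumulates these
#' (organ, disease) coincidences over all organs, each coincidence counted
#' once. The raw count matrix (zero diagonal) is then min-max normalised to
#' `[0, 1]`.
#'
#' @param annotations an [mda_annotations] bundle (uses `$organs`).
#' @param microbe_ids ordered microbe labels defining the matrix axes.
#' @return symmetric matrix `FM` with entries in [0, 1].
#' @export
microbe_functional_similarity <- function(annotations, microbe_ids) {
  stopifnot(length(microbe_ids) >= 1L, !anyDuplicated(microbe_ids))
  n <- length(microbe_ids)
  FM <- matrix(0, n, n, dimnames = list(microbe_ids, microbe_ids))
  org <- annotations$organs
  if (!is.null(org) && nrow(org) > 0L) {
    org <- org[org$microbe %in% microbe_ids, , drop = FALSE]
    org <- unique(org[, c("microbe", "organ", "disease")])
    key <- paste(org$organ, org$disease, sep = "\r")
    for (grp in split(org$microbe, key)) {
      idx <- match(unique(grp), microbe_ids)
      if (length(idx) >= 2L)
        FM[t(utils::combn(idx, 2L))] <- FM[t(utils::combn(idx, 2L))] + 1
    }
    FM <- FM + t(FM)   # counts were accumulated in one triangle
  }
  diag(FM) <- 0
  minmax_normalize(FM, degenerate = "zeros")
}

#' Fuse GIP and functional microbial similarity
#'
#' `SM(i,j) = GM(i,j)` where `FM(i,j) = 0`, else the mean of the two.
#'
#' @param GM,FM conforming similarity matrices with identical labels.
#' @export
fuse_microbe_similarity <- function(GM, FM) {
  if (!identical(dim(GM), dim(FM)) || !identical(dimnames(GM), dimnames(FM)))
    stop("GM and FM must have identical shape and labels")
  ifelse(FM == 0, GM, (GM + FM) / 2)
}

#' Disease semantic similarity over a disease DAG
#'
#' Wang-style semantics: each disease `D` spans the set `T(D)` of itself plus
#' all ancestors; a term at shortest ancestor distance `k` contributes
#' `delta^k`; the semantic value `DV(D)` is the sum of contributions. The
#' similarity of two diseases is the contribution mass on shared terms over
#' `DV(i) + DV(j)`. Diseases absent from the DAG receive an identity-like
#' row (self similarity 1, others 0).
#'
#' @param dag_edges data.frame of (child, parent) disease edges; must be
#'   acyclic.
#' @param disease_ids ordered disease labels for the output axes.
#' @param delta semantic attenuation factor in (0, 1), default 0.5.
#' @return symmetric matrix `DSS` with unit diagonal, entries in [0, 1].
#' @export
disease_semantic_similarity <- function(dag_edges, disease_ids, delta = 0.5) {
  stopifnot(length(disease_ids) >= 1L, !anyDuplicated(disease_ids))
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("delta must lie in (0, 1)")
  n <- length(disease_ids)
  DSS <- diag(1, n)
  dimnames(DSS) <- list(disease_ids, disease_ids)
  if (is.null(dag_edges) || nrow(dag_edges) == 0L) return(DSS)
  check_dag_acyclic(dag_edges)
  g <- igraph::graph_from_data_frame(dag_edges[, 1:2], directed = TRUE)
  nodes <- igraph::V(g)$name
  present <- disease_ids[disease_ids %in% nodes]
  if (length(present) == 0L) return(DSS)
  # contribution of term t in the DAG of D is delta^dist(D -> t): the max over
  # child chains in Eq-style recursion collapses to the shortest ancestor path
  dist <- igraph::distances(g, v = present, mode = "out")
  contrib <- lapply(seq_along(present), function(i) {
    d <- dist[i, ]
    d[is.finite(d)]
  })
  names(contrib) <- present
  DV <- vapply(contrib, function(d) sum(delta^d), 0)
  for (a in seq_along(present)) {
    for (b in seq_len(a)) {
      ta <- contrib[[a]]; tb <- contrib[[b]]
      shared <- intersect(names(ta), names(tb))
      val <- if (length(shared))
        sum(delta^ta[shared] + delta^tb[shared]) / (DV[a] + DV[b]) else 0
      i <- match(present[a], disease_ids); j <- match(present[b], disease_ids)
      DSS[i, j] <- DSS[j, i] <- val
    }
  }
  diag(DSS) <- 1
  DSS
}

#' Semantic values of diseases over a disease DAG
#'
#' The semantic value `DV(D)` sums the contributions `delta^k` of every term
#' in `T(D)` (the disease plus its ancestors), `k` being the shortest
#' ancestor distance. Diseases absent from the DAG have value 1 (their `T`
#' set is just themselves).
#'
#' @inheritParams disease_semantic_similarity
#' @return named numeric vector of semantic values, one per disease.
#' @export
disease_semantic_values <- function(dag_edges, disease_ids, delta = 0.5) {
  stopifnot(length(disease_ids) >= 1L)
  dv <- stats::setNames(rep(1, length(disease_ids)), disease_ids)
  if (is.null(dag_edges) || nrow(dag_edges) == 0L) return(dv)
  check_dag_acyclic(dag_edges)
  g <- igraph::graph_from_data_frame(dag_edges[, 1:2], directed = TRUE)
  present <- disease_ids[disease_ids %in% igraph::V(g)$name]
  if (length(present) == 0L) return(dv)
  dist <- igraph::distances(g, v = present, mode = "out")
  dv[present] <- apply(dist, 1L, function(d) sum(delta^d[is.finite(d)]))
  dv
}

#' Disease functional similarity from gene sets and a weighted gene network
#'
#' Gene log-likelihood scores are min-max normalised over all provided edges
#' (degenerate case maps to 1). Gene-gene functional similarity `FSS` is 1 on
#' the diagonal, the normalised score where an edge exists, 0 otherwise. A
#' gene's affinity to a set is the max `FSS` over members, and the disease
#' pair similarity averages both directions over `m + n` genes. Diseases with
#' empty gene sets receive identity-like rows.
#'
#' @param gene_sets named list: disease id -> character vector of genes.
#' @param gene_edges data.frame (gene1, gene2, lls) with finite weights.
#' @param disease_ids ordered disease labels for the output axes.
#' @return symmetric matrix `DF` with entries in [0, 1].
#' @export
disease_functional_similarity <- function(gene_sets, gene_edges, disease_ids) {
  stopifnot(length(disease_ids) >= 1L, !anyDuplicated(disease_ids))
  n <- length(disease_ids)
  DF <- diag(1, n)
  dimnames(DF) <- list(disease_ids, disease_ids)
  sets <- gene_sets[names(gene_sets) %in% disease_ids]
  sets <- Filter(length, lapply(sets, unique))
  if (length(sets) == 0L) return(DF)

  lls_lookup <- new.env(parent = emptyenv())
  if (!is.null(gene_edges) && nrow(gene_edges) > 0L) {
    if (any(!is.finite(gene_edges$lls)))
      stop("gene edge log-likelihood scores must be finite")
    w <- as.numeric(minmax_normalize(matrix(gene_edges$lls), degenerate = "ones"))
    for (k in seq_along(w)) {
      assign(paste(gene_edges$gene1[k], gene_edges$gene2[k], sep = "\r"),
             w[k], envir = lls_lookup)
      assign(paste(gene_edges$gene2[k], gene_edges$gene1[k], sep = "\r"),
             w[k], envir = lls_lookup)
    }
  }
  fss <- function(g1, g2) {
    if (g1 == g2) return(1)
    val <- mget(paste(g1, g2, sep = "\r"), envir = lls_lookup,
                ifnotfound = 0)[[1L]]
    val
  }
  set_affinity <- function(g, set) max(vapply(set, function(s) fss(g, s), 0))

  with_sets <- names(sets)
  for (a in seq_along(with_sets)) {
    for (b in seq_len(a - 1L)) {
      Gi <- sets[[a]]; Gj <- sets[[b]]
      num <- sum(vapply(Gi, set_affinity, 0, set = Gj)) +
             sum(vapply(Gj, set_affinity, 0, set = Gi))
      val <- num / (length(Gi) + length(Gj))
      i <- match(with_sets[a], disease_ids); j <- match(with_sets[b], disease_ids)
      DF[i, j] <- DF[j, i] <- val
    }
  }
  DF
}

#' Disease symptom similarity (cosine)
#'
#' Pairwise cosine similarity of disease symptom profile rows. An all-zero
#' profile is similar only to itself (self 1, others 0).
#'
#' @param symptom_table non-negative matrix, diseases on rows.
#' @param disease_ids optional ordered disease labels; diseases missing from
#'   the table get identity-like rows.
#' @return symmetric matrix `TD` with entries in [0, 1].
#' @export
symptom_similarity <- function(symptom_table, disease_ids = NULL) {
  if (is.null(disease_ids)) disease_ids <- rownames(symptom_table)
  stopifnot(!is.null(disease_ids), !anyDuplicated(disease_ids))
  n <- length(disease_ids)
  TD <- diag(1, n)
  dimnames(TD) <- list(disease_ids, disease_ids)
  if (is.null(symptom_table) || nrow(symptom_table) == 0L) return(TD)
  if (any(symptom_table < 0)) stop("symptom table must be non-negative")
  present <- intersect(disease_ids, rownames(symptom_table))
  if (length(present) == 0L) return(TD)
  S <- clamped_cosine(symptom_table[present, , drop = FALSE])
  idx <- match(present, disease_ids)
  TD[idx, idx] <- S
  diag(TD) <- 1
  TD
}

#' Fuse the four disease similarity channels
#'
#' `SD` is the elementwise mean of the GIP, semantic, symptom and functional
#' disease similarities.
#'
#' @param GD,DSS,TD,DF conforming matrices with identical labels.
#' @export
fuse_disease_similarity <- function(GD, DSS, TD, DF) {
  mats <- list(GD = GD, DSS = DSS, TD = TD, DF = DF)
  ref <- dimnames(GD)
  for (nm in names(mats))
    if (!identical(dim(mats[[nm]]), dim(GD)) ||
        !identical(dimnames(mats[[nm]]), ref))
      stop("disease similarity matrices must share shape and labels (", nm, ")")
  (GD + DSS + TD + DF) / 4
}
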
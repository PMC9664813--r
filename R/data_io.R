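#' Read a disease-microbe association edge list
#'
#' Parses a tabular text file with at least two columns (disease id, microbe
#' id) into the binary association matrix `A` with diseases on rows and
#' microbes on columns. Duplicate records are collapsed, so `sum(A)` equals
#' the number of distinct (disease, microbe) pairs in the file. Axis labels
#' are ordered by first appearance.
#'
#' Files are tab-separated UTF-8; lines starting with `#` and blank lines are
#' ignored. A header row is optional and recognised when the first two fields
#' are (case-insensitively) `disease`/`microbe` or `disease_id`/`microbe_id`.
#'
#' @param path path to the association file.
#' @return a binary matrix with disease row names and microbe column names.
#' @examples
#' tf <- tempfile()
#' writeLines(c("d1\tm1", "d2\tm1", "d1\tm2", "d1\tm1"), tf)
#' A <- read_associations(tf)
#' sum(A)  # 3 distinct pairs
#' @export
read_associations <- function(path) {
  fields <- read_tsv_fields(path, min_cols = 2L, what = "association file")
  if (is_header_row(fields[[1L]], c("disease", "microbe"),
                    c("disease_id", "microbe_id")))
    fields <- fields[-1L]
  if (length(fields) == 0L) stop("association file contains no data rows: ", path)
  d <- vapply(fields, `[[`, "", 1L)
  m <- vapply(fields, `[[`, "", 2L)
  pairs_to_matrix(d, m)
}

#' Read the annotation inputs that feed the association-independent similarities
#'
#' Assembles the microbe organ/disease annotations, the disease DAG, the
#' disease gene sets, the weighted gene-gene network and the disease x symptom
#' table into one bundle. Every component is optional; absent files yield
#' empty components and the downstream similarities fall back to their neutral
#' defaults. Ids unknown to the association matrix are dropped with a warning
#' giving the count, so partial annotation sets still run.
#'
#' Expected schemas (tab-separated, `#` comments ignored, headers optional
#' except for the symptom matrix whose first row/column are labels):
#' `organs`: microbe, organ, disease; `dag`: child disease, parent disease;
#' `gene_sets`: disease, gene; `gene_edges`: gene, gene, log-likelihood score;
#' `symptoms`: labeled non-negative matrix.
#'
#' @param paths named list with any of `organs`, `dag`, `gene_sets`,
#'   `gene_edges`, `symptoms` mapping to file paths.
#' @param diseases,microbes known entity ids (typically the dimnames of the
#'   association matrix) used to cross-reference annotation ids.
#' @return an object of class `mda_annotations`.
#' @export
read_annotations <- function(paths, diseases, microbes) {
  stopifnot(is.list(paths))
  organs <- dag <- gene_edges <- NULL
  gene_sets <- list()
  symptoms <- NULL

  if (!is.null(paths$organs)) {
    fields <- read_tsv_fields(paths$organs, 3L, "organ annotation file")
    if (length(fields) && is_header_row(fields[[1L]], c("microbe", "organ", "disease")))
      fields <- fields[-1L]
    organs <- data.frame(
      microbe = vapply(fields, `[[`, "", 1L),
      organ   = vapply(fields, `[[`, "", 2L),
      disease = vapply(fields, `[[`, "", 3L),
      stringsAsFactors = FALSE)
    bad <- !(organs$microbe %in% microbes) | !(organs$disease %in% diseases)
    if (any(bad)) {
      warning(sum(bad), " organ annotation row(s) with unknown ids dropped")
      organs <- organs[!bad, , drop = FALSE]
    }
  }

  if (!is.null(paths$dag)) {
    fields <- read_tsv_fields(paths$dag, 2L, "disease DAG file")
    if (length(fields) && is_header_row(fields[[1L]], c("child", "parent")))
      fields <- fields[-1L]
    dag <- data.frame(
      child  = vapply(fields, `[[`, "", 1L),
      parent = vapply(fields, `[[`, "", 2L),
      stringsAsFactors = FALSE)
    check_dag_acyclic(dag)
  }

  if (!is.null(paths$gene_sets)) {
    fields <- read_tsv_fields(paths$gene_sets, 2L, "gene set file")
    if (length(fields) && is_header_row(fields[[1L]], c("disease", "gene")))
      fields <- fields[-1L]
    gs <- data.frame(
      disease = vapply(fields, `[[`, "", 1L),
      gene    = vapply(fields, `[[`, "", 2L),
      stringsAsFactors = FALSE)
    bad <- !(gs$disease %in% diseases)
    if (any(bad)) {
      warning(sum(bad), " gene set row(s) with unknown disease ids dropped")
      gs <- gs[!bad, , drop = FALSE]
    }
    gene_sets <- split(gs$gene, factor(gs$disease, levels = unique(gs$disease)))
    gene_sets <- lapply(gene_sets, unique)
  }

  if (!is.null(paths$gene_edges)) {
    fields <- read_tsv_fields(paths$gene_edges, 3L, "gene network file")
    if (length(fields) && is_header_row(fields[[1L]], c("gene1", "gene2", "lls")))
      fields <- fields[-1L]
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(w) || any(!is.finite(w)))
      stop("gene network file contains non-finite log-likelihood scores")
    gene_edges <- data.frame(
      gene1 = vapply(fields, `[[`, "", 1L),
      gene2 = vapply(fields, `[[`, "", 2L),
      lls = w, stringsAsFactors = FALSE)
  }

  if (!is.null(paths$symptoms)) {
    symptoms <- read_matrix_tsv(paths$symptoms)
    if (any(symptoms < 0)) stop("symptom table contains negative weights")
    unknown <- !(rownames(symptoms) %in% diseases)
    if (any(unknown)) {
      warning(sum(unknown), " symptom row(s) with unknown disease ids dropped")
      symptoms <- symptoms[!unknown, , drop = FALSE]
    }
  }

  mda_annotations(organs = organs, dag_edges = dag, gene_sets = gene_sets,
                  gene_edges = gene_edges, symptoms = symptoms)
}

#' Construct an annotation bundle programmatically
#'
#' @param organs data.frame with columns microbe, organ, disease (or NULL).
#' @param dag_edges data.frame with columns child, parent (or NULL); must be
#'   acyclic.
#' @param gene_sets named list mapping disease id to a character vector of
#'   gene ids.
#' @param gene_edges data.frame with columns gene1, gene2, lls (or NULL).
#' @param symptoms non-negative numeric matrix with disease row names.
#' @return an object of class `mda_annotations`.
#' @export
mda_annotations <- function(organs = NULL, dag_edges = NULL, gene_sets = list(),
                            gene_edges = NULL, symptoms = NULL) {
  if (!is.null(dag_edges)) check_dag_acyclic(dag_edges)
  if (!is.null(symptoms) && any(symptoms < 0))
    stop("symptom table contains negative weights")
  if (!is.null(gene_edges) && any(!is.finite(gene_edges$lls)))
    stop("gene edge log-likelihood scores must be finite")
  structure(list(organs = organs, dag_edges = dag_edges, gene_sets = gene_sets,
                 gene_edges = gene_edges, symptoms = symptoms),
            class = "mda_annotations")
}

#' @export
print.mda_annotations <- function(x, ...) {
  cat("Microbe-disease annotation bundle\n")
  cat(sprintf("  organ annotations : %d rows\n",
              if (is.null(x$organs)) 0L else nrow(x$organs)))
  cat(sprintf("  disease DAG edges : %d\n",
              if (is.null(x$dag_edges)) 0L else nrow(x$dag_edges)))
  cat(sprintf("  gene sets         : %d diseases\n", length(x$gene_sets)))
  cat(sprintf("  gene-gene edges   : %d\n",
              if (is.null(x$gene_edges)) 0L else nrow(x$gene_edges)))
  cat(sprintf("  symptom table     : %s\n",
              if (is.null(x$symptoms)) "absent"
              else paste(dim(x$symptoms), collapse = " x ")))
  invisible(x)
}

#' Write per-pair prediction scores to a TSV
#'
#' Emits one row per (disease, microbe) pair in disease-major order with the
#' full-aggregation score, the same-type-only score, the causal effect
#' factor, the chosen branch and the selected score. Numbers are written at
#' full double precision so a round-trip read recovers them.
#'
#' @param scores a fitted [bdhns] model or the score list it carries.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
write_predictions <- function(scores, path) {
  df <- prediction_table(scores)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read back a prediction TSV written by [write_predictions()]
#' @param path file path.
#' @return data.frame with disease, microbe, score columns.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Flatten a fitted model (or bare score list) into the disease-major table.
prediction_table <- function(scores) {
  if (inherits(scores, "bdhns")) scores <- scores$scores
  y <- scores$y_bar
  stopifnot(is.matrix(y))
  if (any(!is.finite(y))) stop("prediction scores must be finite")
  d_ids <- rownames(y); m_ids <- colnames(y)
  grid <- expand.grid(microbe = seq_along(m_ids), disease = seq_along(d_ids))
  i <- grid$disease; j <- grid$microbe
  pick <- function(M) if (is.null(M)) rep(NA_real_, length(i)) else M[cbind(i, j)]
  data.frame(
    disease = d_ids[i], microbe = m_ids[j],
    y_hat = pick(scores$y_hat), y_hat_s = pick(scores$y_hat_s),
    effect = pick(scores$effect),
    branch = if (is.null(scores$branch)) rep("full", length(i))
             else scores$branch[cbind(i, j)],
    y_bar = pick(y),
    stringsAsFactors = FALSE)
}

#' Write a labeled numeric matrix as TSV (first row/column are ids)
#' @param M matrix with dimnames. @param path output path.
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(M)
}

#' Read a labeled numeric matrix from TSV (header row required)
#' @param path input path.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("labeled matrix file needs an id column plus data: ", path)
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1L]])
  M
}

# -- internal parsing helpers -------------------------------------------------

read_tsv_fields <- function(path, min_cols, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(what, " not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (length(lines) == 0L) stop(what, " is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop(sprintf("malformed row in %s (expected >= %d tab-separated columns, got %d): '%s'",
                 what, min_cols, min(nf), lines[which(nf < min_cols)[1L]]))
  fields
}

is_header_row <- function(row, ...) {
  cand <- list(...)
  low <- tolower(trimws(row))
  any(vapply(cand, function(h) identical(low[seq_along(h)], h), TRUE))
}

# Reject cyclic disease hierarchies, naming an edge on a cycle.
check_dag_acyclic <- function(dag_edges) {
  stopifnot(is.data.frame(dag_edges), ncol(dag_edges) >= 2L)
  if (nrow(dag_edges) == 0L) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(dag_edges[, 1:2], directed = TRUE)
  if (igraph::is_dag(g)) return(invisible(TRUE))
  comp <- igraph::components(g, mode = "strong")
  bad <- which(comp$csize > 1L)[1L]
  members <- names(comp$membership)[comp$membership == bad]
  if (length(members) == 0L) {  # self-loop cycle
    loops <- dag_edges[dag_edges[[1L]] == dag_edges[[2L]], ]
    members <- loops[[1L]][1L]
  }
  on_cycle <- dag_edges[[1L]] %in% members & dag_edges[[2L]] %in% members
  e <- dag_edges[which(on_cycle)[1L], ]
  stop(sprintf("disease hierarchy contains a cycle through edge %s -> %s",
               e[[1L]], e[[2L]]))
}
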
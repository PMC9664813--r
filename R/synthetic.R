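#' Parameters of the block-structured synthetic dataset generator
#'
#' The generator plants `blocks` co-varying communities of diseases and
#' microbes: associations are dense within a block and sparse across blocks,
#' and every similarity channel (organ co-residence, shared DAG ancestry,
#' shared gene pools, shared symptom prototypes) is aligned with the same
#' block structure, so multi-source fusion has a recoverable signal.
#'
#' @param n_d number of diseases (default 15).
#' @param n_m number of microbes (default 60).
#' @param blocks number of planted blocks (default 3).
#' @param p_in within-block association probability (default 0.3).
#' @param p_out background association probability (default 0.02).
#' @param organs_per_block organs hosting each block (default 1).
#' @param genes_per_pool size of each block's gene pool (default 12).
#' @param genes_per_disease genes drawn per disease (default 4).
#' @param gene_leak_prob chance a drawn gene comes from another block's pool
#'   (default 0.2).
#' @param lls_range range of gene-edge log-likelihood scores (default
#'   `c(1, 5)`).
#' @param symptom_dims symptom vector length (default 10).
#' @param symptom_noise_sd sd of the truncated Gaussian symptom noise
#'   (default 0.2).
#' @param seed integer seed; same seed, same dataset.
#' @return list of class `mda_params`.
#' @export
mda_params <- function(n_d = 15L, n_m = 60L, blocks = 3L, p_in = 0.3,
                       p_out = 0.02, organs_per_block = 1L,
                       genes_per_pool = 12L, genes_per_disease = 4L,
                       gene_leak_prob = 0.2, lls_range = c(1, 5),
                       symptom_dims = 10L, symptom_noise_sd = 0.2,
                       seed = 7L) {
  stopifnot(n_d >= 1, n_m >= 1, blocks >= 1, blocks <= min(n_d, n_m),
            p_out >= 0, p_out < p_in, p_in <= 1,
            organs_per_block >= 1, genes_per_pool >= 1,
            genes_per_disease >= 1, genes_per_disease <= genes_per_pool,
            length(lls_range) == 2L, lls_range[1L] <= lls_range[2L],
            symptom_dims >= 1, symptom_noise_sd >= 0)
  structure(list(n_d = as.integer(n_d), n_m = as.integer(n_m),
                 blocks = as.integer(blocks), p_in = p_in, p_out = p_out,
                 organs_per_block = as.integer(organs_per_block),
                 genes_per_pool = as.integer(genes_per_pool),
                 genes_per_disease = as.integer(genes_per_disease),
                 gene_leak_prob = gene_leak_prob, lls_range = lls_range,
                 symptom_dims = as.integer(symptom_dims),
                 symptom_noise_sd = symptom_noise_sd,
                 seed = as.integer(seed)),
            class = "mda_params")
}

#' Generate a complete synthetic microbe-disease input bundle
#'
#' Produces, from one seed, all five inputs the pipeline consumes: the
#' association matrix, organ annotations, a disease DAG (a root with one
#' subtree per block), per-disease gene sets over block gene pools with a
#' dense within-pool weighted gene network, and a disease x symptom table of
#' noisy block prototypes. Ground-truth block labels are returned for
#' recovery checks. Identical parameters (including seed) give identical
#' output.
#'
#' @param params an [mda_params()] list.
#' @return list with `A` (association matrix), `annotations`
#'   ([mda_annotations]), `blocks` (list of disease and microbe block
#'   labels) and `params`.
#' @examples
#' sim <- generate_mda_dataset(mda_params(seed = 7))
#' sum(sim$A)
#' @export
generate_mda_dataset <- function(params = mda_params()) {
  stopifnot(inherits(params, "mda_params"))
  with_seed(params$seed, generate_mda_dataset_impl(params))
}

generate_mda_dataset_impl <- function(p) {
  d_ids <- sprintf("disease_%02d", seq_len(p$n_d))
  m_ids <- sprintf("microbe_%02d", seq_len(p$n_m))
  d_block <- sort(rep_len(seq_len(p$blocks), p$n_d))
  m_block <- sort(rep_len(seq_len(p$blocks), p$n_m))

  sample_A <- function() {
    prob <- ifelse(outer(d_block, m_block, "=="), p$p_in, p$p_out)
    A <- matrix(stats::rbinom(p$n_d * p$n_m, 1L, prob), p$n_d, p$n_m,
                dimnames = list(d_ids, m_ids))
    A
  }
  A <- sample_A()
  if (sum(A) == 0) {
    A <- sample_A()
    if (sum(A) == 0)
      stop("sampled association matrix is empty twice; ",
           "increase p_in/p_out or the matrix size")
  }

  # organ annotations: each microbe lives in its block's organ(s) and is
  # annotated there with every disease of its block
  organ_names <- outer(sprintf("organ_b%d", seq_len(p$blocks)),
                       seq_len(p$organs_per_block),
                       function(b, k) paste0(b, "_", k))
  rows <- do.call(rbind, lapply(seq_len(p$n_m), function(j) {
    b <- m_block[j]
    ds <- d_ids[d_block == b]
    expand.grid(microbe = m_ids[j], organ = organ_names[b, ], disease = ds,
                stringsAsFactors = FALSE)
  }))
  organs <- rows[, c("microbe", "organ", "disease")]

  # disease DAG: synthetic root, one internal parent per block
  block_parent <- sprintf("block_%d_root", seq_len(p$blocks))
  dag <- rbind(
    data.frame(child = block_parent, parent = "disease_root",
               stringsAsFactors = FALSE),
    data.frame(child = d_ids, parent = block_parent[d_block],
               stringsAsFactors = FALSE))

  # gene pools per block, complete weighted network within each pool
  pools <- lapply(seq_len(p$blocks), function(b)
    sprintf("gene_b%d_%02d", b, seq_len(p$genes_per_pool)))
  gene_sets <- lapply(seq_len(p$n_d), function(i) {
    b <- d_block[i]
    own <- sample(pools[[b]], p$genes_per_disease)
    leak <- stats::runif(p$genes_per_disease) < p$gene_leak_prob
    if (any(leak) && p$blocks > 1L) {
      other <- unlist(pools[-b])
      own[leak] <- sample(other, sum(leak))
    }
    unique(own)
  })
  names(gene_sets) <- d_ids
  gene_edges <- do.call(rbind, lapply(pools, function(g) {
    if (length(g) < 2L) return(NULL)
    idx <- t(utils::combn(length(g), 2L))
    data.frame(gene1 = g[idx[, 1L]], gene2 = g[idx[, 2L]],
               lls = stats::runif(nrow(idx), p$lls_range[1L],
                                  p$lls_range[2L]),
               stringsAsFactors = FALSE)
  }))

  # symptom table: block prototype + truncated Gaussian noise
  proto <- matrix(stats::runif(p$blocks * p$symptom_dims), p$blocks,
                  p$symptom_dims)
  # sharpen each prototype along one dimension so blocks occupy distinct
  # symptom directions even at small symptom_dims
  boost <- rep_len(seq_len(p$symptom_dims), p$blocks)
  proto[cbind(seq_len(p$blocks), boost)] <-
    proto[cbind(seq_len(p$blocks), boost)] + 2
  symptoms <- proto[d_block, , drop = FALSE] +
    matrix(stats::rnorm(p$n_d * p$symptom_dims, sd = p$symptom_noise_sd),
           p$n_d)
  symptoms[symptoms < 0] <- 0
  dimnames(symptoms) <- list(d_ids,
                             sprintf("symptom_%02d", seq_len(p$symptom_dims)))

  list(A = A,
       annotations = mda_annotations(organs = organs, dag_edges = dag,
                                     gene_sets = gene_sets,
                                     gene_edges = gene_edges,
                                     symptoms = symptoms),
       blocks = list(disease = stats::setNames(d_block, d_ids),
                     microbe = stats::setNames(m_block, m_ids)),
       params = p)
}

#' Write a synthetic bundle as the five tabular input files
#'
#' Emits `associations.tsv`, `organs.tsv`, `dag.tsv`, `gene_sets.tsv`,
#' `gene_edges.tsv` and `symptoms.tsv` in the formats [read_associations()]
#' and [read_annotations()] parse, so a generated dataset round-trips
#' through the readers.
#'
#' @param dataset result of [generate_mda_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_mda_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             organs = file.path(dir, "organs.tsv"),
             dag = file.path(dir, "dag.tsv"),
             gene_sets = file.path(dir, "gene_sets.tsv"),
             gene_edges = file.path(dir, "gene_edges.tsv"),
             symptoms = file.path(dir, "symptoms.tsv"))
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
  utils::write.table(
    data.frame(disease = rownames(dataset$A)[pos[, 1L]],
               microbe = colnames(dataset$A)[pos[, 2L]]),
    paths["associations"], sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- dataset$annotations
  utils::write.table(ann$organs, paths["organs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$dag_edges, paths["dag"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gs <- data.frame(disease = rep(names(ann$gene_sets),
                                 lengths(ann$gene_sets)),
                   gene = unlist(ann$gene_sets, use.names = FALSE))
  utils::write.table(gs, paths["gene_sets"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$gene_edges, paths["gene_edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(ann$symptoms, paths["symptoms"])
  invisible(paths)
}
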
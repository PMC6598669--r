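#' Run the full pathway-and-reach prioritisation pipeline
#'
#' Orchestrates the method end to end: reach profile and levels on the
#' full network (the pathway subnetwork is extracted only for reporting),
#' binary pathway- and reach-similarity matrices of the candidate genes
#' against the reference drivers, resampled Fisher's exact tests with
#' Benjamini-Hochberg correction, gene scores, and candidate selection.
#'
#' @param network Network graph (or path to an edge-list file).
#' @param pathways Pathway database (named list, or path to a GMT file).
#' @param cd_genes Candidate genes: a character vector, a pathway name
#'   present in `pathways`, or a path to a gene-list file.
#' @param dr_genes Reference driver genes (character vector or file path).
#' @param m Reach order (2 is the method's default channel).
#' @param n_levels Number of reach levels.
#' @param jsi_cutoff Pathway-similarity threshold.
#' @param reps Resampling replicates.
#' @param subset_size Reference genes drawn per replicate.
#' @param alpha Significance threshold for the gene-score frequency
#'   component.
#' @param gs_max Candidacy threshold on the gene score.
#' @param alternative Fisher-test sidedness.
#' @param adjust BH scope (`"replicate"`, `"matrix"`, `"none"`).
#' @param seed Integer seed (required: the p-value matrix is resampled).
#' @param id_map Optional named character vector translating candidate and
#'   reference identifiers onto the network's namespace
#'   ([read_id_map()]).
#' @param levels Optional precomputed [assign_levels()] result (e.g. with
#'   planted overrides applied); computed from the network when `NULL`.
#' @param gold Optional gold-standard driver set; adds `metrics` and
#'   `roc` to the result.
#' @param out_dir Optional directory; when given, writes `candidates.csv`,
#'   `pvalues.csv`, `levels.tsv`, `stats.json`, `manifest.json` and (with
#'   `gold`) `metrics.json` and `roc.csv`.
#' @return List of class `par_run`: `candidates` (full [candidate_table()]),
#'   `selection` ([select_candidates()] result), `pvalues`, `levels`,
#'   `P`, `R`, `network_stats`, `subnetwork_stats`, `dropped`, `config`,
#'   and optionally `metrics`, `roc`.
#' @export
run_par <- function(network, pathways, cd_genes, dr_genes,
                    m = 2, n_levels = 4, jsi_cutoff = 0.0036,
                    reps = 1000, subset_size = 50, alpha = 0.05,
                    gs_max = 1.0, alternative = "greater",
                    adjust = "replicate", seed = NULL,
                    id_map = NULL, levels = NULL, gold = NULL,
                    out_dir = NULL) {
  if (is.character(network)) network <- read_edge_list(network, quiet = TRUE)
  if (is.character(pathways) && length(pathways) == 1L &&
      file.exists(pathways)) {
    pathways <- read_gmt(pathways)
  }
  if (is.character(cd_genes) && length(cd_genes) == 1L) {
    if (cd_genes %in% names(pathways)) {
      cd_genes <- pathways[[cd_genes]]
    } else if (file.exists(cd_genes)) {
      cd_genes <- read_gene_list(cd_genes)
    }
  }
  if (is.character(dr_genes) && length(dr_genes) == 1L &&
      file.exists(dr_genes)) {
    dr_genes <- read_gene_list(dr_genes)
  }
  if (is.null(seed)) {
    stop("seed is required: the p-value matrix is resampled", call. = FALSE)
  }
  stopifnot(reps >= 1, subset_size >= 2)

  dropped <- list()
  if (!is.null(id_map)) {
    cd_m <- map_ids(cd_genes, id_map)
    dr_m <- map_ids(dr_genes, id_map)
    dropped$cd_unmapped <- cd_m$unmapped
    dropped$dr_unmapped <- dr_m$unmapped
    cd_genes <- cd_m$mapped
    dr_genes <- dr_m$mapped
  }
  net_genes <- igraph::V(network)$name
  dropped$cd_not_in_network <- setdiff(cd_genes, net_genes)
  dropped$dr_not_in_network <- setdiff(dr_genes, net_genes)
  cd_genes <- intersect(cd_genes, net_genes)
  dr_genes <- intersect(dr_genes, net_genes)
  if (length(cd_genes) == 0L) {
    stop("no candidate genes left in the network; check identifiers ",
         "or supply an id_map", call. = FALSE)
  }
  if (length(dr_genes) < subset_size) {
    stop("reference driver pool (", length(dr_genes),
         ") smaller than subset_size (", subset_size,
         "); lower subset_size or extend the reference list",
         call. = FALSE)
  }

  if (is.null(levels)) {
    levels <- assign_levels(m_reach(network, m), n_levels = n_levels)
  }
  P <- pathway_similarity_matrix(pathways, cd_genes, dr_genes,
                                 jsi_cutoff = jsi_cutoff, quiet = TRUE)
  R <- reach_similarity_matrix(levels, cd_genes, dr_genes)
  pvalues <- resample_pvalues(P, R, reps = reps, subset_size = subset_size,
                              seed = seed, alternative = alternative,
                              adjust = adjust)
  candidates <- candidate_table(pvalues, known_drivers = dr_genes,
                                alpha = alpha)
  selection <- select_candidates(candidates, known_drivers = dr_genes,
                                 gs_max = gs_max)

  res <- list(
    candidates = candidates,
    selection = selection,
    pvalues = pvalues,
    levels = levels,
    P = P,
    R = R,
    network_stats = network_stats(network),
    subnetwork_stats = network_stats(induced_subnetwork(network, cd_genes)),
    dropped = dropped,
    config = list(m = m, n_levels = n_levels, jsi_cutoff = jsi_cutoff,
                  reps = reps, subset_size = subset_size, alpha = alpha,
                  gs_max = gs_max, alternative = alternative,
                  adjust = adjust, seed = seed,
                  n_cd_genes = length(cd_genes),
                  n_dr_genes = length(dr_genes))
  )
  if (!is.null(gold)) {
    scores <- stats::setNames(candidates$gs, candidates$gene)
    res$roc <- roc_curve(scores, gold, universe = candidates$gene)
    res$metrics <- confusion(candidates$gene[candidates$gs <= gs_max],
                             gold, universe = candidates$gene)
  }
  class(res) <- "par_run"
  if (!is.null(out_dir)) write_par_run(res, out_dir)
  res
}

#' @export
print.par_run <- function(x, ...) {
  cat(sprintf("<par_run> %d candidate genes vs %d reference drivers\n",
              x$config$n_cd_genes, x$config$n_dr_genes))
  cat(sprintf("  m = %d, reps = %d, subset = %d, seed = %d\n",
              x$config$m, x$config$reps, x$config$subset_size,
              x$config$seed))
  cat(sprintf("  candidates with GS <= %.2f: %d (%d novel)\n",
              x$config$gs_max, nrow(x$selection$all),
              nrow(x$selection$novel)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  vs gold: accuracy %.3f, MCC %.3f, AUC %.3f\n",
                x$metrics$accuracy, x$metrics$mcc, x$roc$auc))
  }
  invisible(x)
}

#' Write the artifacts of a pipeline run to disk
#'
#' Plain-text outputs only: CSV/TSV tables plus JSON sidecars.
#'
#' @param run A `par_run` object.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_par_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$candidates, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  pv <- as.data.frame(run$pvalues)
  names(pv) <- paste0("rep", seq_len(ncol(pv)))
  utils::write.csv(cbind(gene = rownames(run$pvalues), pv),
                   file.path(out_dir, "pvalues.csv"), row.names = FALSE)
  lv <- data.frame(gene = names(run$levels$assignment),
                   level = unname(run$levels$assignment))
  utils::write.table(lv, file.path(out_dir, "levels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(network = run$network_stats, subnetwork = run$subnetwork_stats),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  manifest <- c(run$config, list(
    package_version = as.character(utils::packageVersion("pathreach")),
    r_version = as.character(getRversion()),
    dropped = lapply(run$dropped, length),
    timestamp = format(Sys.time(), tz = "UTC")
  ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(run$metrics)) {
    jsonlite::write_json(c(run$metrics, list(auc = run$roc$auc)),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(run$roc$points, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Overlap algebra of published driver-gene lists
#'
#' Computes the Venn partition of two or more driver-gene lists: how many
#' genes appear in exactly one, two, ... lists, the genes common to all
#' lists (the strict reference set) and the genes in at least two lists
#' (the relaxed reference set).
#'
#' @param lists Named (or unnamed) list of >= 2 character vectors.
#' @return List with `union_size`, `by_multiplicity` (integer vector,
#'   count of genes in exactly k lists), `percent_by_multiplicity`
#'   (rounded to 1 decimal), `in_all` (sorted gene vector),
#'   `in_at_least_two` (sorted gene vector).
#' @examples
#' derive_reference_sets(list(c("a", "b", "c"), c("b", "c", "d"), c("c", "e")))
#' @export
derive_reference_sets <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L) {
    stop("need at least two gene lists", call. = FALSE)
  }
  lists <- lapply(lists, function(x) unique(as.character(x)))
  all_genes <- sort(unique(unlist(lists)))
  mult <- rowSums(vapply(lists, function(l) all_genes %in% l,
                         logical(length(all_genes))))
  k <- length(lists)
  by_mult <- vapply(seq_len(k), function(i) sum(mult == i), integer(1))
  names(by_mult) <- paste0("in_", seq_len(k), "_lists")
  list(
    union_size = length(all_genes),
    by_multiplicity = by_mult,
    percent_by_multiplicity = round(100 * by_mult / length(all_genes), 1),
    in_all = all_genes[mult == k],
    in_at_least_two = all_genes[mult >= 2]
  )
}
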
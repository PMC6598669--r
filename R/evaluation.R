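#' Confusion-matrix metrics for a driver-gene prediction
#'
#' Counts predictions against a gold-standard list over a fixed evaluation
#' universe (typically the pathway's genes present in the network) and
#' derives sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total and the Matthews correlation coefficient. MCC is defined
#' as 0 whenever a marginal is zero (random-classifier convention), which
#' matters for the heavily imbalanced driver/non-driver split.
#'
#' @param predicted Genes called drivers (subset of `universe`).
#' @param gold Gold-standard driver genes; only `gold` intersected with
#'   `universe` counts as positive.
#' @param universe All genes under evaluation.
#' @return List with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
confusion <- function(predicted, gold, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty evaluation universe", call. = FALSE)
  predicted <- intersect(unique(as.character(predicted)), universe)
  gold <- intersect(unique(as.character(gold)), universe)
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / length(universe)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

#' ROC curve for gene scores
#'
#' Sweeps a candidacy threshold over every distinct gene score (lower score
#' = more driver-like), anchored at (0, 0) and (1, 1), and integrates the
#' area under the curve by the trapezoid rule.
#'
#' @param scores Named numeric vector, gene -> gene score, covering the
#'   universe; lower means more likely driver.
#' @param gold Gold-standard driver genes.
#' @param universe Evaluation universe; defaults to `names(scores)`.
#' @return List with `points` (data frame of `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, gold, universe = names(scores)) {
  universe <- unique(as.character(universe))
  missing <- setdiff(universe, names(scores))
  if (length(missing) > 0L) {
    stop(length(missing), " universe gene(s) unscored", call. = FALSE)
  }
  s <- scores[universe]
  pos <- universe %in% gold
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("degenerate gold set (all or none of the universe)", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(s)), Inf)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call_pos <- s <= thr[i]
    tpr[i] <- if (n_pos > 0) sum(call_pos & pos) / n_pos else 0
    fpr[i] <- if (n_neg > 0) sum(call_pos & !pos) / n_neg else 0
  }
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]; thr <- thr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Compare reach orders m = 1, 2, 3 on the same inputs
#'
#' Runs the full pathway-and-reach scoring once per reach order, all else
#' (inputs, seed, thresholds) identical, and evaluates each run against a
#' gold-standard driver list with a ROC curve and confusion metrics at the
#' GS <= `gs_max` operating point. When a planted synthetic fixture is
#' supplied its reach-level overrides are applied only to the run whose m
#' matches the planting order.
#'
#' @param net Network graph.
#' @param db Pathway database.
#' @param cd_genes Candidate genes.
#' @param dr_genes Reference driver genes.
#' @param gold Gold-standard drivers for evaluation.
#' @param m_values Reach orders to compare.
#' @param plant Optional `par_plant` object from [plant_drivers()] /
#'   [simulate_par_data()].
#' @param reps,subset_size,seed,jsi_cutoff,alpha,gs_max,n_levels,alternative,adjust
#'   Pipeline parameters, shared across runs (see [run_par()]).
#' @return Named list (one entry per m) of lists with `roc`, `metrics`,
#'   `candidates`.
#' @export
compare_reach_orders <- function(net, db, cd_genes, dr_genes, gold,
                                 m_values = c(1, 2, 3), plant = NULL,
                                 reps = 100, subset_size = 10, seed = 1,
                                 jsi_cutoff = 0.0036, alpha = 0.05,
                                 gs_max = 1.0, n_levels = 4,
                                 alternative = "greater",
                                 adjust = "replicate") {
  P <- pathway_similarity_matrix(db, cd_genes, dr_genes,
                                 jsi_cutoff = jsi_cutoff, quiet = TRUE)
  out <- list()
  for (m in m_values) {
    lev <- assign_levels(m_reach(net, m), n_levels = n_levels)
    if (!is.null(plant) && identical(as.integer(m), as.integer(plant$m))) {
      lev <- override_levels(lev, plant)
    }
    R <- reach_similarity_matrix(lev, cd_genes, dr_genes)
    pm <- resample_pvalues(P, R, reps = reps, subset_size = subset_size,
                           seed = seed, alternative = alternative,
                           adjust = adjust)
    tbl <- candidate_table(pm, known_drivers = dr_genes, alpha = alpha)
    scores <- stats::setNames(tbl$gs, tbl$gene)
    roc <- roc_curve(scores, gold, universe = tbl$gene)
    met <- confusion(tbl$gene[tbl$gs <= gs_max], gold, universe = tbl$gene)
    out[[paste0("m", m)]] <- list(roc = roc, metrics = met, candidates = tbl)
  }
  out
}
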
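#' Binary reach-similarity matrix (matrix R)
#'
#' Rows are candidate genes, columns reference driver genes; a cell is 1
#' when the two genes sit at the same reach level. Genes without a level
#' (absent from the network) are dropped with a warning.
#'
#' @param levels [assign_levels()] result (or any named integer vector of
#'   gene -> level).
#' @param cd_genes Candidate genes (rows).
#' @param dr_genes Reference driver genes (columns).
#' @return 0/1 matrix.
#' @export
reach_similarity_matrix <- function(levels, cd_genes, dr_genes) {
  assignment <- if (inherits(levels, "reach_levels")) levels$assignment else levels
  cd_genes <- unique(as.character(cd_genes))
  dr_genes <- unique(as.character(dr_genes))
  if (length(cd_genes) == 0L || length(dr_genes) == 0L) {
    stop("cd_genes and dr_genes must be non-empty", call. = FALSE)
  }
  cd_miss <- setdiff(cd_genes, names(assignment))
  dr_miss <- setdiff(dr_genes, names(assignment))
  if (length(cd_miss) + length(dr_miss) > 0L) {
    warning(length(cd_miss), " candidate and ", length(dr_miss),
            " reference gene(s) have no reach level; dropped", call. = FALSE)
    cd_genes <- setdiff(cd_genes, cd_miss)
    dr_genes <- setdiff(dr_genes, dr_miss)
  }
  if (length(cd_genes) == 0L || length(dr_genes) == 0L) {
    stop("no genes left after dropping unlevelled genes", call. = FALSE)
  }
  R <- outer(assignment[cd_genes], assignment[dr_genes], `==`) + 0L
  dimnames(R) <- list(cd_genes, dr_genes)
  R
}

#' 2x2 contingency table from one pathway row and one reach row
#'
#' Over a subset of reference columns, counts the four joint patterns of a
#' gene's pathway-similarity and reach-similarity indicators:
#' A = both 1, B = pathway only, C = reach only, D = neither.
#'
#' @param p_row,r_row Named 0/1 vectors sharing column labels.
#' @param columns Column labels (or indices) to count over; defaults to all.
#' @return Named integer vector `c(A, B, C, D)`; `A + B + C + D` equals the
#'   number of selected columns.
#' @export
contingency <- function(p_row, r_row, columns = NULL) {
  if (!identical(names(p_row), names(r_row))) {
    stop("p_row and r_row must share column labels", call. = FALSE)
  }
  if (!is.null(columns)) {
    if (is.character(columns) && !all(columns %in% names(p_row))) {
      stop("unknown column labels in subset", call. = FALSE)
    }
    p_row <- p_row[columns]
    r_row <- r_row[columns]
  }
  if (length(p_row) == 0L) stop("empty column subset", call. = FALSE)
  p <- p_row == 1L
  r <- r_row == 1L
  c(A = sum(p & r), B = sum(p & !r), C = sum(!p & r), D = sum(!p & !r))
}

# Vectorised Fisher exact p-values for 2x2 tables given as count vectors.
# "greater" tests enrichment of the joint (1,1) cell; "two.sided" sums the
# point probabilities <= that of the observed table (the standard
# conditional two-sided rule, with a 1 + 1e-7 relative tolerance for
# floating-point ties).
fisher_p_vec <- function(A, B, C, D,
                         alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  m <- A + B          # row-1 margin (pathway = 1)
  n2 <- C + D         # row-2 margin
  k <- A + C          # column-1 margin (reach = 1)
  p <- switch(alternative,
    greater = stats::phyper(A - 1, m, n2, k, lower.tail = FALSE),
    less = stats::phyper(A, m, n2, k, lower.tail = TRUE),
    two.sided = {
      out <- numeric(length(A))
      for (i in seq_along(A)) {
        lo <- max(0L, k[i] - n2[i])
        hi <- min(k[i], m[i])
        supp <- lo:hi
        d <- stats::dhyper(supp, m[i], n2[i], k[i])
        out[i] <- sum(d[d <= d[A[i] - lo + 1L] * (1 + 1e-7)])
      }
      out
    })
  pmin(p, 1)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact conditional (hypergeometric) p-value for the association between
#' the pathway and reach indicator rows. The default alternative
#' `"greater"` tests enrichment of the joint (1,1) cell, the signal the
#' pathway-and-reach score looks for.
#'
#' @param table Either a `c(A, B, C, D)` vector as returned by
#'   [contingency()] or a 2x2 matrix `rbind(c(A, B), c(C, D))`.
#' @param alternative `"greater"`, `"two.sided"` or `"less"`.
#' @return p-value in (0, 1\]. An all-zero table returns 1 with attribute
#'   `degenerate = TRUE`.
#' @export
fisher_exact <- function(table,
                         alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    table <- c(A = table[1, 1], B = table[1, 2],
               C = table[2, 1], D = table[2, 2])
  }
  stopifnot(length(table) == 4L, all(table >= 0))
  if (sum(table) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  unname(fisher_p_vec(table[[1]], table[[2]], table[[3]], table[[4]],
                      alternative))
}

#' Resampled Fisher p-value matrix
#'
#' For each of `reps` replicates a subset of `subset_size` reference
#' drivers is drawn uniformly without replacement (independently across
#' replicates); for every candidate gene the 2x2 contingency table over
#' that subset is tested with Fisher's exact test. Optionally the nominal
#' p-values are Benjamini-Hochberg adjusted, by default within each
#' replicate column (each replicate is one family of tests across the
#' candidate genes).
#'
#' @param P,R Binary similarity matrices sharing dimnames
#'   ([pathway_similarity_matrix()], [reach_similarity_matrix()]).
#' @param driver_pool Reference columns to sample from; defaults to all
#'   shared columns.
#' @param reps Number of replicates.
#' @param subset_size Reference genes drawn per replicate.
#' @param seed Integer seed making the matrix reproducible.
#' @param alternative Sidedness passed to the Fisher test.
#' @param adjust `"replicate"` (BH within each column), `"matrix"` (BH over
#'   the whole matrix) or `"none"`.
#' @return Numeric genes x replicates matrix of p-values with attributes
#'   `stage` (`"bh_adjusted"` or `"nominal"`), `subset_size`, `alternative`
#'   and `seed`.
#' @export
resample_pvalues <- function(P, R, driver_pool = NULL, reps = 1000,
                             subset_size = 50, seed = NULL,
                             alternative = c("greater", "two.sided", "less"),
                             adjust = c("replicate", "matrix", "none")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  shared_rows <- intersect(rownames(P), rownames(R))
  shared_cols <- intersect(colnames(P), colnames(R))
  if (length(shared_rows) == 0L || length(shared_cols) == 0L) {
    stop("P and R share no labels", call. = FALSE)
  }
  P <- P[shared_rows, shared_cols, drop = FALSE]
  R <- R[shared_rows, shared_cols, drop = FALSE]
  if (is.null(driver_pool)) driver_pool <- shared_cols
  driver_pool <- intersect(as.character(driver_pool), shared_cols)
  if (subset_size > length(driver_pool)) {
    stop("subset_size (", subset_size, ") exceeds driver pool (",
         length(driver_pool), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  G <- length(shared_rows)
  A <- B <- Cc <- matrix(0L, G, reps)
  for (j in seq_len(reps)) {
    sub <- sample(driver_pool, subset_size)
    Ps <- P[, sub, drop = FALSE]
    Rs <- R[, sub, drop = FALSE]
    A[, j] <- as.integer(rowSums(Ps * Rs))
    B[, j] <- as.integer(rowSums(Ps)) - A[, j]
    Cc[, j] <- as.integer(rowSums(Rs)) - A[, j]
  }
  D <- subset_size - A - B - Cc
  pv <- fisher_p_vec(as.vector(A), as.vector(B), as.vector(Cc),
                     as.vector(D), alternative)
  pm <- matrix(pv, G, reps, dimnames = list(shared_rows, NULL))
  stage <- "nominal"
  if (adjust == "replicate") {
    pm <- apply(pm, 2L, stats::p.adjust, method = "BH")
    rownames(pm) <- shared_rows
    stage <- "bh_adjusted"
  } else if (adjust == "matrix") {
    pm[] <- stats::p.adjust(pm, method = "BH")
    stage <- "bh_adjusted"
  }
  structure(pm, stage = stage, subset_size = subset_size,
            alternative = alternative, seed = seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a p-value vector
#' (`p.adjust(method = "BH")` with input validation).
#'
#' @param pvalues Numeric vector with entries in (0, 1\].
#' @return Adjusted vector, elementwise >= the input, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene score from a vector of p-values
#'
#' `GS = count(p > alpha) / length(p) + mean(p)`: the fraction of
#' replicates in which the gene did NOT look significantly similar to the
#' reference subset, plus the mean p-value. Both components lie in \[0, 1\],
#' so GS is in \[0, 2\]; lower is more driver-like, and GS <= 1 is the
#' usual candidacy threshold.
#'
#' @param pvalues Non-empty numeric vector in \[0, 1\] (one gene's
#'   replicate p-values, typically BH-adjusted).
#' @param alpha Significance threshold for the frequency component.
#' @return List with `gs`, `freq_component` and `mean_component`.
#' @export
gene_score <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  freq <- sum(pvalues > alpha) / length(pvalues)
  mu <- mean(pvalues)
  list(gs = freq + mu, freq_component = freq, mean_component = mu)
}

#' Per-gene candidate table from a p-value matrix
#'
#' @param pmatrix Genes x replicates p-value matrix
#'   ([resample_pvalues()]).
#' @param known_drivers Genes flagged as already-known drivers.
#' @param alpha Threshold for the gene-score frequency component.
#' @return `data.frame` with columns `gene`, `gs`, `freq_component`,
#'   `mean_component`, `rank` (ascending GS; ties broken by mean component
#'   then gene identifier) and `known_driver`.
#' @export
candidate_table <- function(pmatrix, known_drivers = character(0),
                            alpha = 0.05) {
  genes <- rownames(pmatrix)
  freq <- rowSums(pmatrix > alpha) / ncol(pmatrix)
  mu <- rowMeans(pmatrix)
  tbl <- data.frame(
    gene = genes,
    gs = freq + mu,
    freq_component = freq,
    mean_component = mu,
    known_driver = genes %in% known_drivers,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  ord <- order(tbl$gs, tbl$mean_component, tbl$gene)
  tbl <- tbl[ord, , drop = FALSE]
  tbl$rank <- seq_len(nrow(tbl))
  rownames(tbl) <- NULL
  tbl[, c("gene", "gs", "freq_component", "mean_component", "rank",
          "known_driver")]
}

#' Select and rank candidate driver genes
#'
#' Keeps genes with gene score at most `gs_max`, ranked ascending (ties by
#' mean component, then identifier); the novel list removes genes already
#' in the known-driver set.
#'
#' @param scores A [candidate_table()] data frame.
#' @param known_drivers Gene identifiers of already-known drivers.
#' @param gs_max Candidacy threshold on the gene score.
#' @return List with `all` (ranked candidate table rows with GS <= gs_max)
#'   and `novel` (the same minus known drivers).
#' @export
select_candidates <- function(scores, known_drivers = character(0),
                              gs_max = 1.0) {
  sel <- scores[scores$gs <= gs_max, , drop = FALSE]
  sel <- sel[order(sel$gs, sel$mean_component, sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  list(
    all = sel,
    novel = sel[!(sel$gene %in% known_drivers), , drop = FALSE]
  )
}

#' Genes in the low p-value ("red band") cluster
#'
#' Hierarchically clusters the rows of a p-value matrix (Euclidean
#' distance, average linkage) and returns the cluster with the lowest mean
#' p-value — the group that forms the red band on the adjusted-p heatmap.
#' Corroborative to the GS-threshold selection, which is the primary path.
#'
#' @param pmatrix Genes x replicates p-value matrix.
#' @param n_clusters Number of clusters to cut the dendrogram into.
#' @return Character vector of gene identifiers, sorted.
#' @export
red_band_cluster <- function(pmatrix, n_clusters = 2) {
  g <- nrow(pmatrix)
  if (g == 1L) return(rownames(pmatrix))
  if (n_clusters < 2L || n_clusters > g) {
    stop("n_clusters must be in [2, number of genes]", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(pmatrix), method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  means <- tapply(rowMeans(pmatrix), cl, mean)
  best <- as.integer(names(means)[which.min(means)])
  sort(rownames(pmatrix)[cl == best])
}
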
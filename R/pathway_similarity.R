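#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated (the Reactome/MSigDB convention). Duplicate members within
#' a line are stored once.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (pathway name -> member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1],
         " has fewer than 3 fields (name, description, genes...)",
         call. = FALSE)
  }
  db <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(db) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(db))) {
    stop("duplicate pathway names in GMT file", call. = FALSE)
  }
  db
}

#' Write a pathway database to GMT
#'
#' @param db Named list of gene-identifier vectors.
#' @param path Output file.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, "na", db[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Pathways a gene belongs to
#'
#' Membership is taken against the whole database, not only the pathway
#' under analysis: a gene's profile is the full list of pathways naming it.
#'
#' @param db Pathway database (named list of gene vectors).
#' @param gene Single gene identifier.
#' @return Character vector of pathway names, sorted, possibly empty.
#' @export
membership <- function(db, gene) {
  hits <- vapply(db, function(g) gene %in% g, logical(1))
  sort(names(db)[hits])
}

# membership profiles for many genes at once (internal; one pass over db)
membership_profiles <- function(db, genes) {
  genes <- as.character(genes)
  prof <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) prof[[g]] <- character(0)
  for (nm in sort(names(db))) {
    members <- intersect(db[[nm]], genes)
    for (g in members) prof[[g]] <- c(prof[[g]], nm)
  }
  prof
}

#' Jaccard similarity index of two pathway lists
#'
#' `|Lr intersect Lc| / |Lr union Lc|`, the overlap of the pathway
#' memberships of two genes. Defined as 0 when both lists are empty (no
#' evidence of similarity).
#'
#' @param lr,lc Character vectors of pathway names.
#' @return Similarity in \[0, 1\].
#' @examples
#' jsi(c("P1", "P2"), c("P2", "P3"))  # 1/3
#' @export
jsi <- function(lr, lc) {
  lr <- unique(lr)
  lc <- unique(lc)
  u <- length(union(lr, lc))
  if (u == 0L) return(0)
  length(intersect(lr, lc)) / u
}

#' Binary pathway-similarity matrix (matrix P)
#'
#' Rows are candidate genes, columns reference driver genes; a cell is 1
#' when the Jaccard similarity of the two genes' pathway-membership lists
#' reaches `jsi_cutoff`. The default cut-off 0.0036 corresponds, for genes
#' belonging to on the order of 10^2 pathways, to requiring at least one
#' common pathway; it should be raised for sparser pathway catalogues.
#'
#' @param db Pathway database.
#' @param cd_genes Candidate genes (matrix rows).
#' @param dr_genes Reference driver genes (matrix columns).
#' @param jsi_cutoff Similarity threshold in (0, 1].
#' @param drop_self Zero the diagonal cell when a candidate gene is itself
#'   a reference column (default keeps it).
#' @param quiet Suppress the message listing genes with no pathway
#'   membership (which yield all-zero rows/columns).
#' @return 0/1 matrix with candidate rows and reference columns.
#' @export
pathway_similarity_matrix <- function(db, cd_genes, dr_genes,
                                      jsi_cutoff = 0.0036,
                                      drop_self = FALSE, quiet = FALSE) {
  cd_genes <- unique(as.character(cd_genes))
  dr_genes <- unique(as.character(dr_genes))
  if (length(cd_genes) == 0L || length(dr_genes) == 0L) {
    stop("cd_genes and dr_genes must be non-empty", call. = FALSE)
  }
  if (jsi_cutoff <= 0 || jsi_cutoff > 1) {
    stop("jsi_cutoff must be in (0, 1]", call. = FALSE)
  }
  prof <- membership_profiles(db, union(cd_genes, dr_genes))
  orphans <- names(prof)[lengths(prof) == 0L]
  if (length(orphans) > 0L && !quiet) {
    message("pathway_similarity_matrix: ", length(orphans),
            " gene(s) with no pathway membership (all-zero profile)")
  }
  P <- matrix(0L, length(cd_genes), length(dr_genes),
              dimnames = list(cd_genes, dr_genes))
  for (r in cd_genes) {
    lr <- prof[[r]]
    for (c in dr_genes) {
      if (jsi(lr, prof[[c]]) >= jsi_cutoff) P[r, c] <- 1L
    }
  }
  if (drop_self) {
    both <- intersect(cd_genes, dr_genes)
    P[cbind(both, both)] <- 0L
  }
  P
}
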
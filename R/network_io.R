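#' Read a gene interaction network from an edge-list file
#'
#' Parses a whitespace/tab-separated edge list of the kind distributed by
#' STRING, BioGrid or Pathway Commons exports (two gene identifier columns,
#' optionally followed by a numeric confidence score). The result is an
#' undirected simple graph: duplicate rows, reversed duplicates and
#' self-loops collapse away. Nodes that appear only in dropped self-loop
#' rows are kept as isolated vertices.
#'
#' @param path Path to the edge-list file. Lines starting with `#` and blank
#'   lines are ignored.
#' @param score_column Optional 1-based column index holding a numeric
#'   confidence score (e.g. 3 for a STRING combined score).
#' @param min_score Optional threshold; rows with `score < min_score` are
#'   dropped. Only applied when both `score_column` and `min_score` are
#'   given.
#' @param quiet Suppress the message reporting dropped self-loops.
#' @return An undirected simple [igraph::igraph] graph whose vertices are
#'   named by gene identifier. Gene identifiers are case-sensitive opaque
#'   strings.
#' @examples
#' tf <- tempfile()
#' writeLines(c("TP53\tMDM2\t900", "MDM2\tTP53\t900", "KRAS\tBRAF\t150"), tf)
#' g <- read_edge_list(tf, score_column = 3, min_score = 400)
#' igraph::ecount(g)  # 1: the duplicate collapses, the low-score row drops
#' @export
read_edge_list <- function(path, score_column = NULL, min_score = NULL,
                           quiet = FALSE) {
  if (!file.exists(path)) {
    stop("edge-list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    stop("malformed edge-list line ", bad, " (need >= 2 columns): ",
         lines[bad], call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (!is.null(score_column) && !is.null(min_score)) {
    if (any(nf < score_column)) {
      bad <- idx[which(nf < score_column)[1]]
      stop("line ", bad, " has no score column ", score_column, call. = FALSE)
    }
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", score_column)))
    if (anyNA(sc)) {
      bad <- idx[which(is.na(sc))[1]]
      stop("non-numeric score on line ", bad, call. = FALSE)
    }
    drop <- sc < min_score
    a <- a[!drop]
    b <- b[!drop]
  }
  self <- a == b
  n_self <- sum(self)
  if (n_self > 0L && !quiet) {
    message("read_edge_list: dropped ", n_self, " self-loop row(s)")
  }
  nodes <- unique(c(a, b))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!self], to = b[!self], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Build a gene network from an in-memory edge table
#'
#' @param edges Two-column data frame or character matrix of endpoints.
#' @param nodes Optional extra vertex names (isolated nodes).
#' @return An undirected simple [igraph::igraph] graph.
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2L)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  self <- a == b
  vs <- unique(c(a, b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!self], to = b[!self], stringsAsFactors = FALSE),
    directed = FALSE, vertices = vs
  )
  igraph::simplify(g)
}

#' Read a plain-text gene list
#'
#' One identifier per line; `#` comments and blank lines are ignored;
#' duplicates collapse.
#'
#' @param path File path.
#' @return Character vector of unique gene identifiers (input order).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("gene-list file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Read a two-column identifier mapping table
#'
#' @param path TSV with source identifier in column 1 and target in column 2.
#'   Later rows for the same source are ignored (the map is a function).
#' @return Named character vector: `map["source"] == "target"`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) {
    stop("id-map file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("id map needs two columns", call. = FALSE)
  tab <- tab[!duplicated(tab[[1L]]), , drop = FALSE]
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Translate gene identifiers through a mapping table
#'
#' Many-to-one maps are allowed (several sources collapsing onto one
#' target); identifiers absent from the map are reported, never invented.
#'
#' @param genes Character vector of identifiers to translate.
#' @param idmap Named character vector as returned by [read_id_map()].
#' @return List with `mapped` (unique translated identifiers) and
#'   `unmapped` (inputs missing from the map, in input order).
#' @export
map_ids <- function(genes, idmap) {
  genes <- unique(as.character(genes))
  hit <- genes %in% names(idmap)
  list(
    mapped = unique(unname(idmap[genes[hit]])),
    unmapped = genes[!hit]
  )
}

#' Subnetwork induced by a gene set
#'
#' Restricts a network to the given genes: kept nodes are the intersection
#' of `genes` with the network, kept edges those with both endpoints
#' retained. Used to extract a pathway subnetwork from a full interaction
#' network.
#'
#' @param net Network graph.
#' @param genes Character vector of gene identifiers.
#' @return The induced [igraph::igraph] subgraph.
#' @export
induced_subnetwork <- function(net, genes) {
  keep <- intersect(igraph::V(net)$name, as.character(genes))
  igraph::induced_subgraph(net, keep)
}

#' Basic structural statistics of a network
#'
#' Density uses the undirected convention 2E / (N (N - 1)); the diameter is
#' the longest shortest path within the largest connected component
#' (disconnected nodes are counted but do not enter the diameter).
#'
#' @param net Network graph.
#' @return List with `n_nodes`, `n_edges`, `density` (`NA` when fewer than
#'   two nodes), `diameter` and `n_isolated`.
#' @export
network_stats <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  dens <- if (n >= 2L) 2 * e / (n * (n - 1)) else NA_real_
  diam <- NA_integer_
  if (e > 0L) {
    comp <- igraph::components(net)
    big <- which.max(comp$csize)
    lcc <- igraph::induced_subgraph(net, which(comp$membership == big))
    diam <- as.integer(igraph::diameter(lcc, unconnected = FALSE))
  }
  list(
    n_nodes = n,
    n_edges = e,
    density = dens,
    diameter = diam,
    n_isolated = sum(igraph::degree(net) == 0L)
  )
}

#' Density from printed node/edge counts, truncated for table comparison
#'
#' Computes the undirected density 2E / (N (N - 1)) from node and edge
#' counts and truncates (not rounds) to a fixed number of decimals, the
#' convention under which published network-summary tables are compared.
#'
#' @param n_nodes,n_edges Counts.
#' @param digits Decimals kept after truncation.
#' @return Truncated density.
#' @examples
#' density_from_counts(17397, 2232405)  # 0.0147
#' @export
density_from_counts <- function(n_nodes, n_edges, digits = 4) {
  stopifnot(n_nodes >= 2)
  d <- 2 * n_edges / (n_nodes * (n_nodes - 1))
  trunc(d * 10^digits) / 10^digits
}
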
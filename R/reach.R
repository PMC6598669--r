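#' Per-gene m-reach profile
#'
#' The m-reach of a gene is the number of other genes reachable from it in
#' at most `m` network steps, divided by the network size. 1-reach is the
#' normalised node degree; 2-reach is the default topology channel of the
#' pathway-and-reach method. A node with 2-reach near 1 can access almost
#' the whole network in two steps.
#'
#' @param net Network graph.
#' @param m Positive integer step count.
#' @param denominator `"N"` divides by the total node count (so values stay
#'   strictly below 1); `"N-1"` divides by N - 1 so a node reaching
#'   everything scores exactly 1. The node itself is never counted in the
#'   numerator under either convention.
#' @return Object of class `reach_profile`: list with `m`, `values` (named
#'   numeric over all nodes) and `denominator`.
#' @export
m_reach <- function(net, m = 2, denominator = c("N", "N-1")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != as.integer(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  n <- igraph::vcount(net)
  if (n == 0L) stop("network is empty", call. = FALSE)
  reached <- igraph::ego_size(net, order = m, mindist = 1)
  div <- if (denominator == "N") n else n - 1L
  vals <- stats::setNames(reached / div, igraph::V(net)$name)
  structure(list(m = as.integer(m), values = vals, denominator = denominator),
            class = "reach_profile")
}

#' @export
print.reach_profile <- function(x, ...) {
  cat(sprintf("<reach_profile> m = %d, %d genes, denominator %s\n",
              x$m, length(x$values), x$denominator))
  cat(sprintf("  reach range [%.6f, %.6f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Partition genes into reach levels (connectivity quantiles)
#'
#' Sorts genes by reach descending and splits them into `n_levels`
#' contiguous segments of near-equal size. Level 1 holds the
#' highest-connectivity genes, level `n_levels` the lowest. When N is not a
#' multiple of `n_levels`, the extra genes go to the highest-reach levels;
#' ties in reach are broken by gene identifier so the assignment is
#' reproducible regardless of input order.
#'
#' @param profile A [m_reach()] profile.
#' @param n_levels Number of levels (quartiles by default).
#' @return Object of class `reach_levels`: list with `assignment` (named
#'   integer vector, gene -> level), `cutpoints` (per-level maximum reach),
#'   `min_reach`, `sizes`, `nominal_per_level` (= floor(N / n_levels)) and
#'   `n_levels`.
#' @export
assign_levels <- function(profile, n_levels = 4) {
  stopifnot(inherits(profile, "reach_profile"))
  vals <- profile$values
  n <- length(vals)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  if (n_levels > n) stop("n_levels exceeds node count", call. = FALSE)
  ord <- order(-vals, names(vals))
  base <- n %/% n_levels
  extra <- n %% n_levels
  sizes <- rep.int(base, n_levels) + c(rep.int(1L, extra),
                                       rep.int(0L, n_levels - extra))
  lev <- rep.int(seq_len(n_levels), sizes)
  assignment <- integer(n)
  assignment[ord] <- lev
  names(assignment) <- names(vals)
  cut_sorted <- vals[ord]
  cutpoints <- vapply(split(cut_sorted, lev), max, numeric(1))
  structure(list(
    assignment = assignment,
    cutpoints = unname(cutpoints),
    min_reach = min(vals),
    sizes = sizes,
    nominal_per_level = base,
    n_levels = as.integer(n_levels),
    m = profile$m
  ), class = "reach_levels")
}

#' @export
print.reach_levels <- function(x, ...) {
  cat(sprintf("<reach_levels> %d levels over %d genes (m = %d)\n",
              x$n_levels, length(x$assignment), x$m))
  for (l in seq_len(x$n_levels)) {
    cat(sprintf("  Level %d: %d genes, max reach %.6f\n",
                l, x$sizes[l], x$cutpoints[l]))
  }
  cat(sprintf("  min reach %.6f; nominal per level %d\n",
              x$min_reach, x$nominal_per_level))
  invisible(x)
}

#' Histogram of reach values
#'
#' @param profile A [m_reach()] profile.
#' @param n_bins Number of equal-width bins spanning \[0, 1\].
#' @return List with `breaks` (length `n_bins + 1`) and `counts` (summing
#'   to the number of genes).
#' @export
reach_distribution <- function(profile, n_bins = 20) {
  stopifnot(inherits(profile, "reach_profile"), n_bins >= 1)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  # left-closed bins [a, b), last bin closed, so a value on an edge counts
  # toward the higher bin
  h <- graphics::hist(profile$values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = breaks, counts = h$counts)
}
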
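#' Configuration for the synthetic-data generator
#'
#' Bundles the sizes, rates and seed controlling [simulate_network()],
#' [simulate_pathways()] and [plant_drivers()]. All randomness flows from
#' the single `seed` through a fixed splitting scheme (`seed` for the
#' network, `seed + 1` for the pathways, `seed + 2` for the planting), so a
#' configuration pins down the whole fixture bit-for-bit.
#'
#' @param n_genes Number of genes (network nodes).
#' @param edges_per_new_node Attachments per new node during
#'   preferential-attachment growth; controls degree skew.
#' @param n_pathways Number of background pathway gene sets.
#' @param pathway_size_range Length-2 integer range of background pathway
#'   sizes.
#' @param n_reference_drivers Size of the reference driver set, sampled
#'   stratified across reach levels.
#' @param n_planted_drivers Planted (to-be-recovered) driver genes,
#'   disjoint from the reference set.
#' @param enrichment Probability in \[0, 1\] that a planted gene copies a
#'   reference driver's pathway memberships and is reported at that
#'   driver's reach level; 0 gives a pure null fixture.
#' @param enrich_channels Which resemblance channels enrichment couples:
#'   any subset of `c("pathway", "reach")`. The default couples both,
#'   because the method's contingency signal is the joint (1,1) cell.
#' @param m Reach order the planting is tied to.
#' @param n_levels Number of reach levels.
#' @param n_filler_per_driver_pathway Non-reference genes added to each
#'   level-linked driver pathway so reference profiles overlap partially,
#'   not identically.
#' @param seed Integer master seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000, edges_per_new_node = 3,
                             n_pathways = 40,
                             pathway_size_range = c(10, 40),
                             n_reference_drivers = 40,
                             n_planted_drivers = 20,
                             enrichment = 1.0,
                             enrich_channels = c("pathway", "reach"),
                             m = 2, n_levels = 4,
                             n_filler_per_driver_pathway = 5,
                             seed = 1) {
  stopifnot(
    n_genes >= edges_per_new_node + 1, edges_per_new_node >= 1,
    n_pathways >= 1, length(pathway_size_range) == 2L,
    pathway_size_range[1] <= pathway_size_range[2],
    pathway_size_range[2] <= n_genes,
    n_reference_drivers >= 1, n_planted_drivers >= 1,
    n_reference_drivers + n_planted_drivers <= n_genes,
    enrichment >= 0, enrichment <= 1,
    all(enrich_channels %in% c("pathway", "reach")),
    m >= 1, n_levels >= 2
  )
  structure(list(
    n_genes = as.integer(n_genes),
    edges_per_new_node = as.integer(edges_per_new_node),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_reference_drivers = as.integer(n_reference_drivers),
    n_planted_drivers = as.integer(n_planted_drivers),
    enrichment = enrichment,
    enrich_channels = enrich_channels,
    m = as.integer(m),
    n_levels = as.integer(n_levels),
    n_filler_per_driver_pathway = as.integer(n_filler_per_driver_pathway),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate a degree-skewed connected gene network
#'
#' Preferential-attachment growth: a seed triangle of three genes, then
#' each new gene attaches to `edges_per_new_node` distinct existing genes
#' chosen with probability proportional to current degree. The result is
#' connected, simple and degree-skewed (hub-dominated, small-world-like),
#' with exactly `3 + (n_genes - 3) * edges_per_new_node` edges when
#' `n_genes >= 3` (for genes added before enough nodes exist, all existing
#' nodes are used).
#'
#' @param config A [synthetic_config()].
#' @return An undirected simple [igraph::igraph] graph with genes named
#'   `g0001`, `g0002`, ...
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  mm <- config$edges_per_new_node
  set.seed(config$seed)
  ids <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  if (n < 3L) {
    return(gene_network(cbind(ids[1], ids[min(2L, n)]), nodes = ids))
  }
  max_edges <- 3L + (n - 3L) * mm
  from <- integer(max_edges)
  to <- integer(max_edges)
  from[1:3] <- c(1L, 1L, 2L)
  to[1:3] <- c(2L, 3L, 3L)
  deg <- numeric(n)
  deg[1:3] <- 2
  ptr <- 3L
  for (v in 4:n) {
    k <- min(mm, v - 1L)
    targets <- sample.int(v - 1L, k, prob = deg[seq_len(v - 1L)])
    from[ptr + seq_len(k)] <- v
    to[ptr + seq_len(k)] <- targets
    ptr <- ptr + k
    deg[targets] <- deg[targets] + 1
    deg[v] <- k
  }
  gene_network(cbind(ids[from[1:ptr]], ids[to[1:ptr]]), nodes = ids)
}

#' Simulate overlapping background pathway gene sets
#'
#' Draws `n_pathways` gene sets over the network's genes, each of a size
#' uniform in `pathway_size_range`, members sampled uniformly (so sets
#' overlap by chance, as real pathway catalogues do).
#'
#' @param net Network graph.
#' @param config A [synthetic_config()].
#' @return Named list of gene vectors (`PW001`, `PW002`, ...).
#' @export
simulate_pathways <- function(net, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  genes <- igraph::V(net)$name
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  db <- lapply(sizes, function(s) sample(genes, s))
  names(db) <- sprintf("PW%03d", seq_along(db))
  db
}

#' Plant a recoverable driver signal into a synthetic fixture
#'
#' Builds the "guilty by resemblance" structure the method is designed to
#' detect. Reference drivers are sampled stratified across the network's
#' reach levels and each level's drivers are joined into a level-linked
#' driver pathway (plus random filler genes), so that among reference
#' drivers shared pathway membership and shared reach level co-occur.
#' Each planted gene then, with probability `enrichment`, copies the full
#' pathway-membership profile of a randomly chosen reference driver
#' (guaranteeing Jaccard similarity with it) and is reported at that
#' driver's reach level via a level override (planting cannot rewire the
#' topology, so the override stands in for the level the gene would have);
#' with probability `1 - enrichment` it is left untouched.
#'
#' @param net Network graph.
#' @param db Background pathway database ([simulate_pathways()]).
#' @param config A [synthetic_config()]. `enrich_channels` selects whether
#'   the pathway profile, the reach level, or both are copied.
#' @return Object of class `par_plant`: list with `reference`, `planted`,
#'   `db` (modified database), `info` (per-planted-gene data frame:
#'   `gene`, `enriched`, `template`), `level_overrides` (named integer
#'   vector for enriched planted genes), `levels` (the unmodified
#'   [assign_levels()] result the planting used) and `m`.
#' @export
plant_drivers <- function(net, db, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  genes <- igraph::V(net)$name
  lev <- assign_levels(m_reach(net, config$m), n_levels = config$n_levels)
  asg <- lev$assignment

  # stratified reference set: near-equal count per reach level
  n_ref <- config$n_reference_drivers
  per <- rep(n_ref %/% config$n_levels, config$n_levels)
  extra <- n_ref %% config$n_levels
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  reference <- character(0)
  for (l in seq_len(config$n_levels)) {
    pool <- names(asg)[asg == l]
    reference <- c(reference, sample(pool, min(per[l], length(pool))))
  }

  # one driver pathway per level: that level's reference drivers + filler
  for (l in seq_len(config$n_levels)) {
    refs_l <- reference[asg[reference] == l]
    if (length(refs_l) == 0L) next
    filler <- sample(setdiff(genes, reference),
                     config$n_filler_per_driver_pathway)
    db[[sprintf("DRV_L%d", l)]] <- c(refs_l, filler)
  }

  planted <- sample(setdiff(genes, reference), config$n_planted_drivers)
  enriched <- stats::runif(length(planted)) < config$enrichment
  template <- rep(NA_character_, length(planted))
  template[enriched] <- sample(reference, sum(enriched), replace = TRUE)

  overrides <- integer(0)
  for (i in seq_along(planted)) {
    if (!enriched[i]) next
    g <- planted[i]
    tpl <- template[i]
    if ("pathway" %in% config$enrich_channels) {
      db <- lapply(db, function(members) {
        members <- setdiff(members, g)
        if (tpl %in% members) members <- c(members, g)
        members
      })
    }
    if ("reach" %in% config$enrich_channels) {
      overrides[g] <- asg[[tpl]]
    }
  }
  db <- db[lengths(db) > 0L]

  structure(list(
    reference = sort(reference),
    planted = planted,
    db = db,
    info = data.frame(gene = planted, enriched = enriched,
                      template = template, stringsAsFactors = FALSE),
    level_overrides = overrides,
    levels = lev,
    m = config$m
  ), class = "par_plant")
}

#' Apply planted reach-level overrides to a level assignment
#'
#' Replaces the assigned level of each enriched planted gene with its
#' template reference driver's level. Only the `assignment` field changes;
#' cutpoints and sizes still describe the unmodified partition.
#'
#' @param levels [assign_levels()] result.
#' @param plant `par_plant` object.
#' @return Modified `reach_levels` object.
#' @export
override_levels <- function(levels, plant) {
  stopifnot(inherits(levels, "reach_levels"), inherits(plant, "par_plant"))
  ov <- plant$level_overrides
  levels$assignment[names(ov)] <- ov
  levels
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper running [simulate_network()],
#' [simulate_pathways()] and [plant_drivers()] from one configuration.
#'
#' @param config A [synthetic_config()].
#' @return List of class `par_simulation` with `network`, `db` (planted
#'   database), `reference`, `planted`, `plant` (the full `par_plant`
#'   object), `levels` and `config`.
#' @export
simulate_par_data <- function(config) {
  net <- simulate_network(config)
  db0 <- simulate_pathways(net, config)
  plant <- plant_drivers(net, db0, config)
  structure(list(
    network = net,
    db = plant$db,
    reference = plant$reference,
    planted = plant$planted,
    plant = plant,
    levels = plant$levels,
    config = config
  ), class = "par_simulation")
}
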
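# Shared fixtures and independent oracles, built in code at test time.

# small named graphs -------------------------------------------------------

path_graph <- function(nodes) {
  gene_network(cbind(nodes[-length(nodes)], nodes[-1]))
}

star_graph <- function(center, leaves) {
  gene_network(cbind(center, leaves))
}

complete_graph <- function(nodes) {
  gene_network(t(utils::combn(nodes, 2)))
}

# Erdos-Renyi-style random simple graph over named nodes
random_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  gene_network(pairs[keep, , drop = FALSE], nodes = nodes)
}

random_pathway_db <- function(genes, n_pathways, size_range = c(2, 6),
                              seed = 1) {
  set.seed(seed)
  db <- lapply(seq_len(n_pathways), function(i) {
    sample(genes, sample(size_range[1]:size_range[2], 1))
  })
  names(db) <- sprintf("P%02d", seq_len(n_pathways))
  db
}

# independent oracles ------------------------------------------------------

# per-node breadth-first search to depth m (no igraph)
bfs_reach_oracle <- function(net, m, denominator = "N") {
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  div <- if (denominator == "N") length(nodes) else length(nodes) - 1L
  vals <- vapply(nodes, function(v) {
    seen <- v
    frontier <- v
    for (step in seq_len(m)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(nxt) == 0L) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    (length(seen) - 1L) / div
  }, numeric(1))
  vals
}

# exact Fisher p-values for one margin triple by full enumeration over the
# hypergeometric support, using binomial coefficients directly
fisher_enum_oracle <- function(A, B, C, D, alternative = "greater") {
  n <- A + B + C + D
  r <- A + B
  k <- A + C
  lo <- max(0L, r + k - n)
  hi <- min(r, k)
  supp <- lo:hi
  probs <- choose(r, supp) * choose(n - r, k - supp) / choose(n, k)
  i <- A - lo + 1L
  switch(alternative,
    greater = sum(probs[supp >= A]),
    less = sum(probs[supp <= A]),
    two.sided = sum(probs[probs <= probs[i] * (1 + 1e-7)])
  )
}

# hand-executed BH step-up: p_(i) * n / i, cumulative-min from the top,
# capped at 1, mapped back to input order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Venn realisation of the published three-list driver-gene overlap:
# union 724, all-three 71, exactly-two 85 (20 + 20 + 45), exactly-one 568
# (14 + 118 + 436), giving per-list totals 125 / 254 / 572. Synthetic gene
# labels; only the partition structure matters.
published_driver_lists <- function() {
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  core <- mk("core", 71)
  ab <- mk("ab", 20); ac <- mk("ac", 20); bc <- mk("bc", 45)
  a1 <- mk("va", 14); b1 <- mk("cb", 118); c1 <- mk("cg", 436)
  list(
    vogelstein = c(core, ab, ac, a1),   # 71 + 20 + 20 + 14  = 125
    cancer5000 = c(core, ab, bc, b1),   # 71 + 20 + 45 + 118 = 254
    cgc        = c(core, ac, bc, c1)    # 71 + 20 + 45 + 436 = 572
  )
}

# default-sized planted fixture used by recovery-style tests: the study
# conditions (200 candidate genes incl. the planted 20, 60-driver
# reference pool stratified over 4 levels, reps 100, subset 30)
planted_fixture <- function(seed = 7, enrichment = 1,
                            n_reference = 60) {
  cfg <- synthetic_config(n_genes = 800, n_reference_drivers = n_reference,
                          n_planted_drivers = 20, enrichment = enrichment,
                          seed = seed)
  sim <- simulate_par_data(cfg)
  set.seed(seed + 1000L)
  others <- sample(setdiff(igraph::V(sim$network)$name,
                           c(sim$reference, sim$planted)), 180)
  sim$cd_genes <- c(sim$planted, others)
  sim
}
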
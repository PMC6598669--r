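test_that("reach_similarity_matrix marks equal levels", {
  lev <- c(a = 1L, b = 1L, c = 4L, d1 = 1L, d2 = 4L)
  R <- reach_similarity_matrix(lev, c("a", "b", "c"), c("d1", "d2"))
  expect_equal(R["a", "d1"], 1L)
  expect_equal(R["a", "d2"], 0L)
  expect_equal(R["c", "d2"], 1L)

  # random 8x4 instance vs per-cell equality oracle
  set.seed(71)
  cd <- sprintf("c%d", 1:8); dr <- sprintf("d%d", 1:4)
  asg <- stats::setNames(sample(1:4, 12, TRUE), c(cd, dr))
  R2 <- reach_similarity_matrix(asg, cd, dr)
  for (r in cd) for (c in dr) {
    expect_equal(R2[r, c], as.integer(asg[[r]] == asg[[c]]))
  }

  expect_warning(reach_similarity_matrix(lev, c("a", "zz"), "d1"),
                 "no reach level")
  expect_error(reach_similarity_matrix(lev, character(0), "d1"),
               "non-empty")
})

test_that("contingency counts the four joint patterns", {
  p <- stats::setNames(c(1, 1, 0, 0), sprintf("d%d", 1:4))
  r <- stats::setNames(c(1, 0, 1, 0), sprintf("d%d", 1:4))
  expect_equal(contingency(p, r), c(A = 1L, B = 1L, C = 1L, D = 1L))

  s <- 7
  ones <- stats::setNames(rep(1, s), sprintf("d%d", 1:s))
  expect_equal(contingency(ones, ones), c(A = s, B = 0L, C = 0L, D = 0L))

  # random 50-column rows + random subset vs per-column scan oracle
  set.seed(81)
  cols <- sprintf("d%02d", 1:50)
  p2 <- stats::setNames(rbinom(50, 1, 0.4), cols)
  r2 <- stats::setNames(rbinom(50, 1, 0.6), cols)
  sub <- sample(cols, 20)
  got <- contingency(p2, r2, sub)
  oracle <- c(A = 0L, B = 0L, C = 0L, D = 0L)
  for (cc in sub) {
    key <- paste0(p2[[cc]], r2[[cc]])
    idx <- c("11" = 1, "10" = 2, "01" = 3, "00" = 4)[[key]]
    oracle[idx] <- oracle[idx] + 1L
  }
  expect_equal(got, oracle)
  expect_equal(sum(got), length(sub))

  names(r2)[1] <- "other"
  expect_error(contingency(p2, r2), "share column labels")
})

test_that("fisher_exact matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)), "two.sided"), 1.0)
  expect_equal(fisher_exact(c(A = 5, B = 0, C = 0, D = 5), "two.sided"),
               2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(c(A = 5, B = 0, C = 0, D = 5), "greater"),
               1 / 252, tolerance = 1e-12)

  z <- fisher_exact(c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(as.numeric(z), 1)
  expect_true(attr(z, "degenerate"))

  set.seed(91)
  for (i in 1:40) {
    tab <- c(A = rpois(1, 3), B = rpois(1, 3), C = rpois(1, 3),
             D = rpois(1, 5))
    if (sum(tab) == 0) next
    mat <- rbind(tab[c("A", "B")], tab[c("C", "D")])
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(unname(fisher_exact(tab, alt)),
                   unname(fisher_enum_oracle(tab[[1]], tab[[2]], tab[[3]],
                                             tab[[4]], alt)),
                   tolerance = 1e-12)
      expect_equal(unname(fisher_exact(tab, alt)),
                   unname(stats::fisher.test(mat, alternative = alt)$p.value),
                   tolerance = 1e-9)
    }
  }
})

test_that("resample_pvalues is deterministic and degenerates correctly", {
  set.seed(101)
  pool <- sprintf("d%02d", 1:12)
  genes <- sprintf("c%02d", 1:15)
  P <- matrix(rbinom(15 * 12, 1, 0.5), 15, 12,
              dimnames = list(genes, pool))
  R <- matrix(rbinom(15 * 12, 1, 0.5), 15, 12,
              dimnames = list(genes, pool))

  # subset = whole pool: every replicate sees the same columns
  pm_full <- resample_pvalues(P, R, reps = 5, subset_size = 12, seed = 1,
                              adjust = "none")
  expect_true(all(pm_full == pm_full[, 1]))

  pm_a <- resample_pvalues(P, R, reps = 20, subset_size = 6, seed = 42)
  pm_b <- resample_pvalues(P, R, reps = 20, subset_size = 6, seed = 42)
  pm_c <- resample_pvalues(P, R, reps = 20, subset_size = 6, seed = 43)
  expect_identical(pm_a, pm_b)
  expect_false(isTRUE(all.equal(unclass(pm_a), unclass(pm_c),
                                check.attributes = FALSE)))
  expect_true(all(pm_a > 0 & pm_a <= 1))
  expect_equal(attr(pm_a, "stage"), "bh_adjusted")

  # adjusted p-values never drop below nominal ones
  pm_nom <- resample_pvalues(P, R, reps = 20, subset_size = 6, seed = 42,
                             adjust = "none")
  expect_true(all(pm_a >= pm_nom - 1e-15))

  expect_error(resample_pvalues(P, R, reps = 5, subset_size = 13),
               "exceeds")
})

test_that("resampled p-values equal per-replicate contingency + Fisher", {
  # reconstruct replicate columns with the same RNG stream and verify each
  # cell against the scalar contingency/fisher_exact path
  set.seed(111)
  pool <- sprintf("d%02d", 1:10)
  genes <- sprintf("c%02d", 1:8)
  P <- matrix(rbinom(80, 1, 0.5), 8, 10, dimnames = list(genes, pool))
  R <- matrix(rbinom(80, 1, 0.5), 8, 10, dimnames = list(genes, pool))
  pm <- resample_pvalues(P, R, reps = 4, subset_size = 5, seed = 7,
                         adjust = "none")
  set.seed(7)
  for (j in 1:4) {
    sub <- sample(pool, 5)
    for (g in genes) {
      tab <- contingency(P[g, ], R[g, ], sub)
      expect_equal(unname(pm[g, j]), unname(fisher_exact(tab, "greater")),
                   tolerance = 1e-12)
    }
  }
})

test_that("bh_adjust reproduces the step-up rule", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(121)
  for (i in 1:25) {
    p <- runif(4)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("gene_score adds the frequency and mean components", {
  expect_equal(gene_score(rep(0, 100))$gs, 0)
  expect_equal(gene_score(rep(1, 100))$gs, 2)
  gs <- gene_score(c(rep(0.01, 500), rep(0.10, 500)))
  expect_equal(gs$gs, 0.5 + 0.055)
  expect_equal(gs$freq_component, 0.5)
  expect_equal(gs$mean_component, 0.055)
  expect_error(gene_score(numeric(0)), "empty")
})

test_that("candidate selection filters on GS and splits off known drivers", {
  tbl <- data.frame(gene = c("g1", "g2", "g3"),
                    gs = c(0.3, 1.4, 0.9),
                    freq_component = c(0.1, 0.7, 0.4),
                    mean_component = c(0.2, 0.7, 0.5),
                    rank = 1:3, known_driver = c(TRUE, FALSE, FALSE))
  sel <- select_candidates(tbl, known_drivers = "g1", gs_max = 1.0)
  expect_equal(sel$all$gene, c("g1", "g3"))
  expect_equal(sel$novel$gene, "g3")

  # 100 random genes vs independent filter-and-sort oracle
  set.seed(131)
  n <- 100
  tbl2 <- data.frame(gene = sprintf("g%03d", 1:n),
                     gs = round(runif(n, 0, 2), 2),
                     freq_component = runif(n),
                     mean_component = runif(n),
                     rank = 1:n,
                     known_driver = FALSE)
  sel2 <- select_candidates(tbl2, gs_max = 1.0)
  oracle <- tbl2[tbl2$gs <= 1.0, ]
  oracle <- oracle[order(oracle$gs, oracle$mean_component, oracle$gene), ]
  expect_equal(sel2$all$gene, oracle$gene)
})

test_that("candidate_table ranks ascending GS with deterministic ties", {
  set.seed(141)
  pm <- matrix(runif(60), 6, 10,
               dimnames = list(sprintf("g%d", 1:6), NULL))
  tbl <- candidate_table(pm, known_drivers = "g2")
  expect_setequal(tbl$rank, 1:6)
  expect_true(!is.unsorted(tbl$gs))
  expect_true(all(tbl$gs >= 0 & tbl$gs <= 2))
  expect_true(tbl$known_driver[tbl$gene == "g2"])
  # GS decomposition matches gene_score on each row
  for (g in rownames(pm)) {
    expect_equal(tbl$gs[tbl$gene == g], gene_score(pm[g, ])$gs)
  }
})

test_that("red_band_cluster recovers the low p-value block", {
  set.seed(151)
  low <- matrix(runif(50, 0, 0.02), 5, 10,
                dimnames = list(sprintf("low%d", 1:5), NULL))
  high <- matrix(runif(80, 0.85, 1), 8, 10,
                 dimnames = list(sprintf("high%d", 1:8), NULL))
  pm <- rbind(low, high)
  expect_setequal(red_band_cluster(pm, 2), sprintf("low%d", 1:5))

  single <- pm[1, , drop = FALSE]
  expect_equal(red_band_cluster(single), "low1")

  # three planted groups, k = 3: the lowest-mean group is returned
  mid <- matrix(runif(60, 0.4, 0.5), 6, 10)
  rownames(mid) <- sprintf("mid%d", 1:6)
  pm3 <- rbind(low, mid, high)
  expect_setequal(red_band_cluster(pm3, 3), sprintf("low%d", 1:5))

  expect_error(red_band_cluster(pm, 20), "n_clusters")
})
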
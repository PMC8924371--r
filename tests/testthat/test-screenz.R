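toy_counts <- function() {
  tibble::tibble(
    guide_id = sprintf("g%d", 1:4),
    gene_id = c("A", "A", "B", "B"),
    s1 = c(100L, 200L, 50L, 650L),
    s2 = c(100L, 200L, 50L, 650L)
  )
}

test_that("normalization matches hand arithmetic and sums to scale", {
  norm <- normalize_counts(toy_counts(), pseudocount = 5, scale = 1e7)
  # hand-computed: total 1000, pseudototal 1020
  expect_equal(norm$s1, (c(100, 200, 50, 650) + 5) * 1e7 / 1020)
  expect_equal(norm$s1, norm$s2)                     # identical samples
  expect_equal(sum(norm$s1), 1e7)                    # totals normalize exactly
  one <- tibble::tibble(guide_id = "g", gene_id = "G", s = 10L)
  expect_equal(normalize_counts(one)$s, 1e7)         # single guide
  zero <- dplyr::mutate(toy_counts(), s1 = 0L)
  expect_error(normalize_counts(zero), "zero total")
})

test_that("guide fold changes are exact log2 ratios", {
  norm <- normalize_counts(toy_counts())
  fc0 <- guide_fold_changes(norm, "s1", "s2")
  expect_equal(fc0$fc, rep(0, 4))                    # treated == control
  doubled <- dplyr::mutate(norm, s1 = s1 * 2)
  expect_equal(guide_fold_changes(doubled, "s1", "s2")$fc, rep(1, 4))
  # 6-guide spreadsheet check
  tb <- tibble::tibble(guide_id = sprintf("g%d", 1:6), gene_id = "G",
                       t = c(2, 4, 8, 1, 3, 5), c = c(1, 1, 2, 4, 3, 10))
  expect_equal(guide_fold_changes(tb, "t", "c")$fc,
               log2(c(2, 4, 4, 0.25, 1, 0.5)))
  expect_equal(guide_fold_changes(tb, "t", "c")$control_readcount, tb$c)
  expect_error(guide_fold_changes(tb, "nope", "c"), "not found")
})

test_that("empirical-Bayes sd tracks known noise and stays monotone", {
  set.seed(31)
  n <- 3000
  reads <- sort(rlnorm(n, 6, 1), decreasing = TRUE)
  fc <- rnorm(n, 0, 0.7)
  s <- empirical_bayes_sd(fc, reads, half_window = 500)
  expect_true(all(s > 0))
  expect_lt(max(abs(s - 0.7)) / 0.7, 0.15)           # ~ sigma everywhere
  # monotone non-decreasing toward low abundance
  ord <- order(reads, decreasing = TRUE)
  expect_true(all(diff(s[ord]) >= 0))
  # fewer guides than one window: single global sd
  s_small <- empirical_bayes_sd(fc[1:50], reads[1:50], half_window = 500)
  expect_equal(s_small, rep(sd(fc[1:50]), 50))
  # constant fold changes are floored, with a warning
  expect_warning(s_flat <- empirical_bayes_sd(rep(0.2, 30), reads[1:30]),
                 "floored")
  expect_true(all(s_flat > 0))
  expect_error(empirical_bayes_sd(1, 1), "2 guides")
})

test_that("gene scores standardize, rank and guard degenerate inputs", {
  z0 <- tibble::tibble(gene_id = rep(sprintf("g%02d", 1:10), each = 4), z = 0)
  sc0 <- gene_scores(z0)
  expect_equal(sc0$normZ, rep(0, 10))
  # identical central p-values stay at 0.5 after BH; no gene is callable
  expect_equal(sc0$fdr_depletion, rep(0.5, 10))
  expect_equal(sc0$fdr_enrichment, rep(0.5, 10))
  expect_length(call_hits(sc0, "depleted", 0.1)$genes, 0)
  expect_equal(sc0$rank, 1:10)                       # id-ordered ties
  expect_equal(sc0$gene_id, sort(sc0$gene_id))

  set.seed(8)
  zr <- tibble::tibble(gene_id = rep(sprintf("g%03d", 1:200), each = 8),
                       z = rnorm(1600))
  sc <- gene_scores(zr)
  expect_equal(sort(sc$rank), 1:200)
  expect_true(all(sc$fdr_depletion >= sc$p_depletion))
  expect_true(all(sc$fdr_enrichment >= sc$p_enrichment))
  # null p-values are uniform (KS at alpha = 0.01)
  expect_gt(ks.test(sc$p_depletion, "punif")$p.value, 0.01)
  # BH monotonicity: more extreme normZ never has larger depletion FDR
  o <- order(sc$normZ)
  expect_true(all(diff(cummax(sc$fdr_depletion[o])) >= 0))
  expect_warning(gene_scores(tibble::tibble(gene_id = c("a", "a", "b"),
                                            z = c(1, -1, NA))), "excluded")
})

test_that("normZ is insensitive to per-sample depth scaling", {
  sim <- simulate_screen(planted_screen_config(n_genes = 300, seed = 17))
  sc1 <- score_screen(sim, treated_phe = "6.63")
  sim2 <- sim
  sim2$counts <- dplyr::mutate(sim$counts, T11_ph6.63_R1 = T11_ph6.63_R1 * 5L)
  sc2 <- score_screen(sim2, treated_phe = "6.63")
  m <- dplyr::inner_join(sc1, sc2, by = "gene_id")
  # exact invariance is broken only by the pseudocount; at screen-scale
  # counts the effect is negligible
  expect_gt(cor(m$normZ.x, m$normZ.y), 0.999)
  expect_lt(max(abs(m$normZ.x - m$normZ.y)), 0.2)
})

test_that("planted acid-essential genes dominate the depleted extreme", {
  sim <- simulate_screen(planted_screen_config(n_genes = 500, seed = 23))
  sc <- score_screen(sim, treated_phe = "6.63", control_phe = "7.4")
  joined <- dplyr::left_join(sc, sim$truth[, c("gene_id", "class")],
                             by = "gene_id")
  med <- joined |>
    dplyr::group_by(class) |>
    dplyr::summarise(m = median(normZ))
  expect_equal(med$class[which.min(med$m)], "acid_essential")
  # the planted class occupies the extreme negative ranks
  top <- joined$class[joined$rank <= 10]
  expect_true(all(top == "acid_essential"))

  hits <- call_hits(sc, "depleted", 0.1)
  planted <- sim$truth$gene_id[sim$truth$class == "acid_essential"]
  expect_gte(mean(planted %in% hits$genes), 0.8)
  expect_true(all(hits$table$fdr_depletion < 0.1))
  expect_equal(hits$boundary_normZ, max(hits$table$normZ))
})

test_that("hit calling is calibrated on null screens and empty on flat input", {
  sim <- simulate_screen(null_screen_config(n_genes = 500, seed = 29))
  sc <- score_screen(sim, treated_phe = "6.63")
  hits <- call_hits(sc, "depleted", 0.1)
  expect_lte(length(hits$genes) / nrow(sc), 0.03)
  z0 <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), z = 0)
  expect_length(call_hits(gene_scores(z0), "depleted")$genes, 0)
  expect_error(call_hits(sc[0, ], "depleted"), "Empty")
})

test_that("gene p-values agree in rank with a guide-permutation null", {
  set.seed(47)
  n_genes <- 20
  guide_z <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:n_genes), each = 4),
    z = rnorm(n_genes * 4) + rep(rnorm(n_genes, 0, 0.8), each = 4)
  )
  sc <- gene_scores(guide_z)
  # permutation oracle: reshuffle guide-to-gene labels, recompute sumZ
  obs <- tapply(guide_z$z, guide_z$gene_id, sum)
  B <- 10000
  perm <- matrix(NA_real_, B, n_genes)
  for (b in 1:B) {
    shuffled <- sample(guide_z$z)
    perm[b, ] <- colSums(matrix(shuffled, nrow = 4))
  }
  p_perm <- sapply(seq_len(n_genes), function(g) {
    (1 + sum(perm[, g] <= obs[g])) / (B + 1)
  })
  rho <- cor(sc$p_depletion[match(names(obs), sc$gene_id)], p_perm,
             method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("set overlap arithmetic covers identical, disjoint and screen-scale cases", {
  mk <- function(genes) structure(list(direction = "depleted",
                                       fdr_threshold = 0.1, genes = genes,
                                       boundary_normZ = NA_real_,
                                       table = NULL), class = "hit_set")
  a <- mk(sprintf("g%d", 1:10))
  expect_equal(set_overlap(a, a)[1:3], list(only_a = 0, both = 10, only_b = 0))
  b <- mk(sprintf("h%d", 1:7))
  expect_equal(set_overlap(a, b)[1:3], list(only_a = 10, both = 0, only_b = 7))
  # published-screen-scale structure: 43 depleted at mild acid, 51 at high
  # acid, 26 shared
  mild <- mk(c(sprintf("s%02d", 1:26), sprintf("m%02d", 1:17)))
  high <- mk(c(sprintf("s%02d", 1:26), sprintf("h%02d", 1:25)))
  ov <- set_overlap(mild, high)
  expect_equal(ov$both, 26)
  expect_equal(ov$only_a + ov$both, 43)
  expect_equal(ov$only_b + ov$both, 51)
  enr <- mk(letters)
  enr$direction <- "enriched"
  expect_error(set_overlap(a, enr), "same direction")
})
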
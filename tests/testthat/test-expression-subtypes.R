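test_that("variance filter keeps the top-variance probes", {
  set.seed(3)
  values <- matrix(rnorm(10 * 6), 10, 6) * (1:10)  # variance rises with row
  mat <- expression_matrix(values)
  expect_equal(variance_filter(mat, 1)$values, mat$values)

  filt <- variance_filter(mat, 0.5)
  v <- apply(mat$values, 1, var)
  expect_setequal(filt$probe_ids, mat$probe_ids[order(-v)[1:5]])

  # a constant probe never survives against non-constant competition
  values[1, ] <- 5
  mat2 <- expression_matrix(values)
  expect_false(mat2$probe_ids[1] %in% variance_filter(mat2, 0.9)$probe_ids)

  expect_error(variance_filter(mat, 0), "keep_fraction")
  expect_error(variance_filter(mat, 1.2), "keep_fraction")
})

test_that("probe exclusion is a set difference", {
  mat <- expression_matrix(matrix(rnorm(20 * 4), 20, 4))
  expect_equal(exclude_probes(mat, character(0))$values, mat$values)
  expect_error(exclude_probes(mat, mat$probe_ids), "every probe")

  set.seed(5)
  bl <- sample(mat$probe_ids, 7)
  expect_message(out <- exclude_probes(mat, bl), "excluded")
  expect_setequal(out$probe_ids, setdiff(mat$probe_ids, bl))
})

test_that("filter(keep = 1) after excluding nothing is the identity", {
  mat <- expression_matrix(matrix(rnorm(30 * 5), 30, 5))
  out <- variance_filter(exclude_probes(mat, character(0)), 1)
  expect_equal(out$values, mat$values)
})

test_that("UPGMA clustering matches a hand-worked 4-sample toy", {
  # 1-D samples at 0, 2, 10, 14:
  #   d(A,B)=2, d(C,D)=4, then d(AB,CD) = mean(10,14,8,12) = 11
  values <- matrix(c(0, 2, 10, 14), nrow = 1,
                   dimnames = list("p1", c("A", "B", "C", "D")))
  cl <- hierarchical_cluster(expression_matrix(values))
  expect_equal(cl$hclust$height, c(2, 4, 11))
  # merge order: A+B first, C+D second, then the two clusters
  expect_equal(cl$hclust$merge[1, ], c(-1, -2))
  expect_equal(cl$hclust$merge[2, ], c(-3, -4))
  expect_equal(cl$hclust$merge[3, ], c(1, 2))
  # identical samples merge at height 0
  dup <- expression_matrix(matrix(c(1, 1, 5), nrow = 1,
                                  dimnames = list("p", c("x", "y", "z"))))
  expect_equal(hierarchical_cluster(dup)$hclust$height[1], 0)
})

test_that("UPGMA heights are non-decreasing and Newick round-trips tips", {
  set.seed(8)
  mat <- expression_matrix(matrix(rnorm(50 * 8), 50, 8))
  cl <- hierarchical_cluster(mat)
  expect_true(all(diff(cl$hclust$height) >= 0))
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, mat$sample_ids)
})

test_that("planted subgroups form the two top clades", {
  hits <- 0
  for (seed in 1:20) {
    truth <- expression_truth(rep(c("g1", "g2"), each = 5),
                              effects = list(s = list(group = "g1",
                                                      effect = 4)),
                              n_probes = 100, seed = seed)
    mat <- gen_expression_matrix(
      truth, list(marker_gene_set("s", sprintf("P%04d", 1:30))))
    hc <- hierarchical_cluster(mat)$hclust
    top2 <- cutree(hc, k = 2)
    if (length(unique(top2[1:5])) == 1 && length(unique(top2[6:10])) == 1)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("moderated t handles exact ties and refuses degenerate designs", {
  values <- matrix(rnorm(20 * 8), 20, 8)
  values[1, ] <- rep(c(1, 2, 3, 4), 2)   # identical group means
  mat <- expression_matrix(values,
                           sample_groups = rep(c("a", "b"), each = 4))
  de <- moderated_de(mat, "a", "b")
  expect_equal(de$t[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_true(all(de$adj_p_value >= de$p_value))
  expect_true(all(de$adj_p_value >= 0 & de$adj_p_value <= 1))
  expect_error(moderated_de(mat, "a", "b", groups = c(rep("a", 1),
                                                      rep("b", 7))),
               "at least 2")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(13)
  mat <- expression_matrix(matrix(rnorm(20 * 10), 20, 10),
                           sample_groups = rep(c("a", "b"), each = 5))
  de <- moderated_de(mat, "a", "b")
  p <- de$p_value
  n <- length(p)
  ord <- order(p)
  stepup <- numeric(n)   # brute-force: cummin of n*p/i from the largest down
  stepup[ord] <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  expect_equal(de$adj_p_value, pmin(1, stepup))
  # monotone in raw p
  expect_true(all(diff(de$adj_p_value[ord]) >= -1e-12))
})

test_that("moderated t matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(17)
  mat <- expression_matrix(matrix(rnorm(300 * 12), 300, 12),
                           sample_groups = rep(c("a", "b"), each = 6))
  mat$values[1:20, 1:6] <- mat$values[1:20, 1:6] + 1.5
  de <- moderated_de(mat, "a", "b")
  design <- cbind(b = 1, a_vs_b = rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(mat$values, design))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, "a_vs_b"]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, "a_vs_b"]),
               tolerance = 1e-8)
})

test_that("moderated t approaches the ordinary t as the prior df vanish", {
  set.seed(19)
  mat <- expression_matrix(matrix(rnorm(50 * 8), 50, 8),
                           sample_groups = rep(c("a", "b"), each = 4))
  de0 <- moderated_de(mat, "a", "b", prior_df = 1e-9, prior_var = 1)
  ordinary <- apply(mat$values, 1, function(x)
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic)
  expect_equal(de0$t, unname(ordinary), tolerance = 1e-6)
})

test_that("fold/FDR selection equals its predicate", {
  de <- data.frame(probe_id = paste0("p", 1:6),
                   logfc = c(2, 1.5, -1.2, 0.5, -3, 1),
                   t = 0, p_value = 0.001,
                   adj_p_value = c(0.001, 0.02, 0.005, 0.001, 0.001, 0.001),
                   direction = "up")
  class(de) <- c("de_result", class(de))
  sel <- select_by_fold_and_fdr(de, fold_min = 2, adj_p_max = 0.01)
  expect_equal(sel$up, c("p1", "p6"))     # logfc >= 1 and adj p < 0.01
  expect_equal(sel$down, c("p3", "p5"))   # logfc <= -1 and adj p < 0.01

  all_null <- transform(de, adj_p_value = 1)
  sel0 <- select_by_fold_and_fdr(all_null)
  expect_length(sel0$up, 0)
  expect_length(sel0$down, 0)

  # fold_min 1 reduces to FDR-only selection (log2 threshold 0)
  sel1 <- select_by_fold_and_fdr(de, fold_min = 1, adj_p_max = 0.01)
  expect_setequal(c(sel1$up, sel1$down),
                  de$probe_id[de$adj_p_value < 0.01 & de$logfc != 0])
})

test_that("signature overlap reproduces published-style percentages", {
  q_up <- paste0("u", 1:80)
  q_dn <- paste0("d", 1:19)
  ov <- signature_overlap(q_up, q_dn,
                          reference_up = c(paste0("u", 1:51), "zz"),
                          reference_down = paste0("d", 1:15))
  expect_equal(ov$up$n_overlap, 51)
  expect_equal(ov$up$percent, 64)
  expect_equal(ov$down$n_overlap, 15)
  expect_equal(ov$down$percent, 79)

  expect_equal(signature_overlap("a", "b", "x", "y")$up$percent, 0)
  expect_equal(signature_overlap(c("a", "b"), character(0),
                                 c("a", "b", "c"), "y")$up$percent, 100)
  expect_true(is.na(signature_overlap(character(0), "b",
                                      "x", "y")$up$percent))
})

test_that("metagene scoring: rank-1 identity, shift response and sign anchor", {
  # rank-1: all marker genes proportional to one sample pattern
  pattern <- c(-2, -1, 0, 1, 2, 3)
  values <- outer(c(1, 2, 0.5, 1.5), pattern)
  dimnames(values) <- list(paste0("g", 1:4), paste0("s", 1:6))
  mat <- expression_matrix(values)
  ms <- marker_gene_set("stage", paste0("g", 1:4))
  sc <- metagene_scores(mat, ms)
  expect_equal(sc$variance_explained, 1, tolerance = 1e-8)
  expect_gt(cor(sc$scores, pattern), 1 - 1e-8)

  # the anchor resolves SVD sign only: negating the data negates the score
  neg <- expression_matrix(-values)
  sc_neg <- metagene_scores(neg, ms)
  expect_equal(unname(sc_neg$scores), unname(-sc$scores), tolerance = 1e-8)

  # shifted subgroup scores strictly higher on average
  truth <- expression_truth(rep(c("hi", "lo"), each = 6),
                            effects = list(stage = list(group = "hi",
                                                        effect = 3)),
                            n_probes = 200, seed = 29)
  m2 <- gen_expression_matrix(truth,
                              list(marker_gene_set("stage",
                                                   sprintf("P%04d", 1:15))))
  sc2 <- metagene_scores(m2, marker_gene_set("stage", sprintf("P%04d", 1:15)))
  g <- rep(c("hi", "lo"), each = 6)
  expect_gt(mean(sc2$scores[g == "hi"]), mean(sc2$scores[g == "lo"]))
})

test_that("metagene score is invariant to per-gene affine rescaling", {
  set.seed(23)
  values <- matrix(rnorm(8 * 10), 8, 10)
  mat <- expression_matrix(values)
  ms <- marker_gene_set("s", mat$probe_ids)
  base <- metagene_scores(mat, ms)
  rescaled <- expression_matrix(values * runif(8, 0.5, 4) + rnorm(8))
  again <- metagene_scores(rescaled, ms)
  expect_equal(unname(again$scores), unname(base$scores), tolerance = 1e-8)
})

test_that("metagene scoring drops degenerate genes and refuses tiny sets", {
  values <- matrix(rnorm(3 * 6), 3, 6)
  values[1, ] <- 7
  mat <- expression_matrix(values)
  expect_warning(sc <- metagene_scores(mat, marker_gene_set("s", mat$probe_ids)),
                 "zero-variance")
  expect_equal(sc$n_genes, 2)
  expect_error(
    suppressWarnings(metagene_scores(
      mat, marker_gene_set("s", mat$probe_ids[1:2]))),
    "fewer than 2")
})

test_that("metagene group comparison: null uniformity, power, degenerate ties", {
  # equal values in 2 vs 2: no evidence at all
  expect_equal(compare_metagene(c(a = 1, b = 1, c = 1, d = 1),
                                c("x", "x", "y", "y"))$p_value, 1)

  # null: p values uniform across replicates (KS)
  set.seed(37)
  pvals <- replicate(200, {
    sc <- rnorm(10)
    compare_metagene(sc, rep(c("x", "y"), each = 5))$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  # groups 5 sd apart: decisive in nearly every seed
  hits <- sum(vapply(1:100, function(s) {
    set.seed(s)
    sc <- c(rnorm(5), rnorm(5, mean = 5))
    compare_metagene(sc, rep(c("x", "y"), each = 5))$p_value < 0.01
  }, logical(1)))
  expect_gte(hits, 95)
})
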
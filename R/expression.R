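## Expression-subtype analysis: filtering, clustering, moderated
## differential expression, signature overlap and metagene scoring.

#' Construct an expression matrix container
#'
#' @param values Numeric matrix, probes × samples, log-scale (e.g. RMA
#'   output), no missing values.
#' @param sample_groups Optional per-sample group labels.
#' @return A list of class `expression_matrix` with `values`, `probe_ids`,
#'   `sample_ids`, `sample_groups`.
#' @export
expression_matrix <- function(values, sample_groups = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (!is.null(sample_groups) && length(sample_groups) != ncol(values))
    stop("sample_groups length must match the number of samples")
  structure(list(values = values, probe_ids = rownames(values),
                 sample_ids = colnames(values),
                 sample_groups = sample_groups),
            class = "expression_matrix")
}

#' Define a developmental-stage marker gene set
#'
#' @param stage_name Stage label (e.g. a nephrogenesis stage).
#' @param gene_ids Non-empty vector of unique gene/probe ids.
#' @return A list of class `marker_gene_set`.
#' @export
marker_gene_set <- function(stage_name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0) stop("gene_ids must be non-empty")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  structure(list(stage_name = stage_name, gene_ids = gene_ids),
            class = "marker_gene_set")
}

#' Keep the most variable probes
#'
#' Probes are ranked by inter-sample variance and the top
#' `ceil(keep_fraction * n)` retained; ties are broken by original probe
#' order.
#'
#' @param mat An [expression_matrix()].
#' @param keep_fraction Fraction of probes to keep, in (0, 1\].
#' @return The filtered [expression_matrix()].
#' @export
variance_filter <- function(mat, keep_fraction = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (ncol(mat$values) < 2) stop("need at least 2 samples")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("`keep_fraction` must be in (0, 1]")
  v <- apply(mat$values, 1, stats::var)
  n_keep <- ceiling(keep_fraction * nrow(mat$values))
  keep <- sort(order(-v)[seq_len(n_keep)])  # order() is stable: ties by row
  expression_matrix(mat$values[keep, , drop = FALSE], mat$sample_groups)
}

#' Remove blacklisted probes
#'
#' Drops probes with known cross-hybridisation (or otherwise unreliable)
#' ids.
#'
#' @param mat An [expression_matrix()].
#' @param blacklist Character vector of probe ids to remove.
#' @return The filtered [expression_matrix()].
#' @export
exclude_probes <- function(mat, blacklist) {
  stopifnot(inherits(mat, "expression_matrix"))
  drop <- mat$probe_ids %in% blacklist
  if (all(drop)) stop("blacklist removes every probe")
  if (any(drop)) message(sum(drop), " probe(s) excluded")
  expression_matrix(mat$values[!drop, , drop = FALSE], mat$sample_groups)
}

#' Average-linkage hierarchical clustering of samples
#'
#' Samples are clustered on Euclidean distance over the retained probes with
#' average (UPGMA) linkage; the dendrogram is also serialised to Newick.
#'
#' @param mat An [expression_matrix()].
#' @return A list: `hclust` (the [stats::hclust()] object), `order` (sample
#'   ids in dendrogram order), `newick` (Newick string).
#' @export
hierarchical_cluster <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (ncol(mat$values) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::dist(t(mat$values)), method = "average")
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}

## Invert the trigamma function by Newton iteration on 1/trigamma
## (monotone, near-linear), as used to back out the prior degrees of
## freedom from the spread of log sample variances.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' For each probe the two-group mean difference on the log scale (log fold
#' change, `group_a` minus `group_b`) is tested with a moderated
#' t-statistic: probe-wise pooled variances are shrunk toward a common prior
#' estimated by marginal moment matching on the log sample variances. With
#' probe variance \eqn{s_g^2} on \eqn{d} residual df and prior
#' \eqn{s_0^2} on \eqn{d_0} df, the posterior variance is
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)} and the moderated t
#' has \eqn{d_0 + d} degrees of freedom. Benjamini-Hochberg step-up adjusted
#' p values control the FDR across probes.
#'
#' @param mat An [expression_matrix()] with `sample_groups` set (or pass
#'   `groups`).
#' @param group_a,group_b Labels of the two groups to compare; each must
#'   have at least 2 samples (otherwise there are no residual df to moderate
#'   and the test refuses).
#' @param groups Optional per-sample labels overriding `mat$sample_groups`.
#' @param prior_df,prior_var Optional overrides of the estimated prior
#'   degrees of freedom and prior variance (mainly for study of the
#'   ordinary-t limit as `prior_df` → 0).
#' @return A data.frame of class `de_result`: `probe_id`, `logfc`,
#'   `t` (moderated), `p_value`, `adj_p_value` (BH), `direction`
#'   (`"up"`/`"down"`/`"none"`); prior estimates in attributes `prior_df`
#'   and `prior_var`.
#' @export
moderated_de <- function(mat, group_a, group_b, groups = NULL,
                         prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (is.null(groups)) groups <- mat$sample_groups
  if (is.null(groups)) stop("no sample groups supplied")
  a <- which(groups == group_a)
  b <- which(groups == group_b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 samples (insufficient residual df)")
  xa <- mat$values[, a, drop = FALSE]
  xb <- mat$values[, b, drop = FALSE]
  lfc <- rowMeans(xa) - rowMeans(xb)
  d <- na + nb - 2
  s2 <- (rowSums((xa - rowMeans(xa))^2) +
           rowSums((xb - rowMeans(xb))^2)) / d

  if (is.null(prior_df) || is.null(prior_var)) {
    z <- log(s2[s2 > 0])
    if (length(z) < 2) stop("too few probes with positive variance")
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
    if (is.null(prior_df)) prior_df <- d0
    if (is.null(prior_var)) prior_var <- s02
  }
  s2_post <- if (is.infinite(prior_df)) rep(prior_var, length(s2)) else
    (prior_df * prior_var + d * s2) / (prior_df + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d + prior_df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(probe_id = mat$probe_ids, logfc = lfc, t = tstat,
                    p_value = p, adj_p_value = adj,
                    direction = ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  attr(out, "residual_df") <- d
  class(out) <- c("de_result", class(out))
  out
}

#' Select probes by fold change and FDR
#'
#' @param de A `de_result` from [moderated_de()].
#' @param fold_min Minimum fold change (linear scale); interpreted as
#'   `|log2 FC| >= log2(fold_min)` on the log2 expression scale.
#' @param adj_p_max Adjusted-p cutoff (strict `<`).
#' @return List with `up` and `down` probe-id vectors.
#' @export
select_by_fold_and_fdr <- function(de, fold_min = 2.0, adj_p_max = 0.01) {
  lf <- log2(fold_min)
  sig <- de$adj_p_value < adj_p_max
  list(up = de$probe_id[sig & de$logfc >= lf],
       down = de$probe_id[sig & de$logfc <= -lf])
}

#' Cross-cohort signature overlap
#'
#' For each direction, the number of query probes also present in the
#' reference signature and the percentage of the query covered, rounded to
#' the nearest integer. Assumes the id universes have already been
#' restricted to probes present in both cohorts.
#'
#' @param query_up,query_down Probe ids differentially expressed in the
#'   query cohort.
#' @param reference_up,reference_down Probe ids from the reference cohort.
#' @return A list with per-direction `n_query`, `n_overlap`, `percent`
#'   (NA when the query is empty).
#' @export
signature_overlap <- function(query_up, query_down,
                              reference_up, reference_down) {
  one <- function(q, ref) {
    n <- length(unique(q))
    k <- length(intersect(q, ref))
    list(n_query = n, n_overlap = k,
         percent = if (n == 0) NA_real_ else round(100 * k / n))
  }
  list(up = one(query_up, reference_up),
       down = one(query_down, reference_down))
}

#' SVD metagene score for a marker gene set
#'
#' The marker genes' rows are z-scaled (mean 0, sd 1 per gene across
#' samples) and the per-sample metagene score is taken from the first
#' singular component of the scaled submatrix: the first right singular
#' vector scaled by the first singular value (or unscaled when
#' `scale_by_singular_value = FALSE`). The SVD's sign ambiguity is resolved
#' by requiring positive correlation between the score and the mean z-scaled
#' marker expression, so that higher scores mean coherently higher marker
#' expression. Zero-variance genes are dropped with a warning.
#'
#' @param mat An [expression_matrix()].
#' @param marker_set A [marker_gene_set()]; at least 2 usable genes must be
#'   present in the matrix.
#' @param scale_by_singular_value Scale scores by the first singular value
#'   (default TRUE).
#' @return A list of class `metagene_score`: `stage_name`, `scores` (named
#'   per sample), `variance_explained` by the first component, `n_genes`
#'   used, `sign_anchor` description.
#' @export
metagene_scores <- function(mat, marker_set, scale_by_singular_value = TRUE) {
  stopifnot(inherits(mat, "expression_matrix"),
            inherits(marker_set, "marker_gene_set"))
  present <- intersect(marker_set$gene_ids, mat$probe_ids)
  sub <- mat$values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker gene(s) dropped")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2)
    stop("fewer than 2 usable marker genes in the matrix")
  z <- t(scale(t(sub)))
  sv <- svd(z)
  score <- sv$v[, 1]
  if (scale_by_singular_value) score <- score * sv$d[1]
  anchor <- colMeans(z)
  if (sum(score * anchor) < 0) score <- -score
  names(score) <- mat$sample_ids
  structure(list(stage_name = marker_set$stage_name, scores = score,
                 variance_explained = sv$d[1]^2 / sum(sv$d^2),
                 n_genes = nrow(z),
                 sign_anchor = "positive correlation with mean marker z-score"),
            class = "metagene_score")
}

#' Compare metagene scores between two groups
#'
#' Two-sided Welch two-sample test on the per-sample metagene scores. The p
#' value is reported raw and explicitly uncorrected for multiple
#' comparisons (correction across stages, if wanted, is the caller's
#' business).
#'
#' @param scores A `metagene_score` (or a named numeric vector of scores).
#' @param groups Per-sample group labels aligned with the scores.
#' @param group_a,group_b The two group labels to compare (default: the two
#'   unique labels present).
#' @return A list: `stage_name`, `p_value` (raw), `mean_a`, `mean_b`,
#'   `corrected` = FALSE.
#' @export
compare_metagene <- function(scores, groups, group_a = NULL, group_b = NULL) {
  x <- if (inherits(scores, "metagene_score")) scores$scores else scores
  stage <- if (inherits(scores, "metagene_score")) scores$stage_name else NA
  if (length(groups) != length(x))
    stop("groups must align with the scores")
  labs <- unique(groups)
  if (is.null(group_a)) group_a <- labs[1]
  if (is.null(group_b)) group_b <- setdiff(labs, group_a)[1]
  xa <- x[groups == group_a]
  xb <- x[groups == group_b]
  if (length(xa) < 2 || length(xb) < 2)
    stop("each group needs at least 2 samples")
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    p <- if (mean(xa) == mean(xb)) 1 else 0   # degenerate: no within-group variance
  } else {
    p <- stats::t.test(xa, xb)$p.value
  }
  list(stage_name = stage, p_value = p, mean_a = mean(xa), mean_b = mean(xb),
       corrected = FALSE)
}
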
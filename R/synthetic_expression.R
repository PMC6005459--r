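#' Describe the truth for a simulated expression matrix
#'
#' @param group_labels Character vector of per-sample group labels (length =
#'   number of samples).
#' @param effects Named list: for each marker-set stage name, a list with
#'   `group` (the designated subgroup) and `effect` (z-score shift added to
#'   that stage's marker genes in that subgroup's samples).
#' @param noise_sd Residual standard deviation (> 0) on the log scale.
#' @param n_probes Number of probes in the universe.
#' @param seed Integer RNG seed.
#' @return A list of class `expression_truth`.
#' @export
expression_truth <- function(group_labels, effects = list(), noise_sd = 1,
                             n_probes = 1000, seed = 1) {
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  eff <- unlist(lapply(effects, `[[`, "effect"))
  if (length(eff) && any(!is.finite(eff))) stop("effect sizes must be finite")
  if (n_probes < 1) stop("`n_probes` must be >= 1")
  structure(list(group_labels = as.character(group_labels), effects = effects,
                 noise_sd = noise_sd, n_probes = as.integer(n_probes),
                 seed = as.integer(seed)),
            class = "expression_truth")
}

#' Simulate a log-scale expression matrix with marker-set shifts
#'
#' Background values are i.i.d. normal with sd `noise_sd`; for each marker
#' set with a declared effect, the set's probes are shifted by
#' `effect * noise_sd` in the designated subgroup's samples. This emulates
#' developmental-stage marker genes being coherently up-regulated in one
#' tumour subtype against a flat background.
#'
#' @param truth An [expression_truth()].
#' @param marker_sets List of [marker_gene_set()] objects. Their gene ids
#'   must exist in the probe universe `P0001 ... P<n_probes>`; sets must be
#'   pairwise disjoint unless `allow_overlap = TRUE`.
#' @param allow_overlap Permit overlapping marker sets.
#' @return An [expression_matrix()] with truth group labels attached.
#' @export
gen_expression_matrix <- function(truth, marker_sets = list(),
                                  allow_overlap = FALSE) {
  stopifnot(inherits(truth, "expression_truth"))
  set.seed(truth$seed)
  n_s <- length(truth$group_labels)
  probes <- sprintf("P%04d", seq_len(truth$n_probes))
  samples <- sprintf("S%03d", seq_len(n_s))
  all_genes <- unlist(lapply(marker_sets, `[[`, "gene_ids"))
  if (length(all_genes)) {
    missing <- setdiff(all_genes, probes)
    if (length(missing))
      stop("marker genes absent from probe universe: ",
           paste(utils::head(missing, 5), collapse = ", "))
    if (!allow_overlap && anyDuplicated(all_genes))
      stop("marker sets overlap; set `allow_overlap = TRUE` to permit")
  }
  values <- matrix(stats::rnorm(truth$n_probes * n_s, sd = truth$noise_sd),
                   nrow = truth$n_probes, dimnames = list(probes, samples))
  for (ms in marker_sets) {
    spec <- truth$effects[[ms$stage_name]]
    if (is.null(spec) || spec$effect == 0) next
    cols <- truth$group_labels == spec$group
    if (!any(cols)) stop("designated subgroup not present: ", spec$group)
    values[ms$gene_ids, cols] <-
      values[ms$gene_ids, cols] + spec$effect * truth$noise_sd
  }
  expression_matrix(values, sample_groups = truth$group_labels)
}
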
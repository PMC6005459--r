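## Top-level configuration and the end-to-end synthetic pipeline binding
## the three analysis strands.

#' Build a validated pipeline configuration
#'
#' Collects every tunable threshold of the three strands plus the
#' synthetic-data parameters, validates ranges up front (before any
#' compute), and round-trips losslessly through YAML.
#'
#' @param seed Integer master seed; every stage derives its RNG stream from
#'   it, so a run is fully reproducible.
#' @param out_dir Output directory.
#' @param strands Subset of `c("baf", "bisulfite", "expression")`.
#' @param gq_min,depth_min,depth_max Heterozygous-site filters.
#' @param dense_min,unmeth_max,min_called Epiallele classification
#'   thresholds.
#' @param min_identity Read/template identity floor for strand assignment.
#' @param keep_fraction Variance-filter retention fraction.
#' @param fold_min,adj_p_max Differential-expression selection thresholds.
#' @param tumour_purity,mean_depth,site_density Synthetic CNV parameters.
#' @param dense_fraction,n_reads Synthetic bisulfite mixture parameters.
#' @param n_probes,n_per_group,marker_effect Synthetic expression
#'   parameters.
#' @param verbose Emit stage-prefixed progress messages to stderr.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("epitrio_run_"),
                            strands = c("baf", "bisulfite", "expression"),
                            gq_min = 14, depth_min = 11, depth_max = 1001,
                            dense_min = 0.9, unmeth_max = 0.1,
                            min_called = 5, min_identity = 0.8,
                            keep_fraction = 0.5, fold_min = 2,
                            adj_p_max = 0.01,
                            tumour_purity = 0.8, mean_depth = 100,
                            site_density = 20,
                            dense_fraction = 0.395, n_reads = 1043,
                            n_probes = 1000, n_per_group = 8,
                            marker_effect = 3, verbose = TRUE) {
  strands <- match.arg(strands, several.ok = TRUE)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, strands = strands,
              gq_min = gq_min, depth_min = depth_min, depth_max = depth_max,
              dense_min = dense_min, unmeth_max = unmeth_max,
              min_called = min_called, min_identity = min_identity,
              keep_fraction = keep_fraction, fold_min = fold_min,
              adj_p_max = adj_p_max, tumour_purity = tumour_purity,
              mean_depth = mean_depth, site_density = site_density,
              dense_fraction = dense_fraction, n_reads = as.integer(n_reads),
              n_probes = as.integer(n_probes),
              n_per_group = as.integer(n_per_group),
              marker_effect = marker_effect, verbose = isTRUE(verbose))
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$gq_min >= 0, "gq_min must be >= 0")
  chk(cfg$depth_min >= 1 && cfg$depth_max >= cfg$depth_min,
      "need 1 <= depth_min <= depth_max")
  chk(cfg$dense_min > 0 && cfg$dense_min <= 1 &&
        cfg$unmeth_max >= 0 && cfg$unmeth_max < cfg$dense_min,
      "need 0 <= unmeth_max < dense_min <= 1")
  chk(cfg$min_called >= 1, "min_called must be >= 1")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1,
      "min_identity must be in (0, 1]")
  chk(cfg$keep_fraction > 0 && cfg$keep_fraction <= 1,
      "keep_fraction must be in (0, 1]")
  chk(cfg$fold_min >= 1, "fold_min must be >= 1")
  chk(cfg$adj_p_max > 0 && cfg$adj_p_max <= 1, "adj_p_max must be in (0, 1]")
  chk(cfg$tumour_purity >= 0 && cfg$tumour_purity <= 1,
      "tumour_purity must be in [0, 1]")
  chk(cfg$dense_fraction >= 0 && cfg$dense_fraction <= 1,
      "dense_fraction must be in [0, 1]")
  chk(cfg$mean_depth >= 1, "mean_depth must be >= 1")
  chk(cfg$n_reads >= 1 && cfg$n_probes >= 1 && cfg$n_per_group >= 2,
      "n_reads/n_probes >= 1 and n_per_group >= 2 required")
  invisible(cfg)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `write_config` the path invisibly; `read_config` the validated
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_msg <- function(cfg, stage, ...) {
  if (cfg$verbose) message("[", stage, "] ", ...)
}

## The default synthetic genome: three chromosomes with one implanted
## cn-LOH, loss and gain segment respectively, the rest neutral.
default_truth_genome <- function(purity) {
  cnv_truth_segments(
    cnv_truth_segment("chr1", 1,        40e6, "neutral_het", purity),
    cnv_truth_segment("chr1", 40e6 + 1, 60e6, "cn_loh",      purity),
    cnv_truth_segment("chr1", 60e6 + 1, 100e6, "neutral_het", purity),
    cnv_truth_segment("chr2", 1,        45e6, "neutral_het", purity),
    cnv_truth_segment("chr2", 45e6 + 1, 65e6, "loss",        purity),
    cnv_truth_segment("chr2", 65e6 + 1, 100e6, "neutral_het", purity),
    cnv_truth_segment("chr3", 1,        50e6, "neutral_het", purity),
    cnv_truth_segment("chr3", 50e6 + 1, 70e6, "gain",        purity),
    cnv_truth_segment("chr3", 70e6 + 1, 100e6, "neutral_het", purity))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates truth-known inputs for the requested strands, executes each
#' strand, writes per-stage outputs under `cfg$out_dir`, and returns (and
#' writes as `summary.json`) a single machine-readable summary: the
#' fractional copy-number aberration score and per-site state accuracy;
#' epiallele fractions; differential-expression counts and marker-set
#' overlap percentages; metagene group-comparison p values. Byte-identical
#' across runs with the same configuration.
#'
#' @param cfg A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = cfg$seed)

  if ("baf" %in% cfg$strands) {
    stage_msg(cfg, "baf", "simulating tumour/normal sites")
    truth <- default_truth_genome(cfg$tumour_purity)
    sites <- gen_tumour_normal_sites(truth, site_density = cfg$site_density,
                                     mean_depth = cfg$mean_depth,
                                     seed = cfg$seed)
    write_sites_vcf(sites, file.path(cfg$out_dir, "sites.vcf"))
    kept <- filter_heterozygous_sites(sites, cfg$gq_min, cfg$depth_min,
                                      cfg$depth_max)
    track <- compute_baf_track(kept)
    res <- segment_states(track)
    write_segments_tsv(res, file.path(cfg$out_dir, "segments.tsv"))
    write_segments_bed(res, file.path(cfg$out_dir, "segments.bed"))
    write_runs_tsv(res, file.path(cfg$out_dir, "loh_runs.tsv"))
    truth_state <- ifelse(kept$truth_state == "neutral_het", "neutral",
                          kept$truth_state)
    summary$baf <- list(
      n_sites = nrow(kept),
      fractional_cna_score = res$fractional_cna_score,
      state_accuracy = mean(res$site_states == truth_state),
      n_loh_runs = nrow(res$loh_runs))
    stage_msg(cfg, "baf", sprintf("score %.4f, accuracy %.3f",
                                  summary$baf$fractional_cna_score,
                                  summary$baf$state_accuracy))
  }

  if ("bisulfite" %in% cfg$strands) {
    stage_msg(cfg, "bisulfite", "simulating amplicon reads")
    ref <- synthetic_amplicon(seed = cfg$seed)
    write_amplicon_fasta(ref, file.path(cfg$out_dir, "amplicon.fasta"))
    sim <- gen_bisulfite_reads(ref, epiallele_truth(
      dense_fraction = cfg$dense_fraction, n_reads = cfg$n_reads,
      seed = cfg$seed))
    names(sim$reads) <- sim$read_ids
    write_fastq(sim$reads, file.path(cfg$out_dir, "reads.fastq"))
    m <- assign_and_call(sim$reads, ref, min_identity = cfg$min_identity)
    utils::write.table(per_cpg_proportions(m),
                       file.path(cfg$out_dir, "per_cpg_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_lollipop(m, file.path(cfg$out_dir, "lollipop.tsv"))
    cls <- classify_epialleles(m, cfg$dense_min, cfg$unmeth_max,
                               cfg$min_called)
    summary$bisulfite <- list(
      n_reads = cls$n_reads, n_dense = cls$n_dense,
      dense_fraction = cls$dense_fraction,
      dense_ci = unname(cls$dense_ci),
      truth_dense_fraction = cfg$dense_fraction)
    stage_msg(cfg, "bisulfite",
              sprintf("dense fraction %.3f (truth %.3f)",
                      cls$dense_fraction, cfg$dense_fraction))
  }

  if ("expression" %in% cfg$strands) {
    stage_msg(cfg, "expression", "simulating expression matrix")
    groups <- rep(c("S1", "other"), each = cfg$n_per_group)
    marker_sets <- list(
      marker_gene_set("stage_I_II", sprintf("P%04d", 1:20)),
      marker_gene_set("stage_III_IV", sprintf("P%04d", 21:40)))
    truth <- expression_truth(
      groups,
      effects = list(stage_I_II = list(group = "S1",
                                       effect = cfg$marker_effect)),
      n_probes = cfg$n_probes, seed = cfg$seed)
    mat <- gen_expression_matrix(truth, marker_sets)
    write_expression_tsv(mat, file.path(cfg$out_dir, "expression.tsv"),
                         file.path(cfg$out_dir, "sample_groups.tsv"))
    write_gmt(marker_sets, file.path(cfg$out_dir, "marker_sets.gmt"))
    filt <- variance_filter(mat, cfg$keep_fraction)
    clus <- hierarchical_cluster(filt)
    writeLines(clus$newick, file.path(cfg$out_dir, "dendrogram.nwk"))
    de <- moderated_de(mat, "S1", "other")
    utils::write.table(de, file.path(cfg$out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- select_by_fold_and_fdr(de, cfg$fold_min, cfg$adj_p_max)
    ov <- signature_overlap(sel$up, sel$down,
                            marker_sets[[1]]$gene_ids, character(0))
    meta <- lapply(marker_sets, function(ms) metagene_scores(mat, ms))
    meta_p <- vapply(meta, function(sc)
      compare_metagene(sc, groups, "S1", "other")$p_value, numeric(1))
    names(meta_p) <- vapply(marker_sets, `[[`, character(1), "stage_name")
    utils::write.table(
      data.frame(sample_id = mat$sample_ids, group = groups,
                 do.call(cbind, lapply(meta, `[[`, "scores"))),
      file.path(cfg$out_dir, "metagene_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    summary$expression <- list(
      n_up = length(sel$up), n_down = length(sel$down),
      marker_overlap_percent = ov$up$percent,
      metagene_p = as.list(meta_p))
    stage_msg(cfg, "expression",
              sprintf("%d up / %d down probes; shifted-set metagene p %.2g",
                      length(sel$up), length(sel$down),
                      meta_p["stage_I_II"]))
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(cfg$out_dir, "summary.json"))
  invisible(summary)
}
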
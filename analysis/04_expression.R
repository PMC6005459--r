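#!/usr/bin/env Rscript

# Expression strand: variance-filter the simulated matrix, cluster samples
# (Euclidean / average linkage), run moderated differential expression with
# BH correction, select two-fold / FDR<0.01 probes, measure their overlap
# with the implanted marker set, and score developmental-stage metagenes.

suppressPackageStartupMessages(library(epitrio))
data_dir <- "results/data"
out <- "results/expression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mat <- read_expression_tsv(file.path(data_dir, "expression.tsv"),
                           file.path(data_dir, "sample_groups.tsv"))
marker_sets <- read_gmt(file.path(data_dir, "marker_sets.gmt"))
groups <- mat$sample_groups

filt <- variance_filter(mat, 0.5)
cat(sprintf("variance filter: %d of %d probes retained\n",
            nrow(filt$values), nrow(mat$values)))
clus <- hierarchical_cluster(filt)
writeLines(clus$newick, file.path(out, "dendrogram.nwk"))
top2 <- cutree(clus$hclust, k = 2)
cat(sprintf("top-2 clades split samples %d / %d\n",
            sum(top2 == 1), sum(top2 == 2)))

de <- moderated_de(mat, "S1", "other")
write.table(de, file.path(out, "de_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sel <- select_by_fold_and_fdr(de, fold_min = 2, adj_p_max = 0.01)
cat(sprintf("DE: %d up, %d down at two-fold and adjusted p < 0.01\n",
            length(sel$up), length(sel$down)))

ov <- signature_overlap(sel$up, sel$down,
                        marker_sets[[1]]$gene_ids, character(0))
cat(sprintf("up-probes overlapping the implanted marker set: %d of %d (%d%%)\n",
            ov$up$n_overlap, ov$up$n_query, ov$up$percent))

meta <- lapply(marker_sets, function(ms) metagene_scores(mat, ms))
cmp <- lapply(meta, compare_metagene, groups = groups,
              group_a = "S1", group_b = "other")
for (x in cmp)
  cat(sprintf("metagene %-14s p = %.3g (uncorrected), S1 mean %.2f vs %.2f\n",
              x$stage_name, x$p_value, x$mean_a, x$mean_b))
write.table(
  data.frame(sample_id = mat$sample_ids, group = groups,
             sapply(meta, `[[`, "scores")),
  file.path(out, "metagene_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

jsonlite::write_json(
  list(n_up = length(sel$up), n_down = length(sel$down),
       marker_overlap_percent = ov$up$percent,
       metagene_p = setNames(lapply(cmp, `[[`, "p_value"),
                             vapply(cmp, `[[`, character(1), "stage_name"))),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
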
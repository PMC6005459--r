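#!/usr/bin/env Rscript

# Generate truth-known synthetic inputs for the three analysis strands:
#   - paired tumour/normal heterozygous-site VCF with implanted cn-LOH,
#     loss and gain segments at purity 0.8,
#   - bisulfite amplicon reads from a 39.5% dense / 60.5% unmethylated
#     epiallele mixture over a 253 bp, 23-CpG amplicon,
#   - a log-scale expression matrix with one subgroup's stage-I/II marker
#     genes shifted up by 3 sd.
# Outputs land in results/data/ and are consumed by scripts 02-04.

suppressPackageStartupMessages(library(epitrio))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## CNV strand: three 100 Mb chromosomes, one 20 Mb event each
purity <- 0.8
truth <- cnv_truth_segments(
  cnv_truth_segment("chr1", 1, 40e6, "neutral_het", purity),
  cnv_truth_segment("chr1", 40e6 + 1, 60e6, "cn_loh", purity),
  cnv_truth_segment("chr1", 60e6 + 1, 100e6, "neutral_het", purity),
  cnv_truth_segment("chr2", 1, 45e6, "neutral_het", purity),
  cnv_truth_segment("chr2", 45e6 + 1, 65e6, "loss", purity),
  cnv_truth_segment("chr2", 65e6 + 1, 100e6, "neutral_het", purity),
  cnv_truth_segment("chr3", 1, 50e6, "neutral_het", purity),
  cnv_truth_segment("chr3", 50e6 + 1, 70e6, "gain", purity),
  cnv_truth_segment("chr3", 70e6 + 1, 100e6, "neutral_het", purity))
sites <- gen_tumour_normal_sites(truth, site_density = 2000 / 300,
                                 mean_depth = 100, seed = seed)
write_sites_vcf(sites, file.path(out, "sites.vcf"))
write.table(sites, file.path(out, "sites_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("CNV strand: %d sites across 3 chromosomes (purity %.1f)\n",
            nrow(sites), purity))

## bisulfite strand
ref <- synthetic_amplicon(length = 253, n_cpg = 23, seed = seed)
write_amplicon_fasta(ref, file.path(out, "amplicon.fasta"))
sim <- gen_bisulfite_reads(ref, epiallele_truth(
  dense_fraction = 0.395, n_reads = 1043, seed = seed))
names(sim$reads) <- sim$read_ids
write_fastq(sim$reads, file.path(out, "reads.fastq"))
write.table(sim$truth, file.path(out, "reads_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("bisulfite strand: %d reads, %.1f%% truly dense\n",
            length(sim$reads), 100 * mean(sim$truth$class == "dense")))

## expression strand: 8 vs 8 samples, two marker sets, one shifted
groups <- rep(c("S1", "other"), each = 8)
marker_sets <- list(marker_gene_set("stage_I_II", sprintf("P%04d", 1:20)),
                    marker_gene_set("stage_III_IV", sprintf("P%04d", 21:40)))
etruth <- expression_truth(groups,
                           effects = list(stage_I_II = list(group = "S1",
                                                            effect = 3)),
                           n_probes = 1000, seed = seed)
mat <- gen_expression_matrix(etruth, marker_sets)
write_expression_tsv(mat, file.path(out, "expression.tsv"),
                     file.path(out, "sample_groups.tsv"))
write_gmt(marker_sets, file.path(out, "marker_sets.gmt"))
cat(sprintf("expression strand: %d probes x %d samples\n",
            nrow(mat$values), ncol(mat$values)))
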
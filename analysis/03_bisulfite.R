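#!/usr/bin/env Rscript

# Bisulfite strand: call per-read per-CpG methylation from the simulated
# amplicon FASTQ, quantify per-CpG proportions, classify epialleles, and
# work the mosaicism arithmetic on published-style count tables (dense-read
# counts, mutation allele fraction, doubled cell fraction).

suppressPackageStartupMessages(library(epitrio))
data_dir <- "results/data"
out <- "results/bisulfite"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- read_amplicon_fasta(file.path(data_dir, "amplicon.fasta"))
reads <- read_fastq(file.path(data_dir, "reads.fastq"))
truth <- read.delim(file.path(data_dir, "reads_truth.tsv"))

m <- assign_and_call(reads, ref)
prop <- per_cpg_proportions(m)
write.table(prop, file.path(out, "per_cpg_proportions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_lollipop(m, file.path(out, "lollipop.tsv"))

cls <- classify_epialleles(m)
print(cls)
truth_f <- mean(truth$class == "dense")
cat(sprintf("truth dense fraction this run: %.3f; estimate %.3f\n",
            truth_f, cls$dense_fraction))

# worked mosaicism arithmetic on the published-style count tables
tumour_adjacent <- classify_epialleles(
  methylation_call_matrix(rbind(matrix(1, 24, 23), matrix(0, 1733, 23))))
replicate_b <- classify_epialleles(
  methylation_call_matrix(rbind(matrix(1, 8, 23), matrix(0, 653, 23))))
cat(sprintf("adjacent kidney: %.1f%%; independent replicate: %.1f%% dense\n",
            100 * tumour_adjacent$dense_fraction,
            100 * replicate_b$dense_fraction))
cell <- estimate_cell_fraction(replicate_b$dense_fraction)
cat(sprintf("=> ~%.1f%% of cells carry one methylated allele\n", 100 * cell))

# mutation allele fraction by local-context counting, 2 alt of 1077
locus <- list(ref_context = "CTGGAACT", alt_context = "CTGGAGAACT")
mreads <- c(rep(paste0("ACA", locus$alt_context, "GTT"), 2),
            rep(paste0("ACA", locus$ref_context, "GTT"), 1075))
af <- mutation_allele_fraction(mreads, locus)
print(af)

jsonlite::write_json(
  list(n_reads = cls$n_reads, dense_fraction = cls$dense_fraction,
       dense_ci = unname(cls$dense_ci), truth_dense_fraction = truth_f,
       replicate_dense_percent = 100 * replicate_b$dense_fraction,
       cell_fraction_percent = 100 * cell,
       mutation_fraction_percent = 100 * af$fraction),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
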
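# Fixtures built in code: call matrices with fixed counts, small site
# tables, and a tiny amplicon used across the bisulfite tests.

# Call matrix with `n_dense` fully methylated and `n - n_dense` fully
# unmethylated reads over `n_sites` CpGs (no missing calls).
count_call_matrix <- function(n_dense, n, n_sites = 23) {
  calls <- rbind(
    matrix(1, n_dense, n_sites),
    matrix(0, n - n_dense, n_sites))
  methylation_call_matrix(calls)
}

# Minimal sorted site table wrapper; defaults pass the heterozygous-site
# filter.
make_sites <- function(chrom = "chr1", pos = seq_along(gq) * 1000,
                       gt = "0/1", gq = rep(99, 5),
                       normal_depth = 100, t_ref = 50, t_alt = 50) {
  n <- length(gq)
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    normal_genotype = rep_len(gt, n),
    normal_ref_depth = rep_len(normal_depth %/% 2, n),
    normal_alt_depth = rep_len(normal_depth - normal_depth %/% 2, n),
    normal_depth = rep_len(normal_depth, n),
    tumour_ref_depth = rep_len(t_ref, n),
    tumour_alt_depth = rep_len(t_alt, n),
    genotype_quality = rep_len(gq, n),
    stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), ]
}

# Small fixed amplicon with two CpGs for hand-checkable conversion tests:
#   pos: 123456789...
#        ACGTTCGACCTAGGA  -> CpGs at 2 and 6
tiny_amplicon <- function() amplicon_ref("tiny", "ACGTTCGACCTAGGA")

# Noise-free reads from the four converted templates.
tiny_templates <- function() convert_reference(tiny_amplicon())
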
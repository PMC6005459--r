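## Readers and writers for the formats the three strands consume and
## produce: minimal VCF (via vcfR), FASTQ/FASTA, GMT-like marker sets
## (via fgsea), TSV tables, BED export, Newick, JSON summaries.
## Internal coordinates are 1-based closed throughout; BED conversion to
## 0-based half-open happens in one place (`to_bed`).

#' Convert 1-based closed intervals to BED (0-based half-open)
#'
#' The single point where the coordinate convention changes.
#'
#' @param start,end 1-based closed positions.
#' @return Data.frame with BED `start` (0-based) and `end` (exclusive).
#' @export
to_bed <- function(start, end) {
  data.frame(start = start - 1, end = end)
}

#' Write tumour/normal sites as a minimal VCF
#'
#' Emits a VCF 4.2 subset (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT)
#' with `GT:AD:DP:GQ` for the normal and tumour samples. REF/ALT bases are
#' placeholders: only genotypes and depths matter downstream.
#'
#' @param sites Site table from [gen_tumour_normal_sites()].
#' @param path Output path.
#' @param normal_sample,tumour_sample Sample column names.
#' @return The path, invisibly.
#' @export
write_sites_vcf <- function(sites, path, normal_sample = "NORMAL",
                            tumour_sample = "TUMOUR") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", normal_sample, tumour_sample, sep = "\t"))
  tumour_dp <- sites$tumour_ref_depth + sites$tumour_alt_depth
  normal <- sprintf("%s:%d,%d:%d:%d", sites$normal_genotype,
                    sites$normal_ref_depth, sites$normal_alt_depth,
                    sites$normal_depth, sites$genotype_quality)
  tumour <- sprintf("0/1:%d,%d:%d:%d", sites$tumour_ref_depth,
                    sites$tumour_alt_depth, tumour_dp,
                    sites$genotype_quality)
  body <- paste(sites$chrom, sites$pos, ".", "A", "C", ".", "PASS", ".",
                "GT:AD:DP:GQ", normal, tumour, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read paired tumour/normal sites from a VCF
#'
#' Parses biallelic SNV records with `GT`, `AD`, `DP`, `GQ` for both
#' samples into the site table the BAF strand consumes. Multiallelic and
#' indel records are skipped and counted.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param tumour_sample,normal_sample Sample column names in the VCF.
#' @return Site data.frame sorted by (chrom, pos) (see
#'   [gen_tumour_normal_sites()] for columns).
#' @export
read_vcf_sites <- function(path, tumour_sample = "TUMOUR",
                           normal_sample = "NORMAL") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  for (fld in c("GT", "AD", "DP", "GQ")) {
    if (!grepl(fld, vcf@gt[1, "FORMAT"]))
      stop("VCF FORMAT lacks required field: ", fld)
  }
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  snv <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1 & nchar(alt) == 1
  if (any(!snv))
    message(sum(!snv), " multiallelic/indel record(s) skipped")
  get <- function(el, sample) {
    x <- vcfR::extract.gt(vcf, element = el)[snv, sample]
    x
  }
  ad_n <- strsplit(get("AD", normal_sample), ",", fixed = TRUE)
  ad_t <- strsplit(get("AD", tumour_sample), ",", fixed = TRUE)
  out <- data.frame(
    chrom = vcf@fix[snv, "CHROM"],
    pos = as.numeric(vcf@fix[snv, "POS"]),
    normal_genotype = get("GT", normal_sample),
    normal_ref_depth = as.integer(vapply(ad_n, `[`, character(1), 1)),
    normal_alt_depth = as.integer(vapply(ad_n, `[`, character(1), 2)),
    normal_depth = as.integer(get("DP", normal_sample)),
    tumour_ref_depth = as.integer(vapply(ad_t, `[`, character(1), 1)),
    tumour_alt_depth = as.integer(vapply(ad_t, `[`, character(1), 2)),
    genotype_quality = as.integer(get("GQ", normal_sample)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read FASTQ
#'
#' Plain four-line-per-record FASTQ; qualities are written as a constant
#' high score (simulated reads carry no per-base quality model).
#'
#' @param reads Character vector of sequences.
#' @param ids Read identifiers.
#' @param path File path.
#' @return `write_fastq` the path invisibly; `read_fastq` a named character
#'   vector of sequences.
#' @export
write_fastq <- function(reads, path, ids = names(reads)) {
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  rec <- rbind(paste0("@", ids), reads, "+",
               vapply(nchar(reads), function(n)
                 strrep("I", n), character(1)))
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  reads <- lines[seq(2, length(lines), by = 4)]
  names(reads) <- ids
  reads
}

#' Write / read an amplicon reference as FASTA
#'
#' @param ref An [amplicon_ref()].
#' @param path File path.
#' @return `write_amplicon_fasta` the path invisibly; `read_amplicon_fasta`
#'   an [amplicon_ref()] (CpG positions re-detected from the sequence).
#' @export
write_amplicon_fasta <- function(ref, path) {
  writeLines(c(paste0(">", ref$name), ref$sequence), path)
  invisible(path)
}

#' @rdname write_amplicon_fasta
#' @export
read_amplicon_fasta <- function(path) {
  lines <- readLines(path)
  name <- sub("^>", "", lines[1])
  amplicon_ref(name, paste(lines[-1], collapse = ""))
}

#' Read / write GMT-like marker gene sets
#'
#' Reading goes through [fgsea::gmtPathways()]. Each line is
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @return `read_gmt` a list of [marker_gene_set()]; `write_gmt` the path
#'   invisibly.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(names(sets), function(nm) marker_gene_set(nm, sets[[nm]]))
}

#' @rdname read_gmt
#' @param marker_sets List of [marker_gene_set()].
#' @export
write_gmt <- function(marker_sets, path) {
  lines <- vapply(marker_sets, function(ms)
    paste(c(ms$stage_name, "na", ms$gene_ids), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Probes × samples with a header row of sample ids and a `probe_id` first
#' column; an optional companion two-column TSV (`sample_id`, `group`)
#' carries group labels.
#'
#' @param mat An [expression_matrix()].
#' @param path File path.
#' @param groups_path Optional path for the sample-group table.
#' @return `write_expression_tsv` the path invisibly; `read_expression_tsv`
#'   an [expression_matrix()].
#' @export
write_expression_tsv <- function(mat, path, groups_path = NULL) {
  df <- data.frame(probe_id = mat$probe_ids, mat$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path) && !is.null(mat$sample_groups))
    utils::write.table(
      data.frame(sample_id = mat$sample_ids, group = mat$sample_groups),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$probe_id
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- utils::read.delim(groups_path)
    groups <- g$group[match(colnames(values), g$sample_id)]
  }
  expression_matrix(values, sample_groups = groups)
}

#' Write segmentation outputs
#'
#' `write_segments_tsv` writes the 1-based closed segment table;
#' `write_segments_bed` exports 0-based half-open intervals with the state
#' as the BED name column; `write_runs_tsv` writes the LOH-run table.
#'
#' @param result A `segmentation_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_segments_tsv <- function(result, path) {
  utils::write.table(result$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
write_segments_bed <- function(result, path) {
  s <- result$segments
  bed <- to_bed(s$start, s$end)
  utils::write.table(
    data.frame(s$chrom, bed$start, bed$end, s$state),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
write_runs_tsv <- function(result, path) {
  utils::write.table(result$loh_runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
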
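## Targeted bisulfite-amplicon analysis: reference conversion, per-read
## per-CpG methylation calling, epiallele classification, mutation allele
## fractions and mosaic cell-fraction estimation.

#' Define a bisulfite amplicon reference
#'
#' @param name Amplicon name.
#' @param sequence Top-strand DNA sequence (A/C/G/T).
#' @param cpg_positions 1-based positions of CpG cytosines on the top strand;
#'   auto-detected from the sequence when `NULL`. Every position must index a
#'   C followed by a G.
#' @param genomic_anchor Optional `c(chrom, start)` for reporting.
#' @return A list of class `amplicon_ref`.
#' @export
amplicon_ref <- function(name, sequence, cpg_positions = NULL,
                         genomic_anchor = NULL) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("sequence must contain only A/C/G/T")
  if (is.null(cpg_positions)) {
    cpg_positions <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
    cpg_positions <- as.integer(cpg_positions[cpg_positions > 0])
  } else {
    cpg_positions <- as.integer(cpg_positions)
    if (length(cpg_positions)) {
      ok <- substring(sequence, cpg_positions, cpg_positions + 1L) == "CG"
      if (!all(ok))
        stop("cpg_positions must each index a C followed by a G")
    }
  }
  structure(list(name = name, sequence = sequence,
                 cpg_positions = cpg_positions,
                 genomic_anchor = genomic_anchor),
            class = "amplicon_ref")
}

#' Expected post-conversion templates for an amplicon
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil (read as T);
#' methylated CpG cytosines are protected. PCR of the converted bottom
#' strand yields, in reference orientation, G→A conversions with the CpG
#' guanine reporting the bottom-strand CpG cytosine. The four templates
#' (top/bottom × fully methylated/unmethylated at CpGs) bound what a clean
#' read can look like.
#'
#' @param ref An [amplicon_ref()].
#' @return Named list of four sequences: `top_methylated`,
#'   `top_unmethylated`, `bottom_methylated`, `bottom_unmethylated`, all in
#'   reference orientation.
#' @export
convert_reference <- function(ref) {
  stopifnot(inherits(ref, "amplicon_ref"))
  chars <- strsplit(ref$sequence, "")[[1]]
  cpg_c <- ref$cpg_positions
  cpg_g <- ref$cpg_positions + 1L
  top <- function(meth) {
    x <- chars
    x[x == "C"] <- "T"
    if (meth) x[cpg_c] <- "C"
    paste(x, collapse = "")
  }
  bottom <- function(meth) {
    x <- chars
    x[x == "G"] <- "A"
    if (meth) x[cpg_g] <- "G"
    paste(x, collapse = "")
  }
  list(top_methylated = top(TRUE), top_unmethylated = top(FALSE),
       bottom_methylated = bottom(TRUE), bottom_unmethylated = bottom(FALSE))
}

#' Construct a methylation call matrix
#'
#' The reads × CpG-sites ternary matrix (1 methylated, 0 unmethylated, NA
#' missing) that downstream epiallele analysis consumes. Usually produced by
#' [assign_and_call()]; exposed so call matrices can be built directly, e.g.
#' from published read counts.
#'
#' @param calls Integer/numeric matrix, reads × sites, values in \{0, 1, NA\}.
#' @param cpg_sites Site positions (column labels).
#' @param read_ids Read identifiers; default `read_1 ...`.
#' @param strand Per-read strand (`"top"`/`"bottom"`), optional.
#' @param conversion_failure Per-read non-CpG cytosine retention fraction.
#' @param n_discarded Count of reads discarded as off-target.
#' @return A list of class `methylation_call_matrix`.
#' @export
methylation_call_matrix <- function(calls, cpg_sites = seq_len(ncol(calls)),
                                    read_ids = NULL, strand = NULL,
                                    conversion_failure = NULL,
                                    n_discarded = 0L) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0, 1, NA)))
    stop("calls must be 0 (unmethylated), 1 (methylated) or NA (missing)")
  if (length(cpg_sites) != ncol(calls))
    stop("cpg_sites length must match the number of call columns")
  if (is.null(read_ids)) read_ids <- sprintf("read_%d", seq_len(nrow(calls)))
  if (length(read_ids) != nrow(calls))
    stop("read_ids length must match the number of call rows")
  if (!is.null(conversion_failure) &&
      any(conversion_failure < 0 | conversion_failure > 1, na.rm = TRUE))
    stop("conversion_failure must be in [0, 1]")
  dimnames(calls) <- list(read_ids, as.character(cpg_sites))
  structure(list(calls = calls, cpg_sites = cpg_sites, read_ids = read_ids,
                 strand = strand, conversion_failure = conversion_failure,
                 n_discarded = as.integer(n_discarded)),
            class = "methylation_call_matrix")
}

#' Assign reads to strands and call per-CpG methylation
#'
#' Each read is compared, ungapped and anchored at the amplicon start
#' (amplicon reads are position-fixed), to the converted top- and
#' bottom-strand templates over CpG-independent positions; it is assigned to
#' the better-matching strand, or discarded as off-target when the best
#' identity falls below `min_identity` or the read covers less than half the
#' amplicon. At each CpG the call is made from the observed base (C
#' methylated / T unmethylated on top; G / A on bottom), missing for any
#' other base or for sites beyond the read. The per-read bisulfite
#' conversion-failure rate is the fraction of covered non-CpG cytosine
#' positions still reading as unconverted.
#'
#' @param reads Character vector of read sequences in reference orientation.
#' @param ref An [amplicon_ref()].
#' @param min_identity Identity floor for strand assignment (default 0.8).
#' @return A [methylation_call_matrix()]; discarded reads are counted in
#'   `n_discarded`.
#' @export
assign_and_call <- function(reads, ref, min_identity = 0.8) {
  stopifnot(inherits(ref, "amplicon_ref"))
  tmpl <- strsplit(ref$sequence, "")[[1]]
  L <- length(tmpl)
  cpg_c <- ref$cpg_positions
  cpg_g <- ref$cpg_positions + 1L
  noncpg <- setdiff(seq_len(L), c(cpg_c, cpg_g))
  top_tmpl <- tmpl; top_tmpl[top_tmpl == "C"] <- "T"
  bot_tmpl <- tmpl; bot_tmpl[bot_tmpl == "G"] <- "A"
  nonc_c <- intersect(noncpg, which(tmpl == "C"))
  nonc_g <- intersect(noncpg, which(tmpl == "G"))

  ids <- if (is.null(names(reads)))
    sprintf("read_%05d", seq_along(reads)) else names(reads)
  len <- nchar(reads)
  too_short <- len < ceiling(L / 2)
  n_disc <- sum(too_short)
  reads <- reads[!too_short]; ids <- ids[!too_short]; len <- len[!too_short]
  n <- length(reads)
  if (n == 0)
    return(methylation_call_matrix(
      matrix(NA_real_, 0, length(cpg_c)), cpg_sites = cpg_c,
      read_ids = character(0), n_discarded = n_disc))

  m <- matrix("N", n, L)
  split_reads <- strsplit(reads, "")
  for (i in seq_len(n)) {
    k <- min(len[i], L)
    m[i, seq_len(k)] <- split_reads[[i]][seq_len(k)]
  }
  covered <- m[, noncpg, drop = FALSE] != "N"
  id_top <- rowSums((m[, noncpg, drop = FALSE] ==
                       rep(top_tmpl[noncpg], each = n)) & covered) /
    pmax(1, rowSums(covered))
  id_bot <- rowSums((m[, noncpg, drop = FALSE] ==
                       rep(bot_tmpl[noncpg], each = n)) & covered) /
    pmax(1, rowSums(covered))
  strand <- ifelse(id_top >= id_bot, "top", "bottom")
  keep <- pmax(id_top, id_bot) >= min_identity
  n_disc <- n_disc + sum(!keep)
  if (n_disc > 0)
    message(n_disc, " read(s) discarded as off-target or too short")
  m <- m[keep, , drop = FALSE]
  strand <- strand[keep]; ids <- ids[keep]
  n <- nrow(m)

  calls <- matrix(NA_real_, n, length(cpg_c))
  is_top <- strand == "top"
  if (any(is_top)) {
    b <- m[is_top, cpg_c, drop = FALSE]
    calls[is_top, ] <- ifelse(b == "C", 1, ifelse(b == "T", 0, NA))
  }
  if (any(!is_top)) {
    b <- m[!is_top, cpg_g, drop = FALSE]
    calls[!is_top, ] <- ifelse(b == "G", 1, ifelse(b == "A", 0, NA))
  }
  conv_fail <- numeric(n)
  for (i in seq_len(n)) {
    pos <- if (is_top[i]) nonc_c else nonc_g
    obs <- m[i, pos]
    obs <- obs[obs != "N"]
    conv_fail[i] <- if (length(obs) == 0) NA_real_ else
      mean(obs == (if (is_top[i]) "C" else "G"))
  }
  methylation_call_matrix(calls, cpg_sites = cpg_c, read_ids = ids,
                          strand = strand, conversion_failure = conv_fail,
                          n_discarded = n_disc)
}

#' Per-CpG methylation proportions
#'
#' @param m A [methylation_call_matrix()].
#' @return A data.frame per site: `cpg_site`, `n_methylated`,
#'   `n_unmethylated`, `proportion` (methylated / called, NA when no read
#'   calls the site).
#' @export
per_cpg_proportions <- function(m) {
  stopifnot(inherits(m, "methylation_call_matrix"))
  n_meth <- colSums(m$calls == 1, na.rm = TRUE)
  n_unmeth <- colSums(m$calls == 0, na.rm = TRUE)
  denom <- n_meth + n_unmeth
  if (any(denom == 0))
    warning(sum(denom == 0), " CpG site(s) with no called reads")
  data.frame(cpg_site = m$cpg_sites, n_methylated = n_meth,
             n_unmethylated = n_unmeth,
             proportion = ifelse(denom > 0, n_meth / denom, NA_real_),
             row.names = NULL)
}

#' Classify reads into epialleles
#'
#' Reads with at least `min_called` non-missing CpG calls are classified by
#' their methylated fraction: densely methylated at or above `dense_min`,
#' unmethylated at or below `unmeth_max`, intermediate otherwise. The dense
#' fraction among classified reads carries a Wilson 95% confidence interval.
#' The default `dense_min` of 0.9 operationalises "methylated at essentially
#' all CpGs" while tolerating an occasional miscalled site.
#'
#' @param m A [methylation_call_matrix()].
#' @param dense_min Minimum methylated fraction for the dense class.
#' @param unmeth_max Maximum methylated fraction for the unmethylated class.
#' @param min_called Minimum non-missing calls for a read to be classified.
#' @return A list of class `epiallele_summary`: counts (`n_reads` classified,
#'   `n_dense`, `n_unmethylated`, `n_intermediate`, `n_excluded`),
#'   `dense_fraction` and its Wilson 95% CI, the thresholds used, and the
#'   per-read class labels.
#' @export
classify_epialleles <- function(m, dense_min = 0.9, unmeth_max = 0.1,
                                min_called = 5) {
  stopifnot(inherits(m, "methylation_call_matrix"))
  if (nrow(m$calls) == 0) stop("empty call matrix")
  if (dense_min <= 0 || dense_min > 1 || unmeth_max < 0 || unmeth_max >= 1 ||
      unmeth_max >= dense_min)
    stop("need 0 <= unmeth_max < dense_min <= 1")
  n_called <- rowSums(!is.na(m$calls))
  frac <- rowMeans(m$calls, na.rm = TRUE)
  usable <- n_called >= min_called
  if (!any(usable)) stop("all reads excluded (fewer than ", min_called,
                         " called sites each)")
  cls <- rep(NA_character_, length(frac))
  cls[usable] <- ifelse(frac[usable] >= dense_min, "dense",
                        ifelse(frac[usable] <= unmeth_max, "unmethylated",
                               "intermediate"))
  n <- sum(usable)
  n_dense <- sum(cls == "dense", na.rm = TRUE)
  ci <- wilson_ci(n_dense, n)
  structure(list(n_reads = n, n_dense = n_dense,
                 n_unmethylated = sum(cls == "unmethylated", na.rm = TRUE),
                 n_intermediate = sum(cls == "intermediate", na.rm = TRUE),
                 n_excluded = sum(!usable),
                 dense_fraction = n_dense / n, dense_ci = ci,
                 dense_min = dense_min, unmeth_max = unmeth_max,
                 min_called = min_called, read_class = cls),
            class = "epiallele_summary")
}

## Wilson score interval (95%) via prop.test without continuity correction.
wilson_ci <- function(x, n, conf_level = 0.95) {
  # suppressed warning concerns the discarded chi-squared p value, not the CI
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE,
                                          conf.level = conf_level))$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' @export
print.epiallele_summary <- function(x, ...) {
  cat(sprintf(
    "%d of %d (%.1f%%) classified reads densely methylated (Wilson 95%% CI %.1f-%.1f%%)\n",
    x$n_dense, x$n_reads, 100 * x$dense_fraction,
    100 * x$dense_ci["lower"], 100 * x$dense_ci["upper"]))
  cat(sprintf("unmethylated: %d; intermediate: %d; excluded (<%d calls): %d\n",
              x$n_unmethylated, x$n_intermediate, x$min_called, x$n_excluded))
  invisible(x)
}

#' Mutation allele fraction from local sequence context
#'
#' Counts reads matching the alternate versus the reference local context
#' around a mutation (deep-sequencing allele counting at a single locus).
#' Reads matching neither context, or both, are excluded and counted as
#' ambiguous.
#'
#' @param reads Character vector of read sequences.
#' @param locus_spec List with `ref_context` and `alt_context`: short
#'   sequences uniquely flanking the locus in its reference and mutant form.
#' @return A list of class `allele_fraction`: `n_ref`, `n_alt`,
#'   `n_ambiguous`, `fraction` = alt / (alt + ref).
#' @export
mutation_allele_fraction <- function(reads, locus_spec) {
  stopifnot(is.list(locus_spec),
            all(c("ref_context", "alt_context") %in% names(locus_spec)))
  has_ref <- grepl(locus_spec$ref_context, reads, fixed = TRUE)
  has_alt <- grepl(locus_spec$alt_context, reads, fixed = TRUE)
  n_ref <- sum(has_ref & !has_alt)
  n_alt <- sum(has_alt & !has_ref)
  n_amb <- length(reads) - n_ref - n_alt
  if ((n_ref + n_alt) < 0.5 * length(reads))
    stop("locus context found in fewer than 50% of reads; wrong amplicon?")
  structure(list(n_ref = n_ref, n_alt = n_alt, n_ambiguous = n_amb,
                 fraction = n_alt / (n_alt + n_ref)),
            class = "allele_fraction")
}

#' @export
print.allele_fraction <- function(x, ...) {
  cat(sprintf("%d of %d (%.2f%%) alleles carry the mutation (%d ambiguous)\n",
              x$n_alt, x$n_alt + x$n_ref, 100 * x$fraction, x$n_ambiguous))
  invisible(x)
}

#' Mosaic cell fraction from a methylated-allele fraction
#'
#' Under the model that each affected cell carries exactly one methylated
#' allele among its two, the fraction of affected cells is twice the
#' allele-level fraction. An allele fraction above 0.5 contradicts the
#' one-allele-per-cell (heterozygous-event) assumption and is rejected.
#'
#' @param allele_fraction Fraction of alleles affected, in \[0, 0.5\].
#' @return The estimated fraction of cells affected.
#' @export
estimate_cell_fraction <- function(allele_fraction) {
  if (any(allele_fraction < 0 | allele_fraction > 0.5))
    stop("allele fraction must be in [0, 0.5] under the heterozygous-event assumption")
  2 * allele_fraction
}
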
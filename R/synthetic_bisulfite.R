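#' Describe a two-epiallele bisulfite read mixture
#'
#' Truth parameters for [gen_bisulfite_reads()]: a mixture of a densely
#' methylated epiallele and an (essentially) unmethylated background
#' epiallele, the situation created by allele-specific promoter
#' hypermethylation, possibly mosaic across cells.
#'
#' @param dense_fraction Fraction of molecules from the densely methylated
#'   epiallele, in \[0, 1\].
#' @param p_meth_dense,p_meth_background Per-CpG methylation probability for
#'   each class; must satisfy `p_meth_dense > p_meth_background`. The dense
#'   epiallele is methylated at every CpG by default; apparent deviations in
#'   reads arise from the separately modeled conversion and sequencing error
#'   processes.
#' @param conversion_rate Bisulfite conversion efficiency for unmethylated
#'   cytosines, in \[0, 1\] (1 = complete conversion).
#' @param seq_error Per-base substitution error rate.
#' @param n_reads Number of reads to draw.
#' @param seed Integer RNG seed.
#' @return A list of class `epiallele_truth`.
#' @export
epiallele_truth <- function(dense_fraction, p_meth_dense = 1,
                            p_meth_background = 0.02, conversion_rate = 0.995,
                            seq_error = 0.001, n_reads = 1000, seed = 1) {
  probs <- c(dense_fraction, p_meth_dense, p_meth_background,
             conversion_rate, seq_error)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (p_meth_dense <= p_meth_background)
    stop("`p_meth_dense` must exceed `p_meth_background`")
  if (n_reads < 1) stop("`n_reads` must be >= 1")
  structure(list(dense_fraction = dense_fraction,
                 p_meth_dense = p_meth_dense,
                 p_meth_background = p_meth_background,
                 conversion_rate = conversion_rate, seq_error = seq_error,
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "epiallele_truth")
}

#' Generate a synthetic amplicon reference with a controlled CpG count
#'
#' Builds a random sequence containing exactly `n_cpg` CpG dinucleotides at
#' roughly evenly spaced positions (a synthetic stand-in for a CpG-island
#' promoter amplicon).
#'
#' @param length Amplicon length in bp.
#' @param n_cpg Number of CpG sites.
#' @param seed Integer RNG seed.
#' @param name Amplicon name.
#' @return An [amplicon_ref()].
#' @export
synthetic_amplicon <- function(length = 253, n_cpg = 23, seed = 1,
                               name = "synthetic_amplicon") {
  if (length < 3 * n_cpg) stop("amplicon too short for ", n_cpg, " CpGs")
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  cg <- which(chars[-length] == "C" & chars[-1] == "G")
  chars[cg + 1L] <- "A"                     # break accidental CpGs
  step <- floor((length - 2) / n_cpg)
  pos <- 1L + step * (seq_len(n_cpg) - 1L) + 1L
  chars[pos] <- "C"; chars[pos + 1L] <- "G"
  chars[pos - 1L][chars[pos - 1L] == "C"] <- "A"  # no CpG directly upstream
  amplicon_ref(name, paste(chars, collapse = ""))
}

## Random per-base substitution to one of the three other bases.
apply_seq_error <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1))
  }
  chars
}

#' Simulate bisulfite amplicon reads from a two-epiallele mixture
#'
#' Each read is drawn from the dense epiallele with probability
#' `dense_fraction` and from the background otherwise, on a random strand.
#' CpG cytosines are retained (methylated) with the class probability;
#' unmethylated cytosines — CpG or not — are converted C→T (top strand) or
#' G→A (bottom strand, read in reference orientation) with probability
#' `conversion_rate`. Uniform substitution errors are added at `seq_error`
#' per base. Reads are full amplicon length (targeted amplicon design).
#'
#' @param ref An [amplicon_ref()].
#' @param truth An [epiallele_truth()].
#' @return A list with `reads` (character vector of read sequences in
#'   reference orientation), `read_ids`, and `truth` — a data.frame with the
#'   per-read class (`dense`/`background`) and strand.
#' @export
gen_bisulfite_reads <- function(ref, truth) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(truth, "epiallele_truth"))
  if (length(ref$cpg_positions) < 1) stop("reference contains no CpG site")
  set.seed(truth$seed)
  tmpl <- strsplit(ref$sequence, "")[[1]]
  L <- length(tmpl)
  cpg <- ref$cpg_positions
  top_c <- setdiff(which(tmpl == "C"), cpg)        # non-CpG C, top strand
  bot_g <- setdiff(which(tmpl == "G"), cpg + 1L)   # non-CpG G, bottom strand
  n <- truth$n_reads
  dense <- stats::runif(n) < truth$dense_fraction
  strand <- ifelse(stats::runif(n) < 0.5, "top", "bottom")
  p_meth <- ifelse(dense, truth$p_meth_dense, truth$p_meth_background)

  reads <- character(n)
  for (i in seq_len(n)) {
    chars <- tmpl
    meth <- stats::runif(length(cpg)) < p_meth[i]
    conv <- function(idx) idx[stats::runif(length(idx)) < truth$conversion_rate]
    if (strand[i] == "top") {
      chars[conv(top_c)] <- "T"
      chars[conv(cpg[!meth])] <- "T"
    } else {
      chars[conv(bot_g)] <- "A"
      chars[conv(cpg[!meth] + 1L)] <- "A"
    }
    chars <- apply_seq_error(chars, truth$seq_error)
    reads[i] <- paste(chars, collapse = "")
  }
  ids <- sprintf("read_%05d", seq_len(n))
  list(reads = reads, read_ids = ids,
       truth = data.frame(read_id = ids,
                          class = ifelse(dense, "dense", "background"),
                          strand = strand, stringsAsFactors = FALSE))
}
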
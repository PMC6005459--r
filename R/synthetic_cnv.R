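#' Define a truth segment for tumour/normal site simulation
#'
#' A truth segment describes one contiguous region of the simulated tumour
#' genome in a single somatic state. Segments are the unit from which
#' [gen_tumour_normal_sites()] draws heterozygous SNP sites, and carry the
#' tumour purity that dilutes the somatic signal with normal cells.
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based closed base positions, `start <= end`.
#' @param state One of `"neutral_het"`, `"cn_loh"`, `"loss"`, `"gain"`.
#'   Loss and gain are single-copy changes; `cn_loh` is copy-neutral loss of
#'   heterozygosity (two copies of one parental allele).
#' @param tumour_purity Fraction of tumour cells in the sample, in \[0, 1\].
#' @return A one-row data.frame of class `cnv_truth_segment`.
#' @export
cnv_truth_segment <- function(chrom, start, end, state, tumour_purity = 1) {
  state <- match.arg(state, c("neutral_het", "cn_loh", "loss", "gain"))
  if (!is.numeric(start) || !is.numeric(end) || start > end)
    stop("`start` must be <= `end`")
  if (start < 1) stop("positions are 1-based; `start` must be >= 1")
  if (tumour_purity < 0 || tumour_purity > 1)
    stop("`tumour_purity` must be in [0, 1]")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), state = state,
                    tumour_purity = tumour_purity,
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_truth_segment", class(out))
  out
}

#' Combine truth segments, checking per-chromosome non-overlap
#'
#' @param ... `cnv_truth_segment` rows (or data.frames of them).
#' @return A data.frame of validated truth segments, sorted by (chrom, start).
#' @export
cnv_truth_segments <- function(...) {
  segs <- do.call(rbind, lapply(list(...), as.data.frame))
  segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  validate_truth_segments(segs)
  segs
}

validate_truth_segments <- function(segs) {
  needed <- c("chrom", "start", "end", "state", "tumour_purity")
  if (!all(needed %in% names(segs)))
    stop("truth segments need columns: ", paste(needed, collapse = ", "))
  if (any(segs$start > segs$end)) stop("segment with start > end")
  if (any(segs$tumour_purity < 0 | segs$tumour_purity > 1))
    stop("tumour_purity outside [0, 1]")
  for (chr in unique(segs$chrom)) {
    s <- segs[segs$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping truth segments on chromosome ", chr)
  }
  invisible(segs)
}

## Expected tumour alt-allele fraction under the single-copy-change dosage
## model. `alt_affected` marks sites where the alternate allele is the
## retained (cn_loh), remaining (loss) or duplicated (gain) allele.
tumour_alt_fraction <- function(state, purity, alt_affected) {
  p <- purity
  switch(state,
    neutral_het = rep(0.5, length(alt_affected)),
    cn_loh = ifelse(alt_affected, (1 + p) / 2, (1 - p) / 2),
    loss   = ifelse(alt_affected, 1 / (2 - p), (1 - p) / (2 - p)),
    gain   = ifelse(alt_affected, (1 + p) / (2 + p), 1 / (2 + p)),
    stop("unknown state: ", state)
  )
}

## Expected tumour coverage relative to the normal (copy number / 2,
## purity-diluted).
tumour_relative_coverage <- function(state, purity) {
  cn <- switch(state, neutral_het = 2, cn_loh = 2, loss = 1, gain = 3)
  (purity * cn + (1 - purity) * 2) / 2
}

#' Simulate heterozygous SNP sites for a tumour/normal pair
#'
#' Draws heterozygous-in-normal biallelic sites uniformly along each truth
#' segment and simulates paired read depths. Normal allele depths are
#' binomial at 0.5; tumour alt depths are binomial with success probability
#' given by the single-copy-change allele-dosage model at the segment's state
#' and purity (neutral 0.5; cn-LOH \eqn{0.5 \pm 0.5p}; loss
#' \eqn{1/(2-p)} or \eqn{(1-p)/(2-p)}; gain \eqn{(1+p)/(2+p)} or
#' \eqn{1/(2+p)}), with the affected allele chosen at random per site.
#' Tumour coverage scales with the purity-diluted copy number.
#'
#' @param truth_segments Data.frame of truth segments
#'   (see [cnv_truth_segments()]).
#' @param site_density Expected heterozygous sites per megabase.
#' @param mean_depth Mean sequencing depth (reads) in the normal.
#' @param seed Integer RNG seed; the generator is reproducible given the seed.
#' @return A data.frame of sites sorted by (chrom, pos) with columns
#'   `chrom`, `pos`, `normal_genotype`, `normal_ref_depth`, `normal_alt_depth`,
#'   `normal_depth`, `tumour_ref_depth`, `tumour_alt_depth`,
#'   `genotype_quality`, and the truth label `truth_state`.
#' @export
gen_tumour_normal_sites <- function(truth_segments, site_density = 20,
                                    mean_depth = 100, seed = 1) {
  validate_truth_segments(truth_segments)
  if (mean_depth < 1) stop("`mean_depth` must be >= 1")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(truth_segments)), function(i) {
    seg <- truth_segments[i, ]
    len <- seg$end - seg$start + 1
    n <- round(site_density * len / 1e6)
    if (n < 1) return(NULL)
    pos <- sort(sample.int(len, n, replace = FALSE)) + seg$start - 1
    normal_depth <- pmax(1L, stats::rpois(n, mean_depth))
    normal_alt <- stats::rbinom(n, normal_depth, 0.5)
    alt_affected <- stats::runif(n) < 0.5
    q <- tumour_alt_fraction(seg$state, seg$tumour_purity, alt_affected)
    tdep <- pmax(1L, stats::rpois(
      n, mean_depth * tumour_relative_coverage(seg$state, seg$tumour_purity)))
    talt <- stats::rbinom(n, tdep, q)
    data.frame(
      chrom = seg$chrom, pos = pos, normal_genotype = "0/1",
      normal_ref_depth = normal_depth - normal_alt,
      normal_alt_depth = normal_alt, normal_depth = normal_depth,
      tumour_ref_depth = tdep - talt, tumour_alt_depth = talt,
      genotype_quality = sample(50:99, n, replace = TRUE),
      truth_state = seg$state, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no sites generated; increase `site_density`")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
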
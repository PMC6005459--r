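## B-allele-fraction track construction from paired tumour/normal sites.

is_het <- function(gt) gt %in% c("0/1", "1/0", "0|1", "1|0")

check_sorted_sites <- function(sites) {
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)")
  invisible(sites)
}

#' Filter to usable heterozygous sites
#'
#' Retains biallelic sites heterozygous in the normal sample with genotype
#' quality at least `gq_min` and read depth within `[depth_min, depth_max]`
#' (inclusive) in both the normal and the tumour sample. These are the sites
#' on which the B-allele-fraction track is built.
#'
#' @param sites Data.frame of sites sorted by (chrom, pos) with columns
#'   `chrom`, `pos`, `normal_genotype`, `normal_depth`, `tumour_ref_depth`,
#'   `tumour_alt_depth`, `genotype_quality`.
#' @param gq_min Minimum genotype quality (phred-like), default 14.
#' @param depth_min,depth_max Inclusive depth bounds for both samples,
#'   defaults 11 and 1001.
#' @return The retained sites, order preserved. May be empty.
#' @export
filter_heterozygous_sites <- function(sites, gq_min = 14, depth_min = 11,
                                      depth_max = 1001) {
  check_sorted_sites(sites)
  tumour_depth <- sites$tumour_ref_depth + sites$tumour_alt_depth
  keep <- is_het(sites$normal_genotype) &
    sites$genotype_quality >= gq_min &
    sites$normal_depth >= depth_min & sites$normal_depth <= depth_max &
    tumour_depth >= depth_min & tumour_depth <= depth_max
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the mirrored-BAF and log-ratio track
#'
#' For each site the tumour B-allele fraction is `alt / (ref + alt)`, the
#' mirrored BAF is `max(baf, 1 - baf)` (folding out the arbitrary choice of
#' which allele is "B"), and the log ratio is the log2 of the
#' library-size-normalised tumour/normal depth ratio, median-centred across
#' the genome so that the dominant (neutral) state sits at 0.
#'
#' @param sites Filtered sites (see [filter_heterozygous_sites()]).
#' @return A data.frame with columns `chrom`, `pos`, `baf`, `mirrored_baf`,
#'   `logratio`. Sites with zero tumour depth are dropped with a warning.
#' @export
compute_baf_track <- function(sites) {
  tumour_depth <- sites$tumour_ref_depth + sites$tumour_alt_depth
  zero <- tumour_depth == 0
  if (any(zero)) {
    warning(sum(zero), " site(s) with zero tumour depth dropped")
    sites <- sites[!zero, , drop = FALSE]
    tumour_depth <- tumour_depth[!zero]
  }
  if (nrow(sites) == 0) stop("no sites with tumour coverage")
  baf <- sites$tumour_alt_depth / tumour_depth
  lr <- log2((tumour_depth / sum(tumour_depth)) /
               (sites$normal_depth / sum(sites$normal_depth)))
  lr <- lr - stats::median(lr)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, baf = baf,
                    mirrored_baf = pmax(baf, 1 - baf), logratio = lr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
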
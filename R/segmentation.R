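## Hidden-Markov segmentation of the (mirrored BAF, log ratio) track into
## somatic copy/LOH states, LOH-run detection, and the fractional
## copy-number aberration score.

segmentation_states <- c("neutral", "cn_loh", "loss", "gain")

#' Emission model for the segmentation HMM
#'
#' Per-state Gaussian emission means for the mirrored BAF and the log2
#' depth ratio. The defaults are purity-free reference points: neutral
#' (0.5, 0); copy-neutral LOH with an elevated mirrored BAF at log ratio 0;
#' single-copy loss with elevated mirrored BAF and negative log ratio;
#' single-copy gain with a moderate BAF shift and positive log ratio.
#' Under the single-copy dosage model at purity 0.8 the exact centres are
#' mirrored BAF 0.90 / 0.83 / 0.64 for cn-LOH / loss / gain and log ratios
#' -0.74 / +0.49 for loss / gain; the defaults sit near these while staying
#' serviceable across the purity range where states remain separable.
#'
#' @param baf_mean,lr_mean Named numeric vectors of per-state means.
#' @param baf_sd,lr_sd Emission standard deviations (shared across states).
#' @param self_transition Probability of staying in the same state between
#'   adjacent sites; the remainder is split evenly across the other states.
#' @return A list of class `hmm_emission_model`.
#' @export
hmm_emission_model <- function(
    baf_mean = c(neutral = 0.52, cn_loh = 0.87, loss = 0.83, gain = 0.64),
    lr_mean  = c(neutral = 0, cn_loh = 0, loss = -0.6, gain = 0.45),
    baf_sd = 0.07, lr_sd = 0.3, self_transition = 0.999) {
  stopifnot(identical(sort(names(baf_mean)), sort(segmentation_states)),
            identical(sort(names(lr_mean)), sort(segmentation_states)),
            baf_sd > 0, lr_sd > 0,
            self_transition > 0, self_transition < 1)
  structure(list(baf_mean = baf_mean[segmentation_states],
                 lr_mean = lr_mean[segmentation_states],
                 baf_sd = baf_sd, lr_sd = lr_sd,
                 self_transition = self_transition),
            class = "hmm_emission_model")
}

## Viterbi decoding over the 4 states for one chromosome's track.
## Emissions: independent Gaussians on (mirrored_baf, logratio).
viterbi_states <- function(mbaf, lr, model) {
  n <- length(mbaf)
  k <- length(segmentation_states)
  loge <- matrix(0, n, k)
  for (j in seq_len(k)) {
    loge[, j] <- stats::dnorm(mbaf, model$baf_mean[j], model$baf_sd, log = TRUE) +
      stats::dnorm(lr, model$lr_mean[j], model$lr_sd, log = TRUE)
  }
  log_stay <- log(model$self_transition)
  log_move <- log((1 - model$self_transition) / (k - 1))
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- log(1 / k) + loge[1, ]
  for (t in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[t - 1, ] + ifelse(seq_len(k) == j, log_stay, log_move)
      psi[t, j] <- which.max(cand)
      delta[t, j] <- cand[psi[t, j]] + loge[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  segmentation_states[path]
}

#' Segment a BAF/log-ratio track into somatic states
#'
#' Decodes, per chromosome, the most likely hidden-state sequence over
#' \{neutral, cn_loh, loss, gain\} from the (mirrored BAF, log ratio) pairs
#' using a 4-state HMM with Gaussian emissions and Viterbi decoding, then
#' merges runs of same-state sites into segments. Copy-neutral LOH is
#' distinguished from loss/gain by a log ratio near zero. Chromosomes with
#' fewer than `min_sites` sites are emitted as a single neutral segment with
#' a warning.
#'
#' @param track Output of [compute_baf_track()].
#' @param model An [hmm_emission_model()].
#' @param min_sites Minimum sites per chromosome for decoding (default 5).
#' @return A list of class `segmentation_result` with elements `segments`
#'   (data.frame: chrom, start, end, state, n_sites, mean_mirrored_baf,
#'   mean_logratio), `fractional_cna_score`, `loh_runs`, and `site_states`
#'   (per-site decoded state, aligned with `track`).
#' @export
segment_states <- function(track, model = hmm_emission_model(),
                           min_sites = 5) {
  if (nrow(track) < 1) stop("empty track")
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  site_state <- character(nrow(track))
  seg_rows <- list()
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    if (length(idx) < min_sites) {
      warning("chromosome ", chr, " has fewer than ", min_sites,
              " sites; emitted as one neutral segment")
      st <- rep("neutral", length(idx))
    } else {
      st <- viterbi_states(track$mirrored_baf[idx], track$logratio[idx], model)
    }
    site_state[idx] <- st
    run <- rle(st)
    stop_i <- cumsum(run$lengths)
    start_i <- stop_i - run$lengths + 1
    seg_rows[[chr]] <- data.frame(
      chrom = chr,
      start = track$pos[idx][start_i], end = track$pos[idx][stop_i],
      state = run$values, n_sites = run$lengths,
      mean_mirrored_baf = vapply(seq_along(run$values), function(i)
        mean(track$mirrored_baf[idx][start_i[i]:stop_i[i]]), numeric(1)),
      mean_logratio = vapply(seq_along(run$values), function(i)
        mean(track$logratio[idx][start_i[i]:stop_i[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  res <- structure(list(segments = segments, site_states = site_state,
                        fractional_cna_score = NA_real_,
                        loh_runs = NULL),
                   class = "segmentation_result")
  res$fractional_cna_score <- fractional_cna_score(res)
  res$loh_runs <- find_loh_runs(track, res)
  res
}

#' Fractional copy-number aberration score
#'
#' The total length of segments in a copy-number-changed state (loss or
#' gain) divided by the total length of all reported segments. Copy-neutral
#' LOH contributes to the denominator only: it alters zygosity, not copy
#' number, so a genome whose sole event is cn-LOH scores 0. Segment length
#' is `end - start + 1` over the span of supporting sites.
#'
#' @param result A `segmentation_result` (or a data.frame of segments).
#' @return A ratio in \[0, 1\].
#' @export
fractional_cna_score <- function(result) {
  segments <- if (inherits(result, "segmentation_result"))
    result$segments else result
  if (is.null(segments) || nrow(segments) == 0) stop("empty segment list")
  len <- segments$end - segments$start + 1
  sum(len[segments$state %in% c("loss", "gain")]) / sum(len)
}

#' Find maximal contiguous LOH runs
#'
#' A run is a maximal stretch of consecutive filtered sites (per chromosome)
#' decoded as LOH (cn_loh or loss). For each run the nearest flanking
#' neutral-state heterozygous sites are reported — the positions of the most
#' distal retained heterozygosity on each side (NA where the run reaches the
#' first/last covered site, e.g. a telomeric run).
#'
#' @param track Output of [compute_baf_track()] (sorted by chrom, pos).
#' @param result A `segmentation_result` from [segment_states()].
#' @return A data.frame: `chrom`, `first_pos`, `last_pos`,
#'   `n_contiguous_sites`, `copy_neutral` (TRUE when every site in the run is
#'   cn_loh), `flank_before`, `flank_after`.
#' @export
find_loh_runs <- function(track, result) {
  st <- result$site_states
  stopifnot(length(st) == nrow(track))
  empty <- data.frame(chrom = character(), first_pos = numeric(),
                      last_pos = numeric(), n_contiguous_sites = integer(),
                      copy_neutral = logical(), flank_before = numeric(),
                      flank_after = numeric(), stringsAsFactors = FALSE)
  rows <- list()
  for (chr in unique(track$chrom)) {
    idx <- which(track$chrom == chr)
    loh <- st[idx] %in% c("cn_loh", "loss")
    if (!any(loh)) next
    run <- rle(loh)
    stop_i <- cumsum(run$lengths)
    start_i <- stop_i - run$lengths + 1
    for (r in which(run$values)) {
      i0 <- start_i[r]; i1 <- stop_i[r]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr,
        first_pos = track$pos[idx][i0], last_pos = track$pos[idx][i1],
        n_contiguous_sites = i1 - i0 + 1L,
        copy_neutral = all(st[idx][i0:i1] == "cn_loh"),
        flank_before = if (i0 > 1) track$pos[idx][i0 - 1] else NA_real_,
        flank_after = if (i1 < length(idx)) track$pos[idx][i1 + 1]
                      else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation:", nrow(x$segments), "segment(s) over",
      length(unique(x$segments$chrom)), "chromosome(s)\n")
  cat(sprintf("Fractional copy-number aberration score: %.4g\n",
              x$fractional_cna_score))
  if (nrow(x$loh_runs)) {
    cat("LOH runs:\n")
    print(x$loh_runs)
  } else cat("No LOH runs detected\n")
  invisible(x)
}
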
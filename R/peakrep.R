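#' Random pseudoreplicate split
#'
#' Partitions a fragment table into two halves of sizes `floor(n/2)` and
#' `ceiling(n/2)`, chosen at random without replacement. Deterministic
#' for a fixed seed; the caller's RNG state is untouched.
#'
#' @param fragments `data.frame` of fragments (any columns; rows are the
#'   unit of splitting).
#' @param seed integer seed.
#' @return List of two `data.frame`s whose rows partition the input.
#' @export
split_pseudoreplicates <- function(fragments, seed) {
  n <- nrow(fragments)
  if (n < 2) stop("need at least 2 fragments to split")
  idx <- with_seed(seed, sample.int(n))
  k <- n %/% 2
  list(fragments[sort(idx[seq_len(k)]), , drop = FALSE],
       fragments[sort(idx[(k + 1):n]), , drop = FALSE])
}

#' Minimal Poisson-window broad peak caller
#'
#' A deliberately small enrichment caller for synthetic data: each
#' window of a [window_profile()] is tested against a global Poisson
#' background (one-sided upper tail, `P(X >= count)`), significant
#' windows (`p < p_threshold`) are merged when separated by at most
#' `merge_gap` bp, the per-peak p-value is the minimum window p, and q
#' is the Benjamini-Hochberg adjusted value over all tested windows.
#' This is not a reimplementation of MACS2; real-data peak files come in
#' through [read_peaks()].
#'
#' @param profile a [window_profile()] of fragment counts.
#' @param background_rate expected background fragment count per window.
#' @param p_threshold window-level p cutoff (default 0.05, the relaxed
#'   threshold used before reproducibility filtering).
#' @param merge_gap maximum bp gap between merged significant windows.
#' @return Peak `data.frame` (as [read_peaks()]) sorted by position.
#' @export
call_broad_peaks_minimal <- function(profile, background_rate,
                                     p_threshold = 0.05, merge_gap = 100L) {
  if (background_rate <= 0) stop("background_rate must be > 0")
  if (p_threshold <= 0) stop("p_threshold must be > 0")
  counts <- profile$count %||% profile$value
  p <- ppois(counts - 1, background_rate, lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  sig <- which(p < p_threshold)
  if (!length(sig)) return(empty_peaks())
  sp <- profile[sig, , drop = FALSE]
  sp$p <- p[sig]; sp$q <- q[sig]; sp$cnt <- counts[sig]
  sp <- sp[order(sp$chrom, sp$start), , drop = FALSE]
  new_peak <- c(TRUE, sp$chrom[-1] != sp$chrom[-nrow(sp)] |
                  sp$start[-1] - sp$end[-nrow(sp)] > merge_gap)
  grp <- cumsum(new_peak)
  agg <- function(f, v) as.vector(tapply(v, grp, f))
  data.frame(chrom = agg(function(z) z[1], sp$chrom),
             start = as.integer(agg(min, sp$start)),
             end = as.integer(agg(max, sp$end)),
             name = sprintf("peak_%d", seq_len(max(grp))),
             score = agg(max, sp$cnt),
             strand = ".",
             signal = agg(max, sp$value),
             p = agg(min, sp$p), q = agg(min, sp$q),
             stringsAsFactors = FALSE)
}

#' Reproducible peak retention
#'
#' Implements the ENCODE-style rescue rule: a peak called on the pooled
#' replicates is retained if it overlaps (>= 1 bp) peaks from both
#' biological replicates, or peaks from both pooled pseudoreplicates.
#' This lets a marginal peak in one replicate be rescued by a strong
#' pooled signal.
#'
#' @param pooled peaks called on pooled replicates.
#' @param rep1,rep2 peaks from the two biological replicates.
#' @param psr1,psr2 peaks from the two pooled pseudoreplicates.
#' @return The `pooled` table with logical columns `overlaps_rep1`,
#'   `overlaps_rep2`, `overlaps_psr1`, `overlaps_psr2`, `retained`.
#' @export
retain_reproducible <- function(pooled, rep1, rep2, psr1, psr2) {
  pooled$overlaps_rep1 <- overlaps_any0(pooled, rep1)
  pooled$overlaps_rep2 <- overlaps_any0(pooled, rep2)
  pooled$overlaps_psr1 <- overlaps_any0(pooled, psr1)
  pooled$overlaps_psr2 <- overlaps_any0(pooled, psr2)
  pooled$retained <- (pooled$overlaps_rep1 & pooled$overlaps_rep2) |
    (pooled$overlaps_psr1 & pooled$overlaps_psr2)
  pooled
}

#' FDR filtering of retained peaks
#'
#' Final high-confidence filter on the caller's q-value: histone marks
#' keep `q < 1e-3`, ATAC keeps `q < 1e-4` (strict inequalities). Peaks
#' with undefined q are dropped and counted in a message. Order is
#' preserved.
#'
#' @param peaks peak `data.frame` with a `q` column.
#' @param assay `"histone"` or `"atac"`.
#' @return Filtered peak `data.frame`.
#' @export
filter_q <- function(peaks, assay = c("histone", "atac")) {
  assay <- match.arg(assay)
  cutoff <- if (assay == "histone") 1e-3 else 1e-4
  undef <- is.na(peaks$q)
  if (any(undef))
    message(sprintf("filter_q: dropped %d peak(s) with undefined q", sum(undef)))
  peaks <- peaks[!undef, , drop = FALSE]
  peaks[peaks$q < cutoff, , drop = FALSE]
}
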
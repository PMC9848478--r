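#' Sample sheet constructor
#'
#' One row per sequencing library. `role` distinguishes IP libraries from
#' their chromatin inputs; `spike_mapped_reads` is the number of reads
#' mapping specifically to the exogenous spike-in genome (IP only; the
#' input carries no spike-in in the protocol).
#'
#' @param sample_id,antibody,cell_type character vectors.
#' @param sex `"M"`/`"F"` (optional, `NA` allowed).
#' @param week gestational week label (optional).
#' @param role `"IP"` or `"input"`.
#' @param replicate integer replicate index.
#' @param target_mapped_reads total reads mapped to the target genome.
#' @param spike_mapped_reads total reads mapped to the spike genome.
#' @return `data.frame` sample sheet.
#' @export
sample_sheet <- function(sample_id, antibody, cell_type, sex = NA, week = NA,
                         role = "IP", replicate = 1L,
                         target_mapped_reads, spike_mapped_reads = NA) {
  df <- data.frame(sample_id = as.character(sample_id),
                   antibody = as.character(antibody),
                   cell_type = as.character(cell_type),
                   sex = sex, week = week, role = role,
                   replicate = as.integer(replicate),
                   target_mapped_reads = as.numeric(target_mapped_reads),
                   spike_mapped_reads = as.numeric(spike_mapped_reads),
                   stringsAsFactors = FALSE)
  if (any(df$target_mapped_reads <= 0)) stop("target_mapped_reads must be > 0")
  df
}

#' Spike-in normalization factors
#'
#' For all IP samples sharing an antibody, the factor is
#' `f_s = G / spike_mapped_reads_s` with `G` the geometric mean of the
#' group's spike read totals, so that the geometric mean of the returned
#' factors is exactly 1. The factor compensates global abundance changes
#' of the mark: fewer target-derived reads per spike read means more of
#' the mark per cell, and vice versa. Only the ratio between two samples'
#' factors is identifiable; the geometric-mean reference fixes the scale.
#'
#' @param samples a [sample_sheet()] `data.frame`.
#' @param antibody antibody group to compute factors for.
#' @return `data.frame` with columns `sample_id`, `antibody_group`,
#'   `factor`.
#' @examples
#' sh <- sample_sheet(c("a", "b"), "H3K9me3", c("PGC", "GSC"),
#'                    target_mapped_reads = 1e6,
#'                    spike_mapped_reads = c(1000, 2000))
#' spike_factors(sh, "H3K9me3")
#' @export
spike_factors <- function(samples, antibody) {
  stopifnot_cols(samples, c("sample_id", "antibody", "role", "spike_mapped_reads"))
  grp <- samples[samples$antibody == antibody & samples$role == "IP", ]
  if (!nrow(grp)) stop("no IP samples for antibody ", antibody)
  bad <- is.na(grp$spike_mapped_reads) | grp$spike_mapped_reads <= 0
  if (any(bad))
    stop("zero/missing spike reads for sample(s): ",
         paste(grp$sample_id[bad], collapse = ", "))
  g <- exp(mean(log(grp$spike_mapped_reads)))
  data.frame(sample_id = grp$sample_id, antibody_group = antibody,
             factor = g / grp$spike_mapped_reads, stringsAsFactors = FALSE)
}

#' Spike-in / input / length normalized signal
#'
#' For region r and IP sample s,
#' \deqn{NC_{r,s} = f_s \frac{c^{IP}_{r,s} + \epsilon}{\hat c^{input}_{r,s} + \epsilon} \Big/ (L_r/1000)}
#' where \eqn{\hat c^{input}} is the paired input count depth-scaled to
#' the IP sample's `target_mapped_reads` and \eqn{f_s} the spike-in
#' factor (1 for depth-only normalization). The pseudocount keeps the
#' ratio finite on zero counts. Each IP column must have an input column
#' from the same cell type; pairing is by `cell_type` (and `sex` when
#' present) or an explicit `pairing` map.
#'
#' @param ip_counts region x IP-sample integer matrix (columns named by
#'   `sample_id`).
#' @param input_counts region x input-sample matrix.
#' @param samples [sample_sheet()] covering all columns.
#' @param factors factors `data.frame` from [spike_factors()], or `NULL`
#'   for depth-only normalization (all factors 1).
#' @param regions region table supplying lengths `L_r` (rows matched to
#'   `rownames(ip_counts)` by `id`).
#' @param epsilon pseudocount (default 0.5).
#' @param pairing optional named character vector `ip sample -> input sample`.
#' @return A `signal_matrix`: list with `values` (region x sample), the
#'   `regions`, `samples` and `epsilon` used.
#' @export
normalize_signal <- function(ip_counts, input_counts, samples, factors = NULL,
                             regions, epsilon = 0.5, pairing = NULL) {
  ip_counts <- as.matrix(ip_counts); input_counts <- as.matrix(input_counts)
  if (epsilon <= 0 && any(input_counts == 0))
    stop("epsilon must be > 0 when input contains zero counts")
  if (any(ip_counts < 0) || any(input_counts < 0)) stop("counts must be >= 0")
  ids <- rownames(ip_counts) %||% regions$id
  regions <- regions[match(ids, regions$id), , drop = FALSE]
  if (anyNA(regions$id)) stop("count matrix rows missing from region table")
  L <- regions$end - regions$start

  meta <- function(sid) {
    i <- match(sid, samples$sample_id)
    if (is.na(i)) stop("sample not in sheet: ", sid)
    samples[i, ]
  }
  if (is.null(pairing)) {
    pairing <- vapply(colnames(ip_counts), function(sid) {
      m <- meta(sid)
      cand <- samples[samples$role == "input" &
                      samples$cell_type == m$cell_type, ]
      if (!is.na(m$sex) && any(!is.na(cand$sex)))
        cand <- cand[is.na(cand$sex) | cand$sex == m$sex, ]
      cand <- cand[cand$sample_id %in% colnames(input_counts), ]
      if (!nrow(cand))
        stop("no input pairing found for IP sample ", sid)
      cand$sample_id[1]
    }, "")
  }

  fmap <- if (is.null(factors)) NULL else stats::setNames(factors$factor, factors$sample_id)
  nc <- matrix(NA_real_, nrow(ip_counts), ncol(ip_counts),
               dimnames = list(ids, colnames(ip_counts)))
  for (sid in colnames(ip_counts)) {
    m <- meta(sid)
    inp_id <- pairing[[sid]]
    mi <- meta(inp_id)
    scale <- m$target_mapped_reads / mi$target_mapped_reads
    chat <- input_counts[, inp_id] * scale
    f <- if (is.null(fmap)) 1 else fmap[[sid]]
    if (is.null(f) || is.na(f)) stop("no normalization factor for sample ", sid)
    nc[, sid] <- f * (ip_counts[, sid] + epsilon) / (chat + epsilon) / (L / 1000)
  }
  structure(list(values = nc, regions = regions, samples = samples,
                 epsilon = epsilon, pairing = pairing),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d regions x %d samples (epsilon = %g)\n",
              nrow(x$values), ncol(x$values), x$epsilon))
  invisible(x)
}

#' Replicate-mean signal per cell type
#'
#' Averages the normalized columns of a [normalize_signal()] result over
#' the IP replicates of one antibody in one cell type.
#'
#' @param signal a `signal_matrix`.
#' @param antibody,cell_type group selectors.
#' @return Named numeric vector of mean NC per region.
#' @export
signal_mean <- function(signal, antibody, cell_type) {
  s <- signal$samples
  keep <- s$sample_id[s$role == "IP" & s$antibody == antibody &
                      s$cell_type == cell_type]
  keep <- intersect(keep, colnames(signal$values))
  if (!length(keep)) stop("no IP columns for ", antibody, " in ", cell_type)
  rowMeans(signal$values[, keep, drop = FALSE])
}

#' Fixed-step window profiles
#'
#' Counts fragments overlapping sliding windows (default 50 bp windows
#' at 25 bp offset) and multiplies by a per-sample normalization factor.
#' Bin mode is the same call with `step == window_size` (5 kb bins for
#' ChIP genome comparisons, 1 kb for ATAC).
#'
#' @param fragments `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_lengths named vector of chromosome lengths to tile.
#' @param window_size,step window geometry in bp; `step <= window_size`.
#' @param factor per-sample normalization factor applied to every window.
#' @return `data.frame` with `chrom`, `start`, `end`, `value` and class
#'   `window_profile`.
#' @export
window_profile <- function(fragments, chrom_lengths, window_size = 50L,
                           step = 25L, factor = 1) {
  if (window_size <= 0 || step <= 0) stop("window_size and step must be > 0")
  if (step > window_size)
    stop("step > window_size would leave unscanned gaps")
  tiles <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, len)),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, tiles)
  counts <- if (nrow(fragments)) {
    GenomicRanges::countOverlaps(as_granges0(prof), as_granges0(fragments))
  } else rep(0L, nrow(prof))
  prof$count <- as.integer(counts)
  prof$value <- counts * factor
  structure(prof, class = c("window_profile", "data.frame"),
            window_size = as.integer(window_size), step = as.integer(step),
            factor = factor)
}

#' Export a window profile as bedGraph
#'
#' @param profile a [window_profile()].
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  write.table(profile[, c("chrom", "start", "end", "value")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
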
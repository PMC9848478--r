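# Independent brute-force oracles. These deliberately avoid the package's
# IRanges-backed code paths: plain loops over 0-based half-open intervals.

# >=1 bp intersection of two half-open intervals
ov1 <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1

# logical vector: does query row i overlap any subject row?
oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(ov1(query$chrom[i], query$start[i], query$end[i],
            subject$chrom, subject$start, subject$end))
  }, TRUE)
}

oracle_retain <- function(pooled, rep1, rep2, psr1, psr2) {
  r1 <- oracle_overlaps_any(pooled, rep1)
  r2 <- oracle_overlaps_any(pooled, rep2)
  p1 <- oracle_overlaps_any(pooled, psr1)
  p2 <- oracle_overlaps_any(pooled, psr2)
  (r1 & r2) | (p1 & p2)
}

oracle_occupancy <- function(nc, peaks, regions, negative_regions) {
  thr <- mean(nc[negative_regions$id])
  vapply(seq_len(nrow(regions)), function(i) {
    hit <- any(ov1(regions$chrom[i], regions$start[i], regions$end[i],
                   peaks$chrom, peaks$start, peaks$end))
    hit && nc[[regions$id[i]]] > thr
  }, TRUE)
}

oracle_nearest <- function(tes, promoters, max_dist = 100000) {
  gid <- promoters$gene_id
  out <- NULL
  for (i in seq_len(nrow(tes))) {
    mid <- (tes$start[i] + tes$end[i]) %/% 2
    best <- NULL
    for (j in seq_len(nrow(promoters))) {
      if (promoters$chrom[j] != tes$chrom[i]) next
      signed <- if (promoters$strand[j] == "+") mid - promoters$tss[j]
                else promoters$tss[j] - mid
      if (abs(signed) >= max_dist) next
      if (is.null(best) || abs(signed) < abs(best$d) ||
          (abs(signed) == abs(best$d) && gid[j] < best$g))
        best <- list(d = signed, g = gid[j])
    }
    if (!is.null(best))
      out <- rbind(out, data.frame(te_id = tes$id[i], gene_id = best$g,
                                   distance = best$d))
  }
  out
}

oracle_transitions <- function(sigA, sigB) {
  # dictionary counting
  d <- new.env(parent = emptyenv())
  for (i in seq_along(sigA)) {
    key <- paste(sigA[i], sigB[i], sep = "->")
    d[[key]] <- (d[[key]] %||% 0) + 1
  }
  keys <- ls(d)
  stats::setNames(vapply(keys, function(k) d[[k]], 0), keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-enumeration normal score for the rank-sum statistic:
# enumerate all choose(N, n1) group assignments of the pooled ranks and
# convert the exact inclusive tail probability of the observed statistic
# into a Z score.
oracle_wilcoxon_z <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  combs <- utils::combn(N, n1)
  w_all <- apply(combs, 2, function(idx) sum(rk[idx]))
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  p <- min(lo, hi)               # one-sided inclusive tail
  stats::qnorm(p)                # negative; magnitude is what matters
}

# random peak/region fixture builders
rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                           max_len = 2000, prefix = "iv") {
  s <- floor(runif(n, 0, max_pos))
  data.frame(id = sprintf("%s_%d", prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = as.integer(s),
             end = as.integer(s + 1 + floor(runif(n, 0, max_len))),
             strand = ".", kind = "te", stringsAsFactors = FALSE)
}
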
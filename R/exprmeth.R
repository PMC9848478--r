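#' RPKM-style expression transform
#'
#' Maps a per-region read count to `log2(RPKM + 1)`, where the million
#' in RPKM is restricted to reads mapping to protein-coding gene regions
#' (`T_pc`), and the kilobase is the region length:
#' `log2( count / (T_pc/1e6) / (L_r/1000) + 1 )`.
#'
#' @param count non-negative read count(s).
#' @param T_pc total protein-coding-mapped reads of the sample.
#' @param L_r region length in bp.
#' @return Numeric value(s) on the `log2(RPKM+1)` scale.
#' @examples
#' rpkm_log_transform(10, 1e6, 1000)  # log2(11)
#' @export
rpkm_log_transform <- function(count, T_pc, L_r) {
  if (any(count < 0)) stop("count must be >= 0")
  if (any(T_pc <= 0) || any(L_r <= 0)) stop("T_pc and L_r must be > 0")
  log2(count / (T_pc / 1e6) / (L_r / 1000) + 1)
}

#' Expression category thresholds
#'
#' The empirical thresholds separating the two modes of the bimodal
#' `log2(RPKM+1)` distribution: TEs use 0.4/1.4, genes use 1.5/5.0.
#'
#' @param kind `"te"` or `"gene"`.
#' @param low,high override the defaults; must satisfy `low < high`.
#' @return List with class `category_thresholds`.
#' @export
category_thresholds <- function(kind = c("te", "gene"), low = NULL, high = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "te") c(0.4, 1.4) else c(1.5, 5.0)
  low <- low %||% def[1]; high <- high %||% def[2]
  if (low >= high) stop("low threshold must be < high")
  structure(list(kind = kind, low = low, high = high),
            class = "category_thresholds")
}

#' Categorize expression values
#'
#' Boundary behavior follows the printed rules exactly:
#' `value <= low` is not expressed, `low < value <= high` is lowly
#' expressed, `value > high` is expressed.
#'
#' @param value numeric vector on the `log2(RPKM+1)` scale.
#' @param thresholds a [category_thresholds()].
#' @return Factor with levels `not_expressed`, `lowly_expressed`,
#'   `expressed`.
#' @export
categorize_expression <- function(value, thresholds = category_thresholds("te")) {
  if (any(value < 0)) stop("expression values must be >= 0 on log2(RPKM+1) scale")
  out <- ifelse(value <= thresholds$low, "not_expressed",
         ifelse(value <= thresholds$high, "lowly_expressed", "expressed"))
  factor(out, levels = c("not_expressed", "lowly_expressed", "expressed"))
}

#' Threshold differential-expression rule
#'
#' A region is differentially expressed between conditions A and B when
#' (i) the expression differs at least 4-fold, read on the
#' `log2(RPKM+1)` scale as `|B - A| >= 2`, and (ii) the higher of the
#' two values exceeds `min_expr` (0.4, the TE not-expressed bound).
#' When an external significance vector is supplied (e.g. from a count
#' model fitted elsewhere), it is AND-combined with the threshold rule.
#'
#' @param valueA,valueB numeric vectors on the `log2(RPKM+1)` scale.
#' @param id optional region ids.
#' @param min_expr floor on the higher value (default 0.4).
#' @param min_delta minimum `|B - A|` (default 2, i.e. 4-fold).
#' @param significant optional logical vector of external DE
#'   significance, AND-combined when present.
#' @return `data.frame` with `id`, `delta` (B - A), `higher_value`,
#'   `de`, `direction` (`up` = higher in B, `down`, `none`).
#' @export
call_de <- function(valueA, valueB, id = NULL, min_expr = 0.4, min_delta = 2,
                    significant = NULL) {
  stopifnot(length(valueA) == length(valueB))
  delta <- valueB - valueA
  higher <- pmax(valueA, valueB)
  de <- abs(delta) >= min_delta & higher > min_expr
  if (!is.null(significant)) de <- de & significant
  data.frame(id = id %||% as.character(seq_along(delta)),
             delta = delta, higher_value = higher, de = de,
             direction = ifelse(!de, "none", ifelse(delta > 0, "up", "down")),
             stringsAsFactors = FALSE)
}

#' Region-average DNA methylation
#'
#' Averages per-CpG methylated fractions over the CpGs of each region
#' whose bisulfite coverage is more than `min_coverage` reads (strictly
#' greater; a CpG at exactly 5x is excluded under the default). The mean
#' is unweighted. Regions with no qualifying CpG have undefined
#' methylation (`defined = FALSE`, `mean_meth = NA`).
#'
#' @param cpgs `data.frame` with columns `meth_reads`, `total_reads` and
#'   either a `region_id` column or `chrom`/`pos` columns to be
#'   intersected with `regions`.
#' @param regions optional region table used to place CpGs when `cpgs`
#'   has no `region_id`.
#' @param min_coverage coverage that must be exceeded (default 5).
#' @return `data.frame` with `region_id`, `mean_meth`, `n_cpgs_used`,
#'   `defined`.
#' @export
region_methylation <- function(cpgs, regions = NULL, min_coverage = 5L) {
  if (any(cpgs$meth_reads > cpgs$total_reads) || any(cpgs$meth_reads < 0))
    stop("need 0 <= meth_reads <= total_reads")
  if (is.null(cpgs$region_id)) {
    if (is.null(regions)) stop("need `regions` when cpgs carry no region_id")
    stopifnot_cols(cpgs, c("chrom", "pos"))
    cg <- GenomicRanges::GRanges(cpgs$chrom,
                                 IRanges::IRanges(cpgs$pos + 1L, cpgs$pos + 1L))
    hit <- GenomicRanges::findOverlaps(cg, as_granges0(regions))
    cpgs <- cpgs[S4Vectors::queryHits(hit), , drop = FALSE]
    cpgs$region_id <- regions$id[S4Vectors::subjectHits(hit)]
  }
  ids <- if (!is.null(regions)) regions$id else unique(cpgs$region_id)
  ok <- cpgs$total_reads > min_coverage
  frac <- cpgs$meth_reads / cpgs$total_reads
  mean_by <- tapply(frac[ok], factor(cpgs$region_id[ok], levels = ids), mean)
  n_by <- tapply(rep(1L, sum(ok)), factor(cpgs$region_id[ok], levels = ids), sum)
  n_by[is.na(n_by)] <- 0L
  data.frame(region_id = ids, mean_meth = as.numeric(mean_by),
             n_cpgs_used = as.integer(n_by),
             defined = as.integer(n_by) >= 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}
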
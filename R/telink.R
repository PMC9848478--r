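#' Assign TEs to their nearest promoter
#'
#' Each TE is anchored at its midpoint and assigned to the gene whose
#' TSS is nearest, provided the distance is strictly below `max_dist`
#' (default 100 kb). Distances are signed in gene orientation: negative
#' means the TE lies 5' (upstream) of the TSS. Equidistant ties break to
#' the lexicographically smallest gene id. TEs with no TSS within range
#' are omitted.
#'
#' @param tes TE region table.
#' @param promoters promoter table carrying `tss`, `strand` and
#'   `gene_id` (as built by [promoter_from_tss()]); `id` is used when
#'   `gene_id` is absent.
#' @param max_dist exclusive distance cutoff in bp.
#' @return `data.frame` with `te_id`, `gene_id`, `distance` (signed),
#'   `within_window`.
#' @export
assign_nearest_promoter <- function(tes, promoters, max_dist = 100000L) {
  stopifnot_cols(promoters, c("chrom", "tss", "strand"), "promoters")
  gid <- promoters$gene_id %||% promoters$id
  gid <- ifelse(is.na(gid), promoters$id, gid)
  out <- vector("list", nrow(tes))
  mid <- (tes$start + tes$end) %/% 2
  for (i in seq_len(nrow(tes))) {
    same <- which(promoters$chrom == tes$chrom[i])
    if (!length(same)) next
    plus <- promoters$strand[same] == "+"
    signed <- ifelse(plus, mid[i] - promoters$tss[same],
                     promoters$tss[same] - mid[i])
    absd <- abs(signed)
    inwin <- absd < max_dist
    if (!any(inwin)) next
    cand <- same[inwin]; signed <- signed[inwin]; absd <- absd[inwin]
    ord <- order(absd, gid[cand])
    j <- ord[1]
    out[[i]] <- data.frame(te_id = tes$id[i], gene_id = gid[cand][j],
                           distance = signed[j], within_window = TRUE,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(te_id = character(), gene_id = character(),
                      distance = integer(), within_window = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Correlation of TE and gene differential expression over links
#'
#' Pearson correlation between the expression change of each linked TE
#' and the change of its assigned gene. Undefined (`NA`, flagged) below
#' 3 complete pairs.
#'
#' @param links `data.frame` from [assign_nearest_promoter()].
#' @param te_delta named numeric: expression delta per TE id.
#' @param gene_delta named numeric: expression delta per gene id.
#' @return List with `r`, `n`, `level` (and `defined`).
#' @export
link_correlation <- function(links, te_delta, gene_delta) {
  x <- te_delta[links$te_id]
  y <- gene_delta[links$gene_id]
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(r = NA_real_, n = n, level = NA_character_, defined = FALSE))
  es <- pearson(x[ok], y[ok])
  list(r = es$value, n = es$n, level = es$level, defined = TRUE)
}

#' Distance-binned TE-gene correlation profile
#'
#' Splits links into signed-distance bins tiling [-100 kb, +100 kb) and
#' computes [link_correlation()] within each bin; bins with fewer than 3
#' pairs are reported as undefined.
#'
#' @inheritParams link_correlation
#' @param bin_width bin width in bp; must divide 200 kb.
#' @param max_dist window half-width (default 100 kb).
#' @return `data.frame` with `bin_start`, `bin_end`, `r`, `n`.
#' @export
distance_binned_correlation <- function(links, te_delta, gene_delta,
                                        bin_width = 10000L,
                                        max_dist = 100000L) {
  if ((2 * max_dist) %% bin_width != 0)
    stop("bin_width must divide the full window span")
  edges <- seq(-max_dist, max_dist, by = bin_width)
  res <- lapply(seq_len(length(edges) - 1L), function(i) {
    sel <- links$distance >= edges[i] & links$distance < edges[i + 1]
    lc <- link_correlation(links[sel, , drop = FALSE], te_delta, gene_delta)
    data.frame(bin_start = edges[i], bin_end = edges[i + 1],
               r = lc$r, n = lc$n)
  })
  do.call(rbind, res)
}

#' Classify putative regulatory TEs
#'
#' Among TEs differentially up-regulated in the target cell type, a TE
#' is a putative regulator of its linked gene when it lies upstream of
#' the TSS (negative signed distance) and carries an active chromatin
#' mark or an ATAC signal.
#'
#' @param links `data.frame` from [assign_nearest_promoter()].
#' @param de_up named logical per TE id: up-regulated in the target.
#' @param active named logical per TE id: any active mark present.
#' @param atac named logical per TE id: ATAC signal present.
#' @return `data.frame` with `te_id`, `gene_id`, `upstream`,
#'   `has_active_mark_or_atac`, `putative_regulatory`.
#' @export
classify_regulatory_te <- function(links, de_up, active, atac) {
  sel <- links[de_up[links$te_id] %in% TRUE, , drop = FALSE]
  up <- sel$distance < 0
  act <- (active[sel$te_id] %in% TRUE) | (atac[sel$te_id] %in% TRUE)
  data.frame(te_id = sel$te_id, gene_id = sel$gene_id,
             upstream = up, has_active_mark_or_atac = act,
             putative_regulatory = up & act,
             stringsAsFactors = FALSE, row.names = NULL)
}
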
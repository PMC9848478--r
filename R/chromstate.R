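#' Mark vocabularies
#'
#' The assay panel consists of eight marks/assays. For state
#' classification, `5mC`, `H3K9me3`, `H3K27me3` and `H2aK119ub` form the
#' repressive set and `H3K4me3`/`H3K27ac` the active set; `H3K4me1` and
#' `ATAC` are tracked as flags outside both sets.
#'
#' @format Character vectors.
#' @export
mark_panel <- function() c("5mC", "H3K9me3", "H3K27me3", "H2aK119ub",
                           "H3K4me3", "H3K4me1", "H3K27ac", "ATAC")

#' @rdname mark_panel
#' @export
repressive_marks <- function() c("5mC", "H3K9me3", "H3K27me3", "H2aK119ub")

#' @rdname mark_panel
#' @export
active_marks <- function() c("H3K4me3", "H3K27ac")

#' Binary occupancy from peaks and normalized signal
#'
#' A region is occupied by a mark in a cell type when both conditions
#' hold: it overlaps at least one retained broad peak, and its
#' normalized signal exceeds the mean normalized signal over negative
#' regions. Occupancy is evaluated per cell type on the replicate-mean
#' normalized counts. When `negative_regions` is `NULL` the negative set
#' defaults to the regions (of the same table) overlapping no retained
#' peak.
#'
#' @param nc named numeric vector of replicate-mean normalized counts,
#'   names = region ids; must cover `regions` and the negative set.
#' @param retained_peaks retained peak `data.frame`.
#' @param regions region table to call occupancy on.
#' @param negative_regions optional region table defining the background
#'   threshold; `NULL` for the peak-free default.
#' @return Named logical vector over `regions$id`.
#' @export
call_occupancy <- function(nc, retained_peaks, regions, negative_regions = NULL) {
  has_peak <- overlaps_any0(regions, retained_peaks)
  if (is.null(negative_regions)) {
    negative_regions <- regions[!has_peak, , drop = FALSE]
  }
  if (!nrow(negative_regions))
    stop("negative region set is empty; occupancy threshold undefined")
  neg_nc <- nc[negative_regions$id]
  if (anyNA(neg_nc)) stop("signal missing for some negative regions")
  thr <- mean(neg_nc)
  val <- nc[regions$id]
  if (anyNA(val)) stop("signal missing for some regions")
  stats::setNames(has_peak & (val > thr), regions$id)
}

#' 5mC occupancy from region methylation
#'
#' DNA methylation enters the state model through the region-average
#' methylation (see [region_methylation()]), not through peaks: a region
#' is 5mC-occupied when its mean methylation is at or above `threshold`.
#' Regions with undefined methylation (no sufficiently covered CpG) are
#' called unoccupied and flagged.
#'
#' @param region_meth `data.frame` from [region_methylation()] with
#'   columns `region_id`, `mean_meth`, `defined`.
#' @param threshold methylated fraction cutoff in (0,1), default 0.5.
#' @return Named logical vector with attribute `undefined` listing the
#'   ids whose methylation was undefined.
#' @export
call_meth_occupancy <- function(region_meth, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  occ <- !is.na(region_meth$mean_meth) & region_meth$defined &
    region_meth$mean_meth >= threshold
  structure(stats::setNames(occ, region_meth$region_id),
            undefined = region_meth$region_id[!region_meth$defined])
}

#' Assemble an occupancy matrix
#'
#' @param ... named logical vectors (one per mark), identical region ids.
#' @return region x mark logical matrix.
#' @export
occupancy_matrix <- function(...) {
  cols <- list(...)
  if (length(cols) == 1 && is.list(cols[[1]]) && !is.data.frame(cols[[1]]))
    cols <- cols[[1]]
  ids <- names(cols[[1]])
  for (v in cols)
    if (!identical(names(v), ids)) stop("occupancy vectors disagree on region ids")
  m <- do.call(cbind, lapply(cols, as.logical))
  dimnames(m) <- list(ids, names(cols))
  m
}

#' Combinatorial chromatin-state assignment
#'
#' Each region's boolean mark vector is summarized as its repressive
#' signature (the exact subset of repressive marks present, e.g.
#' `"5mC+H3K9me3"`), its active subset, an H3K4me1 flag, and a derived
#' category: `bivalent` when both a repressive and an active mark are
#' present, `repressive` / `active` when only one side is, and `neutral`
#' otherwise (H3K4me1 or ATAC alone leave a region neutral, matching
#' their treatment as flags outside the two classifying sets). The four
#' categories partition any region set.
#'
#' @param occ region x mark logical matrix (rownames = region ids,
#'   colnames from [mark_panel()]; missing marks are treated as absent).
#' @return `data.frame` with `id`, `signature`, `active_signature`,
#'   `h3k4me1`, `atac`, `category`.
#' @export
assign_states <- function(occ) {
  occ <- as.matrix(occ)
  if (is.null(rownames(occ))) stop("occupancy matrix must have region-id rownames")
  grab <- function(marks) {
    got <- intersect(marks, colnames(occ))
    m <- matrix(FALSE, nrow(occ), length(marks), dimnames = list(NULL, marks))
    m[, got] <- occ[, got]
    m
  }
  rep_m <- grab(repressive_marks())
  act_m <- grab(active_marks())
  sig_of <- function(m) {
    apply(m, 1, function(r) paste(colnames(m)[r], collapse = "+"))
  }
  rep_sig <- sig_of(rep_m); act_sig <- sig_of(act_m)
  has_rep <- rowSums(rep_m) > 0; has_act <- rowSums(act_m) > 0
  category <- ifelse(has_rep & has_act, "bivalent",
              ifelse(has_rep, "repressive",
              ifelse(has_act, "active", "neutral")))
  data.frame(id = rownames(occ),
             signature = ifelse(rep_sig == "", "none", rep_sig),
             active_signature = ifelse(act_sig == "", "none", act_sig),
             h3k4me1 = if ("H3K4me1" %in% colnames(occ)) occ[, "H3K4me1"] else FALSE,
             atac = if ("ATAC" %in% colnames(occ)) occ[, "ATAC"] else FALSE,
             category = category, stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-type specificity of occupancy
#'
#' Per region and mark, classifies occupancy as specific to one cell
#' type, shared, or absent from both. The four labels partition the
#' region x mark grid.
#'
#' @param occA,occB occupancy matrices over identical regions and marks.
#' @param labels length-2 character: names of the two cell types.
#' @return Character matrix (region x mark) with entries
#'   `"<A>-specific"`, `"<B>-specific"`, `"shared"`, `"neither"`.
#' @export
specificity <- function(occA, occB, labels = c("A", "B")) {
  if (!identical(dimnames(occA), dimnames(occB)))
    stop("occupancy matrices must share regions and marks")
  out <- matrix("neither", nrow(occA), ncol(occA), dimnames = dimnames(occA))
  out[occA & !occB] <- paste0(labels[1], "-specific")
  out[!occA & occB] <- paste0(labels[2], "-specific")
  out[occA & occB] <- "shared"
  out
}

#' Repressive-signature transition table
#'
#' Cross-tabulates repressive signatures between two cell types over
#' matched regions: entry (i, j) counts regions with signature i in A
#' and signature j in B. The grand total equals the number of regions;
#' row sums equal signature counts in A. Transitions out of `"none"`
#' into a non-empty signature are the de novo gains.
#'
#' @param statesA,statesB [assign_states()] tables over the same ids.
#' @return A `table` (source signature x destination signature) with
#'   class `transition_table`.
#' @export
transitions <- function(statesA, statesB) {
  if (!setequal(statesA$id, statesB$id) || nrow(statesA) != nrow(statesB))
    stop("state tables must cover identical region ids")
  statesB <- statesB[match(statesA$id, statesB$id), ]
  tab <- table(source = statesA$signature, destination = statesB$signature)
  class(tab) <- c("transition_table", class(tab))
  tab
}

#' De novo repressive occupancy
#'
#' Regions carrying no repressive mark in `statesA` but a non-empty
#' repressive signature in `statesB`.
#'
#' @inheritParams transitions
#' @return Character vector of region ids.
#' @export
de_novo_regions <- function(statesA, statesB) {
  statesB <- statesB[match(statesA$id, statesB$id), ]
  statesA$id[statesA$signature == "none" & statesB$signature != "none"]
}

#' TE family enrichment in a subgroup
#'
#' Compares family composition of a subgroup of regions against a
#' background superset: the expected count of family f is
#' `|subgroup| * n_background(f) / |background|`, the enrichment rate is
#' observed/expected, and the table-level effect size is Cohen's w from
#' [chisq_gof_effect_size()].
#'
#' @param subgroup,background region tables with a `te_family` column;
#'   `subgroup` must be a subset of `background`.
#' @param family_col attribute column holding the family label.
#' @return `data.frame` (family, observed, expected, enrichment) with
#'   attribute `effect_size` (an `effect_size` object).
#' @export
family_enrichment <- function(subgroup, background, family_col = "te_family") {
  if (!nrow(subgroup) || !nrow(background))
    stop("subgroup and background must be non-empty")
  if (!all(subgroup$id %in% background$id))
    stop("subgroup must be a subset of background")
  fams <- sort(unique(background[[family_col]]))
  obs <- as.vector(table(factor(subgroup[[family_col]], levels = fams)))
  bg <- as.vector(table(factor(background[[family_col]], levels = fams)))
  expd <- nrow(subgroup) * bg / nrow(background)
  keep <- bg > 0
  es <- chisq_gof_effect_size(obs[keep], expd[keep])
  structure(data.frame(family = fams[keep], observed = obs[keep],
                       expected = expd[keep],
                       enrichment = obs[keep] / expd[keep],
                       stringsAsFactors = FALSE),
            effect_size = es)
}
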
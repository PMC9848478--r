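#' Synthetic-world configuration
#'
#' Parameters of the ground-truth generator. The generator emulates the
#' statistical structure the pipeline assumes: negative-binomial
#' IP/input counts, an exogenous spike-in at a fixed cell fraction
#' (1/20) whose read total scales with sequencing depth divided by the
#' cellular abundance of the mark, mark-by-cell-type global abundance
#' multipliers, region state vectors drawn from a joint distribution
#' over the eight-mark panel for a cell-type pair, state-coupled bimodal
#' expression with planted differential-expression deltas, TE-gene delta
#' coupling at correlation `rho`, and binomial CpG methylation with
#' variable coverage. All IP libraries of an antibody group are
#' "sequenced" to matched nominal depth; the spike factor computed from
#' raw spike totals is only depth-comparable under that convention.
#'
#' @param seed master seed; each output type derives its own stream.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_promoters,n_tes region counts.
#' @param te_family_proportions named proportions over TE families.
#' @param young_families families biased toward H3K9me3 states.
#' @param young_k9_bias multiplicative weight on H3K9me3-containing
#'   states for young families.
#' @param te_length_range TE length range in bp.
#' @param state_distribution `data.frame(stateA, stateB, prob)` of
#'   "+"-joined mark subsets; see [default_state_distribution()].
#' @param cell_types length-2 character (reference first).
#' @param global_multiplier named list `mark -> c(A = , B = )` of global
#'   abundance multipliers (default all 1).
#' @param nb_mean_occupied,nb_mean_unoccupied,nb_input_mean,nb_dispersion
#'   negative-binomial count model.
#' @param n_replicates IP replicates per mark and cell type.
#' @param spike_cell_fraction spike-in cell admixture (default 1/20).
#' @param expr_base_te,expr_base_gene category base means on the
#'   `log2(RPKM+1)` scale (not/lowly/expressed).
#' @param expr_noise_sd expression noise sd (default 0.1).
#' @param de_fraction fraction of regions with a planted DE delta.
#' @param de_delta_range range of planted (up) deltas.
#' @param null_delta_sd sd of non-DE delta jitter.
#' @param rho TE-gene delta correlation for linked pairs.
#' @param meth_occupied_mean,meth_unoccupied_mean true regional
#'   methylation for 5mC-occupied / unoccupied regions.
#' @param cpgs_per_region_mean,coverage_mean,beta_concentration CpG
#'   placement, coverage and per-CpG dispersion.
#' @return List with class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L, chrom_length = 1.5e6,
                             n_promoters = 120L, n_tes = 240L,
                             te_family_proportions = c(SVA = 0.08, L1HS = 0.07,
                               ERVK = 0.10, Alu = 0.30, L1 = 0.20,
                               `DNA:hAT` = 0.15, L2 = 0.10),
                             young_families = c("SVA", "L1HS", "ERVK"),
                             young_k9_bias = 3,
                             te_length_range = c(300L, 3000L),
                             state_distribution = default_state_distribution(),
                             cell_types = c("GSC", "PGC"),
                             global_multiplier = NULL,
                             nb_mean_occupied = 100, nb_mean_unoccupied = 4,
                             nb_input_mean = 20, nb_dispersion = 10,
                             n_replicates = 2L,
                             spike_cell_fraction = 1 / 20,
                             expr_base_te = c(0.1, 0.9, 2.5),
                             expr_base_gene = c(0.3, 3.0, 7.0),
                             expr_noise_sd = 0.1,
                             de_fraction = 0.2,
                             de_delta_range = c(2.5, 4),
                             null_delta_sd = 0.3,
                             rho = 0.5,
                             meth_occupied_mean = 0.85,
                             meth_unoccupied_mean = 0.10,
                             cpgs_per_region_mean = 10,
                             coverage_mean = 15,
                             beta_concentration = 50) {
  p <- state_distribution$prob
  if (abs(sum(p) - 1) > 1e-8) stop("state probabilities must sum to 1")
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (is.null(global_multiplier)) {
    marks <- setdiff(mark_panel(), "5mC")
    global_multiplier <- lapply(stats::setNames(marks, marks),
                                function(m) stats::setNames(c(1, 1), cell_types))
  }
  if (any(unlist(global_multiplier) <= 0)) stop("multipliers must be > 0")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default joint state distribution
#'
#' Archetypal state flows between a somatic reference (cell A) and a
#' hypomethylated germ-cell type (cell B): global 5mC loss with
#' derepression, H3K9me3 retention at a subset of (young) TEs,
#' Polycomb (H3K27me3/H2aK119ub) compensation at formerly methylated
#' regions, stable bivalent and active states, and a neutral
#' H3K4me1-only compartment.
#'
#' @return `data.frame` with columns `stateA`, `stateB`, `prob`.
#' @export
default_state_distribution <- function() {
  data.frame(
    stateA = c("5mC", "5mC+H3K9me3", "5mC+H3K9me3", "5mC",
               "H3K27me3", "H3K27me3+H3K4me3", "H3K4me3+H3K27ac+ATAC",
               "H3K4me1", "none", "5mC"),
    stateB = c("none", "H3K9me3", "5mC+H3K9me3", "H3K27me3+H2aK119ub",
               "H3K27me3+H2aK119ub", "H3K27me3+H3K4me3",
               "H3K4me3+H3K27ac+ATAC", "H3K4me1", "none", "5mC"),
    prob = c(0.14, 0.12, 0.08, 0.10, 0.08, 0.10, 0.18, 0.08, 0.07, 0.05),
    stringsAsFactors = FALSE)
}

state_to_occ <- function(states) {
  marks <- mark_panel()
  m <- matrix(FALSE, length(states), length(marks),
              dimnames = list(names(states), marks))
  for (i in seq_along(states)) {
    if (states[i] != "none")
      m[i, strsplit(states[i], "+", fixed = TRUE)[[1]]] <- TRUE
  }
  m
}

#' Simulate a genome annotation
#'
#' Promoter TSSs are placed on a jittered grid (so windows never
#' overlap or clip), strands drawn at random; TEs are placed uniformly
#' with lengths and family labels from the configuration. Deterministic
#' per seed.
#'
#' @param config a [synthetic_config()].
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(config) {
  spec <- promoter_window_spec()
  chroms <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                            paste0("chr", seq_len(config$n_chromosomes)))
  width <- spec$upstream + spec$downstream
  per_chrom <- ceiling(config$n_promoters / length(chroms))
  spacing <- (config$chrom_length - 2 * width) / (per_chrom + 1)
  if (spacing < 1.5 * width)
    stop("infeasible packing: chromosome too short for requested promoters")
  with_seed(derive_seed(config$seed, "annotation"), {
    proms <- list(); k <- 0
    for (ch in names(chroms)) {
      for (i in seq_len(per_chrom)) {
        if (k >= config$n_promoters) break
        k <- k + 1
        tss <- round(width + i * spacing + runif(1, -spacing / 4, spacing / 4))
        strand <- sample(c("+", "-"), 1)
        proms[[k]] <- promoter_from_tss(ch, tss, strand, spec,
                                        id = sprintf("prom_%d", k),
                                        gene_id = sprintf("gene_%d", k),
                                        chrom_length = chroms[[ch]])
      }
    }
    promoters <- do.call(rbind, proms)
    fams <- sample(names(config$te_family_proportions), config$n_tes,
                   replace = TRUE, prob = config$te_family_proportions)
    # uniform placement, rejection-sampled so regions never overlap
    # (TE copies and promoters are disjoint annotations in practice);
    # a 500 bp margin keeps one region's fragment pileup from spilling
    # into a neighbor's occupancy call
    margin <- 500L
    taken <- lapply(stats::setNames(nm = names(chroms)), function(ch) {
      m <- do.call(rbind, lapply(proms, function(pp)
        if (pp$chrom == ch) c(pp$start, pp$end) else NULL))
      if (is.null(m)) matrix(numeric(), ncol = 2) else m
    })
    te_chrom <- sample(names(chroms), config$n_tes, replace = TRUE)
    te_len <- round(runif(config$n_tes, config$te_length_range[1],
                          config$te_length_range[2]))
    te_start <- integer(config$n_tes)
    for (i in seq_len(config$n_tes)) {
      placed <- FALSE
      for (try in 1:200) {
        s <- round(runif(1, margin, chroms[[te_chrom[i]]] - te_len[i] - margin))
        occ <- taken[[te_chrom[i]]]
        if (!nrow(occ) ||
            all(s - margin >= occ[, 2] | s + te_len[i] + margin <= occ[, 1])) {
          taken[[te_chrom[i]]] <- rbind(occ, c(s, s + te_len[i]))
          te_start[i] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place TE ", i,
             " without overlap; reduce n_tes or enlarge chromosomes")
    }
    tes <- data.frame(id = sprintf("te_%d", seq_len(config$n_tes)),
                      chrom = te_chrom, start = as.integer(te_start),
                      end = as.integer(te_start + te_len), strand = ".",
                      kind = "te", te_family = fams,
                      te_class = ifelse(fams %in% config$young_families,
                                        "young", "old"),
                      stringsAsFactors = FALSE)
    genome_annotation(chroms, promoters, tes)
  })
}

#' Draw ground-truth state vectors
#'
#' Samples a (state in A, state in B) pair per region from the joint
#' state distribution. TEs of evolutionarily young families draw from
#' the table reweighted toward H3K9me3-containing states.
#'
#' @param config a [synthetic_config()].
#' @param annotation a [simulate_annotation()] result.
#' @return List: `states` (`data.frame` region_id, kind, stateA,
#'   stateB), plus occupancy matrices `occA`, `occB` over all regions.
#' @export
simulate_truth <- function(config, annotation) {
  dist <- config$state_distribution
  regions <- rbind(annotation$promoters[c("id", "kind")],
                   annotation$tes[c("id", "kind")])
  young <- c(rep(FALSE, nrow(annotation$promoters)),
             annotation$tes$te_family %in% config$young_families)
  w_young <- dist$prob *
    ifelse(grepl("H3K9me3", dist$stateB), config$young_k9_bias, 1)
  with_seed(derive_seed(config$seed, "states"), {
    idx <- integer(nrow(regions))
    idx[!young] <- sample.int(nrow(dist), sum(!young), replace = TRUE,
                              prob = dist$prob)
    if (any(young))
      idx[young] <- sample.int(nrow(dist), sum(young), replace = TRUE,
                               prob = w_young)
    states <- data.frame(region_id = regions$id, kind = regions$kind,
                         stateA = dist$stateA[idx], stateB = dist$stateB[idx],
                         stringsAsFactors = FALSE)
    list(states = states,
         occA = state_to_occ(stats::setNames(states$stateA, states$region_id)),
         occB = state_to_occ(stats::setNames(states$stateB, states$region_id)),
         multipliers = config$global_multiplier)
  })
}

#' Simulate spike-in ChIP count data
#'
#' For every histone/ATAC mark, cell type and replicate: per-region IP
#' counts are negative binomial with mean `nb_mean_occupied` (occupied)
#' or `nb_mean_unoccupied` reads per kb of region, scaled by region
#' length; matched inputs are NB at a flat `nb_input_mean` per region,
#' so the ratio-over-length normalization yields a length-free
#' abundance measure. The spike read total is Poisson with mean
#' `depth * spike_cell_fraction / multiplier(mark, cell)`, so a global
#' loss of a mark (more target chromatin competed away) raises the
#' spike share exactly as in the wet protocol, and the true multipliers
#' are recoverable by [spike_factors()] + [normalize_signal()].
#' Fragment lists (one 150 bp fragment per counted read, placed
#' uniformly within its region, plus a uniform intergenic background at
#' the unoccupied per-kb rate) are emitted for the peak-calling stage.
#'
#' @param config a [synthetic_config()].
#' @param truth a [simulate_truth()] result.
#' @param annotation a [simulate_annotation()] result.
#' @param marks marks to simulate (default: all panel marks except 5mC).
#' @param fragments also emit per-sample fragment tables (default TRUE).
#' @return List: `ip_counts`, `input_counts` (region x sample),
#'   `samples` (sheet), `fragments` (named list of data.frames).
#' @export
simulate_chip <- function(config, truth, annotation,
                          marks = setdiff(mark_panel(), "5mC"),
                          fragments = TRUE) {
  regions <- rbind(annotation$promoters[c("id", "chrom", "start", "end")],
                   annotation$tes[c("id", "chrom", "start", "end")])
  n <- nrow(regions)
  kb <- (regions$end - regions$start) / 1000
  cells <- config$cell_types
  chroms <- annotation$chromosomes
  with_seed(derive_seed(config$seed, "chip"), {
    ip <- list(); input <- list(); sheets <- list(); frags <- list()
    for (mk in marks) {
      occ <- cbind(truth$occA[regions$id, mk], truth$occB[regions$id, mk])
      for (ci in seq_along(cells)) {
        mult <- config$global_multiplier[[mk]][[cells[ci]]]
        mu <- ifelse(occ[, ci], config$nb_mean_occupied,
                     config$nb_mean_unoccupied) * kb
        for (rep_i in seq_len(config$n_replicates)) {
          sid <- sprintf("%s.%s.ip%d", mk, cells[ci], rep_i)
          cnt <- rnbinom(n, size = config$nb_dispersion, mu = mu)
          ip[[sid]] <- cnt
          depth <- sum(cnt)
          spike <- rpois(1, max(1, depth * config$spike_cell_fraction / mult))
          sheets[[sid]] <- sample_sheet(sid, mk, cells[ci], role = "IP",
                                        replicate = rep_i,
                                        target_mapped_reads = depth,
                                        spike_mapped_reads = spike)
          if (fragments) {
            reps <- rep.int(seq_len(n), cnt)
            pos <- regions$start[reps] +
              floor(runif(length(reps)) *
                      pmax(1, regions$end[reps] - regions$start[reps] - 150))
            reg_fr <- data.frame(chrom = regions$chrom[reps],
                                 start = as.integer(pos),
                                 end = as.integer(pos + 150L),
                                 stringsAsFactors = FALSE)
            bg_fr <- do.call(rbind, lapply(names(chroms), function(ch) {
              nb <- rpois(1, config$nb_mean_unoccupied * chroms[[ch]] / 1000)
              s <- floor(runif(nb, 0, chroms[[ch]] - 150))
              data.frame(chrom = ch, start = as.integer(s),
                         end = as.integer(s + 150L), stringsAsFactors = FALSE)
            }))
            frags[[sid]] <- rbind(reg_fr, bg_fr)
          }
        }
      }
    }
    for (ci in seq_along(cells)) {
      sid <- sprintf("input.%s", cells[ci])
      cnt <- rnbinom(n, size = config$nb_dispersion, mu = config$nb_input_mean)
      input[[sid]] <- cnt
      sheets[[sid]] <- sample_sheet(sid, "input", cells[ci], role = "input",
                                    target_mapped_reads = sum(cnt))
    }
    list(ip_counts = matrix(unlist(ip), nrow = n,
                            dimnames = list(regions$id, names(ip))),
         input_counts = matrix(unlist(input), nrow = n,
                               dimnames = list(regions$id, names(input))),
         samples = do.call(rbind, sheets),
         fragments = if (fragments) frags else NULL)
  })
}

#' Simulate bivariate-normal TE-gene delta pairs
#'
#' Linked-pair expression deltas with exact planted correlation
#' structure: `gene = rho * te + sqrt(1 - rho^2) * noise`, both
#' marginals sd `sd`.
#'
#' @param n number of pairs.
#' @param rho planted correlation.
#' @param seed RNG seed.
#' @param sd marginal standard deviation.
#' @return `data.frame` with `te_delta`, `gene_delta`.
#' @export
simulate_link_deltas <- function(n, rho = 0.5, seed = 1L, sd = 1.5) {
  with_seed(seed, {
    z1 <- rnorm(n); z2 <- rnorm(n)
    data.frame(te_delta = sd * z1,
               gene_delta = sd * (rho * z1 + sqrt(1 - rho^2) * z2))
  })
}

#' Simulate state-coupled expression with planted DE
#'
#' Base expression per region follows the chromatin-state category in
#' each cell type (active states near the "expressed" mode, repressive
#' states near zero), giving the bimodal distribution the category
#' thresholds assume. A fraction `de_fraction` of TEs receives a
#' planted upward delta in cell B drawn from `de_delta_range` (>= 2.5
#' by default, comfortably past the 4-fold rule); all other TE deltas
#' are small null jitter truncated to [-1, 1]. Genes linked to a TE
#' (nearest-TSS within 100 kb) inherit a delta correlated with their
#' nearest linked TE at `rho`; unlinked genes get independent planted
#' or null deltas. Values are clamped at 0, the natural floor of the
#' `log2(RPKM+1)` scale.
#'
#' @param config a [synthetic_config()].
#' @param truth a [simulate_truth()] result.
#' @param annotation a [simulate_annotation()] result.
#' @param links optional precomputed [assign_nearest_promoter()] table.
#' @return List: `values` (region x cell-type matrix, `log2(RPKM+1)`),
#'   `true_de` (`data.frame` region_id, kind, delta, de), `links`.
#' @export
simulate_expression <- function(config, truth, annotation, links = NULL) {
  if (is.null(links))
    links <- assign_nearest_promoter(annotation$tes, annotation$promoters)
  st <- truth$states
  base_of <- function(state, kind) {
    cat <- assign_states(state_to_occ(stats::setNames(state, seq_along(state))))$category
    bases <- ifelse(kind == "te",
                    list(config$expr_base_te), list(config$expr_base_gene))
    vapply(seq_along(cat), function(i) {
      b <- bases[[i]]
      switch(cat[i], active = b[3], bivalent = b[2],
             neutral = b[2], repressive = b[1])
    }, 0)
  }
  with_seed(derive_seed(config$seed, "expression"), {
    is_te <- st$kind == "te"
    n <- nrow(st)
    delta <- rnorm(n, 0, config$null_delta_sd)
    delta <- pmax(pmin(delta, 1), -1)
    planted <- rep(FALSE, n)
    planted[is_te] <- runif(sum(is_te)) < config$de_fraction
    delta[planted] <- runif(sum(planted), config$de_delta_range[1],
                            config$de_delta_range[2])
    # genes inherit a rho-correlated delta from their nearest linked TE
    sd_t <- sd(delta[is_te])
    gene_ids <- annotation$promoters$gene_id
    driver <- links$te_id[match(gene_ids, links$gene_id)]
    gi <- match(st$region_id, annotation$promoters$id)
    for (i in which(!is.na(gi))) {
      drv <- driver[gi[i]]
      if (!is.na(drv)) {
        dt <- delta[match(drv, st$region_id)]
        delta[i] <- config$rho * dt +
          sqrt(1 - config$rho^2) * sd_t * rnorm(1)
      }
    }
    baseA <- base_of(st$stateA, st$kind)
    baseB <- base_of(st$stateB, st$kind)
    valA <- pmax(0, baseA + rnorm(n, 0, config$expr_noise_sd))
    valB <- pmax(0, baseB + delta + rnorm(n, 0, config$expr_noise_sd))
    values <- cbind(valA, valB)
    dimnames(values) <- list(st$region_id, config$cell_types)
    list(values = values,
         true_de = data.frame(region_id = st$region_id, kind = st$kind,
                              delta = delta, de = planted,
                              stringsAsFactors = FALSE),
         links = links)
  })
}

#' Simulate per-CpG bisulfite methylation tables
#'
#' CpGs are placed uniformly within each region; coverage is Poisson
#' and methylated reads binomial around a per-CpG beta-distributed
#' methylation level centered on the region's true mean
#' (`meth_occupied_mean` when the region carries 5mC in that cell type,
#' `meth_unoccupied_mean` otherwise).
#'
#' @param config a [synthetic_config()].
#' @param truth a [simulate_truth()] result.
#' @param annotation a [simulate_annotation()] result.
#' @return Named list (one per cell type) of CpG `data.frame`s with
#'   `chrom`, `pos`, `meth_reads`, `total_reads`, `region_id`, plus
#'   `true_means` per cell type.
#' @export
simulate_methylation <- function(config, truth, annotation) {
  regions <- rbind(annotation$promoters[c("id", "chrom", "start", "end")],
                   annotation$tes[c("id", "chrom", "start", "end")])
  occ5 <- cbind(truth$occA[regions$id, "5mC"], truth$occB[regions$id, "5mC"])
  with_seed(derive_seed(config$seed, "methylation"), {
    out <- list(); tm <- list()
    for (ci in seq_along(config$cell_types)) {
      mu <- ifelse(occ5[, ci], config$meth_occupied_mean,
                   config$meth_unoccupied_mean)
      ncpg <- 1L + rpois(nrow(regions), config$cpgs_per_region_mean - 1)
      reps <- rep.int(seq_len(nrow(regions)), ncpg)
      pos <- regions$start[reps] +
        floor(runif(length(reps)) * (regions$end[reps] - regions$start[reps]))
      k <- config$beta_concentration
      p <- rbeta(length(reps), mu[reps] * k, (1 - mu[reps]) * k)
      cov <- rpois(length(reps), config$coverage_mean)
      meth <- rbinom(length(reps), cov, p)
      out[[config$cell_types[ci]]] <-
        data.frame(chrom = regions$chrom[reps], pos = as.integer(pos),
                   meth_reads = meth, total_reads = cov,
                   region_id = regions$id[reps], stringsAsFactors = FALSE)
      tm[[config$cell_types[ci]]] <- stats::setNames(mu, regions$id)
    }
    c(out, list(true_means = tm))
  })
}

#' Run the whole generator and optionally write its outputs
#'
#' Produces the annotation, truth, ChIP counts and fragments,
#' expression and methylation for one synthetic world, and (when
#' `out_dir` is given) writes everything as plain-text files: BED and
#' region tables, TSV count/expression matrices, a TSV sample sheet,
#' fragment TSVs, CpG tables, and `truth.json`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory.
#' @return List with `annotation`, `truth`, `chip`, `expression`,
#'   `methylation`, `config`.
#' @export
simulate_all <- function(config = synthetic_config(), out_dir = NULL) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(config, annotation)
  chip <- simulate_chip(config, truth, annotation)
  expression <- simulate_expression(config, truth, annotation)
  methylation <- simulate_methylation(config, truth, annotation)
  res <- list(annotation = annotation, truth = truth, chip = chip,
              expression = expression, methylation = methylation,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_regions(annotation$promoters, file.path(out_dir, "promoters.tsv"),
                  "region-table")
    write_regions(annotation$tes, file.path(out_dir, "tes.tsv"),
                  "region-table")
    write_regions(rbind(annotation$promoters[1:6], annotation$tes[1:6]),
                  file.path(out_dir, "regions.bed"), "bed")
    wm <- function(m, f) write.table(data.frame(id = rownames(m), m,
                                                check.names = FALSE),
                                     file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wm(chip$ip_counts, "ip_counts.tsv")
    wm(chip$input_counts, "input_counts.tsv")
    write.table(chip$samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wm(expression$values, "expression.tsv")
    for (ct in config$cell_types)
      write.table(methylation[[ct]],
                  file.path(out_dir, sprintf("cpg_%s.tsv", ct)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(states = truth$states, multipliers = truth$multipliers,
           true_de = expression$true_de[expression$true_de$de, ],
           links = expression$links,
           seed = config$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
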
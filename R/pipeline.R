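#' Pipeline configuration
#'
#' A single configuration object drives all stages. The default runs
#' the pipeline end-to-end on a synthetic world; real data enter by
#' replacing stage inputs with files read through the IO layer.
#' Configurations can be loaded from JSON with [read_pipeline_config()].
#'
#' @param out_dir output directory (created on demand).
#' @param seed master seed; forwarded to the generator and the SOM.
#' @param synth a [synthetic_config()].
#' @param epsilon pseudocount for [normalize_signal()].
#' @param meth_threshold 5mC occupancy cutoff for
#'   [call_meth_occupancy()].
#' @param window_size,step,merge_gap peak-calling window geometry.
#' @param peak_p relaxed window p threshold before retention.
#' @param bin_width distance bin width for the TE-gene profile.
#' @param som a [som_config()].
#' @param log_level `"info"` or `"quiet"`.
#' @return List with class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = file.path(tempdir(), "epistate_run"),
                            seed = 1L,
                            synth = synthetic_config(seed = seed),
                            epsilon = 0.5, meth_threshold = 0.5,
                            window_size = 50L, step = 25L,
                            merge_gap = 100L, peak_p = 0.05,
                            bin_width = 10000L,
                            som = som_config(seed = seed, rlen = 2000L),
                            log_level = "info") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Unknown keys are rejected with the offending name, so typos fail
#' loudly rather than silently using a default.
#'
#' @param path JSON file with top-level keys matching
#'   [pipeline_config()] arguments (`synth` and `som` as nested
#'   objects).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$synth)) {
    bad <- setdiff(names(raw$synth), names(formals(synthetic_config)))
    if (length(bad)) stop("unknown synth key(s): ", paste(bad, collapse = ", "))
    raw$synth <- do.call(synthetic_config, raw$synth)
  }
  if (!is.null(raw$som)) {
    bad <- setdiff(names(raw$som), names(formals(som_config)))
    if (length(bad)) stop("unknown som key(s): ", paste(bad, collapse = ", "))
    raw$som <- do.call(som_config, raw$som)
  }
  do.call(pipeline_config, raw)
}

p_log <- function(config, ...) {
  if (identical(config$log_level, "info"))
    message(sprintf("[epistate] %s", sprintf(...)))
}

hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

manifest_path <- function(config) file.path(config$out_dir, "manifest.json")

read_manifest <- function(config) {
  p <- manifest_path(config)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE) else list()
}

record_stage <- function(config, stage, files, input_hash) {
  man <- read_manifest(config)
  man[[stage]] <- list(
    stage = stage, input_hash = input_hash,
    seed = config$seed,
    version = as.character(utils::packageVersion("epistate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = lapply(files, function(f)
      list(path = sub(paste0(normalizePath(config$out_dir), .Platform$file.sep),
                      "", normalizePath(f), fixed = TRUE),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, manifest_path(config), auto_unbox = TRUE)
  invisible(man)
}

stage_up_to_date <- function(config, stage, input_hash) {
  man <- read_manifest(config)
  ent <- man[[stage]]
  if (is.null(ent) || !identical(ent$input_hash, input_hash)) return(FALSE)
  all(vapply(ent$files, function(f)
    file.exists(file.path(config$out_dir, f$path)), TRUE))
}

write_stage_tsv <- function(df, config, stage, name) {
  dir <- file.path(config$out_dir, stage)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, name)
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  path
}

STAGES <- c("simulate", "normalize", "peaks", "occupancy", "states",
            "transitions", "express", "link", "som", "stats")

#' Run one pipeline stage
#'
#' Stages run in dependency order inside a shared in-memory state;
#' outputs are written atomically under `out_dir/<stage>/` and recorded
#' in a JSON manifest with content hashes, parameters hash, seed and
#' package version. A stage whose inputs are unchanged is skipped
#' ("up to date") unless `force`.
#'
#' @param name one of `"simulate"`, `"normalize"`, `"peaks"`,
#'   `"occupancy"`, `"states"`, `"transitions"`, `"express"`, `"link"`,
#'   `"som"`, `"stats"`.
#' @param config a [pipeline_config()].
#' @param state environment carrying upstream results (as created by
#'   [run_all()]); a fresh one is made when omitted.
#' @param force rerun even when up to date.
#' @return The state environment, invisibly.
#' @export
run_stage <- function(name, config, state = new.env(parent = emptyenv()),
                      force = FALSE) {
  name <- match.arg(name, STAGES)
  deps <- switch(name,
    simulate = character(),
    normalize = "simulate", peaks = "simulate",
    occupancy = c("normalize", "peaks"),
    states = "occupancy", transitions = "states",
    express = "simulate", link = c("simulate", "express"),
    som = c("normalize", "express"), stats = c("states", "express"))
  for (d in deps)
    if (is.null(state[[d]]))
      stop(sprintf("stage '%s' requires stage '%s' to run first", name, d))
  input_hash <- hash_obj(list(config[setdiff(names(config), "out_dir")],
                              lapply(deps, function(d) state[[paste0(d, "_hash")]])))
  if (!force && stage_up_to_date(config, name, input_hash) &&
      !is.null(state[[name]])) {
    p_log(config, "stage %s: up to date", name)
    return(invisible(state))
  }
  p_log(config, "running stage %s", name)
  files <- switch(name,
    simulate = stage_simulate(config, state),
    normalize = stage_normalize(config, state),
    peaks = stage_peaks(config, state),
    occupancy = stage_occupancy(config, state),
    states = stage_states(config, state),
    transitions = stage_transitions(config, state),
    express = stage_express(config, state),
    link = stage_link(config, state),
    som = stage_som(config, state),
    stats = stage_stats(config, state))
  state[[paste0(name, "_hash")]] <- input_hash
  record_stage(config, name, files, input_hash)
  invisible(state)
}

stage_simulate <- function(config, state) {
  sim <- simulate_all(config$synth, out_dir = file.path(config$out_dir, "simulate"))
  state$simulate <- sim
  list.files(file.path(config$out_dir, "simulate"), full.names = TRUE)
}

stage_normalize <- function(config, state) {
  sim <- state$simulate
  samples <- sim$chip$samples
  regions <- rbind(sim$annotation$promoters[1:6], sim$annotation$tes[1:6])
  marks <- unique(samples$antibody[samples$role == "IP"])
  factors <- do.call(rbind, lapply(marks, spike_factors, samples = samples))
  signal <- normalize_signal(sim$chip$ip_counts, sim$chip$input_counts,
                             samples, factors, regions,
                             epsilon = config$epsilon)
  state$normalize <- list(signal = signal, factors = factors)
  c(write_stage_tsv(factors, config, "normalize", "spike_factors.tsv"),
    write_stage_tsv(data.frame(id = rownames(signal$values), signal$values,
                               check.names = FALSE),
                    config, "normalize", "normalized_counts.tsv"))
}

stage_peaks <- function(config, state) {
  sim <- state$simulate
  chroms <- sim$annotation$chromosomes
  frags <- sim$chip$fragments
  samples <- sim$chip$samples
  ip <- samples[samples$role == "IP", ]
  groups <- unique(ip[c("antibody", "cell_type")])
  retained <- list()
  for (g in seq_len(nrow(groups))) {
    mk <- groups$antibody[g]; ct <- groups$cell_type[g]
    sids <- ip$sample_id[ip$antibody == mk & ip$cell_type == ct]
    reps <- frags[sids]
    pooled <- do.call(rbind, reps)
    psr <- split_pseudoreplicates(pooled, derive_seed(config$seed,
                                                      paste0("psr.", mk, ".", ct)))
    call_one <- function(fr) {
      prof <- window_profile(fr, chroms, config$window_size, config$step)
      call_broad_peaks_minimal(prof, background_rate = max(mean(prof$count), 0.05),
                               p_threshold = config$peak_p,
                               merge_gap = config$merge_gap)
    }
    pk <- retain_reproducible(call_one(pooled),
                              call_one(reps[[1]]), call_one(reps[[2]]),
                              call_one(psr[[1]]), call_one(psr[[2]]))
    pk <- pk[pk$retained, , drop = FALSE]
    assay <- if (mk == "ATAC") "atac" else "histone"
    retained[[paste(mk, ct, sep = ".")]] <- filter_q(pk, assay)
  }
  state$peaks <- retained
  tab <- do.call(rbind, lapply(names(retained), function(k) {
    if (!nrow(retained[[k]])) return(NULL)
    cbind(group = k, retained[[k]])
  }))
  write_stage_tsv(tab %||% data.frame(), config, "peaks", "retained_peaks.tsv")
}

stage_occupancy <- function(config, state) {
  sim <- state$simulate
  signal <- state$normalize$signal
  cells <- config$synth$cell_types
  marks <- setdiff(mark_panel(), "5mC")
  occ <- list()
  meth_tabs <- list()
  for (ci in seq_along(cells)) {
    ct <- cells[ci]
    per_mark <- list()
    for (mk in marks) {
      nc <- signal_mean(signal, mk, ct)
      pk <- state$peaks[[paste(mk, ct, sep = ".")]]
      per_mark[[mk]] <- unlist(lapply(
        list(sim$annotation$promoters, sim$annotation$tes),
        function(rg) call_occupancy(nc, pk, rg)))
    }
    rm_tab <- region_methylation(sim$methylation[[ct]])
    ids <- names(per_mark[[1]])
    rm_tab <- rm_tab[match(ids, rm_tab$region_id), ]
    per_mark[["5mC"]] <- call_meth_occupancy(rm_tab, config$meth_threshold)
    meth_tabs[[ct]] <- rm_tab
    occ[[ct]] <- occupancy_matrix(per_mark[mark_panel()])
  }
  state$occupancy <- list(occ = occ, meth = meth_tabs)
  files <- character()
  for (ct in cells)
    files <- c(files, write_stage_tsv(
      data.frame(id = rownames(occ[[ct]]), occ[[ct]], check.names = FALSE),
      config, "occupancy", sprintf("occupancy_%s.tsv", ct)))
  files
}

stage_states <- function(config, state) {
  cells <- config$synth$cell_types
  st <- lapply(state$occupancy$occ, assign_states)
  state$states <- st
  vapply(cells, function(ct)
    write_stage_tsv(st[[ct]], config, "states", sprintf("states_%s.tsv", ct)),
    "")
}

stage_transitions <- function(config, state) {
  cells <- config$synth$cell_types
  tt <- transitions(state$states[[cells[1]]], state$states[[cells[2]]])
  state$transitions <- tt
  long <- as.data.frame(tt, stringsAsFactors = FALSE)
  write_stage_tsv(long, config, "transitions", "transitions.tsv")
}

stage_express <- function(config, state) {
  sim <- state$simulate
  vals <- sim$expression$values
  is_te <- sim$expression$true_de$kind == "te"
  thr_te <- category_thresholds("te"); thr_gene <- category_thresholds("gene")
  cat_tab <- data.frame(
    id = rownames(vals),
    kind = ifelse(is_te, "te", "gene"),
    vals, check.names = FALSE,
    category_A = as.character(ifelse(is_te,
      as.character(categorize_expression(vals[, 1], thr_te)),
      as.character(categorize_expression(vals[, 1], thr_gene)))),
    category_B = as.character(ifelse(is_te,
      as.character(categorize_expression(vals[, 2], thr_te)),
      as.character(categorize_expression(vals[, 2], thr_gene)))),
    stringsAsFactors = FALSE)
  de <- call_de(vals[, 1], vals[, 2], id = rownames(vals))
  state$express <- list(categories = cat_tab, de = de)
  c(write_stage_tsv(cat_tab, config, "express", "categories.tsv"),
    write_stage_tsv(de, config, "express", "de_calls.tsv"))
}

stage_link <- function(config, state) {
  sim <- state$simulate
  links <- sim$expression$links
  de <- state$express$de
  delta <- stats::setNames(de$delta, de$id)
  prom <- sim$annotation$promoters
  gene_delta <- stats::setNames(delta[prom$id], prom$gene_id)
  prof <- distance_binned_correlation(links, delta, gene_delta,
                                      bin_width = config$bin_width)
  overall <- link_correlation(links, delta, gene_delta)
  state$link <- list(links = links, profile = prof, overall = overall)
  c(write_stage_tsv(links, config, "link", "links.tsv"),
    write_stage_tsv(prof, config, "link", "distance_correlation.tsv"))
}

stage_som <- function(config, state) {
  sim <- state$simulate
  signal <- state$normalize$signal
  cells <- config$synth$cell_types
  marks <- setdiff(mark_panel(), c("5mC", "ATAC"))
  chip_cols <- do.call(cbind, lapply(cells, function(ct)
    do.call(cbind, lapply(marks, function(mk) {
      v <- signal_mean(signal, mk, ct)
      matrix(v, ncol = 1, dimnames = list(names(v), paste(mk, ct, sep = ".")))
    }))))
  atac <- signal_mean(signal, "ATAC", cells[2])
  expr <- sim$expression$values
  meth <- state$occupancy$meth[[cells[2]]]
  fm <- prepare_features(list(chip = chip_cols,
                              atac = matrix(atac, ncol = 1,
                                            dimnames = list(names(atac), "ATAC")),
                              rna = expr),
                         meth = meth)
  fit <- train_som(fm, config$som)
  state$som <- fit
  assign_df <- data.frame(id = names(fit$assignment), node = fit$assignment)
  c(write_stage_tsv(fit$codebook, config, "som", "codebook.tsv"),
    write_stage_tsv(assign_df, config, "som", "assignment.tsv"),
    write_stage_tsv(fit$qe, config, "som", "quantization_error.tsv"))
}

stage_stats <- function(config, state) {
  sim <- state$simulate
  cells <- config$synth$cell_types
  vals <- sim$expression$values
  is_te <- sim$expression$true_de$kind == "te"
  wx <- wilcoxon_effect_size(vals[is_te, 2], vals[is_te, 1])
  catA <- table(state$states[[cells[1]]]$category)
  catB <- table(factor(state$states[[cells[2]]]$category,
                       levels = names(catA)))
  gof <- chisq_gof_effect_size(as.numeric(catB),
                               pmax(as.numeric(catA), 0.5) *
                                 sum(catB) / sum(pmax(as.numeric(catA), 0.5)))
  corr <- state$link$overall %||% list(r = NA, n = 0, level = NA)
  res <- data.frame(
    statistic = c("wilcoxon_r_te_expression", "cohen_w_state_shift",
                  "pearson_r_te_gene"),
    value = c(wx$value, gof$value, corr$r),
    n = c(wx$n, gof$n, corr$n),
    level = c(wx$level, gof$level, corr$level),
    stringsAsFactors = FALSE)
  state$stats <- res
  write_stage_tsv(res, config, "stats", "effect_sizes.tsv")
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order on one configuration and
#' writes a final report: occupancy counts per mark and cell type,
#' state-category partitions, the repressive-signature transition
#' table, DE summaries, SOM node occupancy and the headline effect
#' sizes. Deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param force rerun all stages.
#' @return The state environment (stage results as entries), invisibly;
#'   the report is at `out_dir/report.json`.
#' @export
run_all <- function(config = pipeline_config(), force = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  for (s in STAGES) run_stage(s, config, state, force = force)
  cells <- config$synth$cell_types
  report <- list(
    seed = config$seed,
    n_regions = nrow(state$states[[1]]),
    occupancy_counts = lapply(state$occupancy$occ, colSums),
    state_categories = lapply(state$states, function(s) table(s$category)),
    transition_total = sum(state$transitions),
    n_de = sum(state$express$de$de),
    som_nodes = nrow(state$som$codebook),
    som_final_qe = state$som$qe$qe[nrow(state$som$qe)],
    effect_sizes = state$stats)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  p_log(config, "pipeline complete: %s", config$out_dir)
  invisible(state)
}

#' Command-line entry point
#'
#' `epistate <stage|all> [--config cfg.json] [--out dir] [--seed N]
#' [--force]`. Exit codes: 0 ok, 1 user error, 2 internal error.
#'
#' @param args character vector of arguments (default: command line).
#' @return Exit status, invisibly.
#' @export
epistate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: epistate <stage|all> [--config cfg.json] [--out dir] [--seed N] [--force]")
    cmd <- args[1]; args <- args[-1]
    getopt <- function(flag) {
      i <- which(args == flag)
      if (length(i)) args[i + 1] else NULL
    }
    cfg <- if (!is.null(getopt("--config"))) read_pipeline_config(getopt("--config"))
           else pipeline_config()
    if (!is.null(getopt("--seed"))) {
      seed <- as.integer(getopt("--seed"))
      cfg$seed <- seed
      cfg$synth$seed <- seed
      cfg$som$seed <- seed
    }
    if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
    force <- "--force" %in% args
    if (cmd == "all") {
      run_all(cfg, force = force)
    } else {
      state <- new.env(parent = emptyenv())
      for (s in STAGES) {
        run_stage(s, cfg, state, force = force)
        if (s == cmd) break
      }
      if (!cmd %in% STAGES) stop("unknown stage: ", cmd)
    }
    0L
  }, error = function(e) {
    message("epistate error: ", conditionMessage(e))
    if (grepl("usage:|unknown", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
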
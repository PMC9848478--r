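test_that("annotation simulation is deterministic and respects config", {
  cfg <- synthetic_config(seed = 5, n_promoters = 30, n_tes = 60)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$promoters), 30)
  expect_equal(nrow(a1$tes), 60)
  expect_true(all(a1$promoters$end - a1$promoters$start == 2500))
  # promoters never overlap each other, TEs never overlap anything
  all_rg <- rbind(a1$promoters[1:6], a1$tes[1:6])
  for (ch in names(a1$chromosomes)) {
    sub <- all_rg[all_rg$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  cfg_sva <- synthetic_config(seed = 1, n_promoters = 10, n_tes = 20,
                              te_family_proportions = c(SVA = 1))
  expect_true(all(simulate_annotation(cfg_sva)$tes$te_family == "SVA"))
  expect_error(simulate_annotation(synthetic_config(n_promoters = 5000)),
               "infeasible")
})

test_that("truth states follow the configured joint distribution", {
  cfg <- synthetic_config(seed = 8, n_promoters = 200, n_tes = 400)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  expect_equal(nrow(tr$states), 600)
  pairs <- paste(tr$states$stateA, tr$states$stateB)
  legal <- paste(cfg$state_distribution$stateA, cfg$state_distribution$stateB)
  expect_true(all(pairs %in% legal))
  # young families are enriched for H3K9me3-bearing germline states
  te_states <- tr$states[tr$states$kind == "te", ]
  young <- ann$tes$te_family %in% cfg$young_families
  k9 <- grepl("H3K9me3", te_states$stateB)
  expect_gt(mean(k9[young]), mean(k9[!young]))
})

test_that("chip counts have the configured enrichment and NB dispersion", {
  cfg <- synthetic_config(seed = 3, n_promoters = 50, n_tes = 300,
                          te_length_range = c(1000L, 1000L),
                          nb_dispersion = 1e6)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  ch <- simulate_chip(cfg, tr, ann, marks = "H3K9me3", fragments = FALSE)
  te_ids <- ann$tes$id
  occ <- tr$occA[te_ids, "H3K9me3"]
  cnt <- ch$ip_counts[te_ids, "H3K9me3.GSC.ip1"]
  # occupied vs unoccupied means differ by the configured ratio (1 kb TEs)
  expect_equal(mean(cnt[occ]) / mean(cnt[!occ]),
               cfg$nb_mean_occupied / cfg$nb_mean_unoccupied,
               tolerance = 0.25)
  # dispersion -> infinity approaches the Poisson variance/mean = 1
  un <- cnt[!occ]
  expect_lt(abs(var(un) / mean(un) - 1), 0.4)
  cfg2 <- synthetic_config(seed = 3, n_promoters = 50, n_tes = 300,
                           te_length_range = c(1000L, 1000L),
                           nb_dispersion = 2)
  ch2 <- simulate_chip(cfg2, simulate_truth(cfg2, simulate_annotation(cfg2)),
                       simulate_annotation(cfg2), marks = "H3K9me3",
                       fragments = FALSE)
  un2 <- ch2$ip_counts[te_ids, "H3K9me3.GSC.ip1"][!occ]
  expect_gt(var(un2) / mean(un2), 1.5)
})

test_that("fragment emission matches counts and adds uniform background", {
  cfg <- synthetic_config(seed = 4, n_promoters = 20, n_tes = 40)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  ch <- simulate_chip(cfg, tr, ann, marks = "H3K4me3")
  fr <- ch$fragments[["H3K4me3.GSC.ip1"]]
  expect_gte(nrow(fr), sum(ch$ip_counts[, "H3K4me3.GSC.ip1"]))
  expect_true(all(fr$end - fr$start == 150))
})

test_that("methylation tables concentrate around the true region means", {
  cfg <- synthetic_config(seed = 6, n_promoters = 40, n_tes = 80,
                          cpgs_per_region_mean = 100, coverage_mean = 50,
                          meth_occupied_mean = 0.9)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  me <- simulate_methylation(cfg, tr, ann)
  rm_tab <- region_methylation(me$GSC)
  truem <- me$true_means$GSC[rm_tab$region_id]
  expect_true(all(rm_tab$defined))
  expect_lt(max(abs(rm_tab$mean_meth - truem)), 0.05)
  # coverage capped below the filter -> everything undefined
  cfg_low <- synthetic_config(seed = 6, n_promoters = 10, n_tes = 10,
                              coverage_mean = 0.5)
  ann_l <- simulate_annotation(cfg_low)
  me_l <- simulate_methylation(cfg_low, simulate_truth(cfg_low, ann_l), ann_l)
  me_l$GSC$total_reads <- pmin(me_l$GSC$total_reads, 4L)
  expect_false(any(region_methylation(me_l$GSC)$defined))
})

test_that("generator outputs round-trip through the IO layer", {
  cfg <- synthetic_config(seed = 2, n_promoters = 15, n_tes = 30)
  out <- withr::local_tempdir()
  sim <- simulate_all(cfg, out_dir = out)
  back <- read_regions(file.path(out, "tes.tsv"), "region-table")
  expect_equal(back$start, sim$annotation$tes$start)
  expect_equal(back$end, sim$annotation$tes$end)
  expect_equal(back$te_family, sim$annotation$tes$te_family)
  bed <- read_regions(file.path(out, "regions.bed"), "bed")
  expect_equal(nrow(bed), 45)
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 2)
  expect_equal(nrow(truth$states), 45)
  # per-stream seeding: same master seed reproduces every output
  sim2 <- simulate_all(cfg)
  expect_identical(sim$chip$ip_counts, sim2$chip$ip_counts)
  expect_identical(sim$expression$values, sim2$expression$values)
})
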
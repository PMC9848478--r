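prom_fix <- function(tss, strand = "+", chrom = "chr1") {
  do.call(rbind, lapply(seq_along(tss), function(i)
    promoter_from_tss(chrom[min(i, length(chrom))], tss[i],
                      strand[min(i, length(strand))],
                      id = sprintf("p%d", i), gene_id = sprintf("g%d", i))))
}

test_that("nearest-promoter assignment honors distance, sign and ties", {
  prom <- prom_fix(c(100000, 210000), c("+", "+"))
  tes <- regions(c("near", "far", "mid"), "chr1",
                 c(49500, 430000, 149500), c(50500, 431000, 150500))
  links <- assign_nearest_promoter(tes, prom)
  # "near": mid 50000, 50 kb from g1, 160 kb from g2 -> g1
  expect_equal(links$gene_id[links$te_id == "near"], "g1")
  expect_equal(links$distance[links$te_id == "near"], -50000)  # upstream of +
  # "far": beyond 100 kb from both -> unlinked
  expect_false("far" %in% links$te_id)
  # "mid": mid 150000, 50 kb from g1 and 60 kb from g2 -> nearest wins
  expect_equal(links$gene_id[links$te_id == "mid"], "g1")
  expect_true(all(abs(links$distance) < 100000))

  # equidistant tie breaks to the lexicographically smallest gene id
  prom2 <- prom_fix(c(100000, 200000))
  tie <- regions("t", "chr1", 149500, 150500)
  expect_equal(assign_nearest_promoter(tie, prom2)$gene_id, "g1")

  # strand awareness: downstream of a minus-strand gene is negative side
  promm <- prom_fix(50000, "-")
  te_right <- regions("t", "chr1", 59500, 60500)  # mid 60000, 3' of TSS... 5'?
  lk <- assign_nearest_promoter(te_right, promm)
  expect_equal(lk$distance, -10000)  # minus strand: upstream = higher coord
})

test_that("nearest assignment matches the all-pairs brute-force oracle", {
  set.seed(23)
  for (rep in 1:3) {
    ntss <- 60
    prom <- prom_fix(sort(round(runif(ntss, 5000, 5e5))),
                     sample(c("+", "-"), ntss, TRUE),
                     chrom = sample(c("chr1", "chr2"), ntss, TRUE))
    tes <- rand_intervals(200, max_pos = 5e5, prefix = "t")
    got <- assign_nearest_promoter(tes, prom)
    exp <- oracle_nearest(tes, prom)
    expect_equal(got$te_id, exp$te_id)
    expect_equal(got$gene_id, exp$gene_id)
    expect_equal(got$distance, exp$distance)
    expect_true(all(abs(got$distance) < 100000))
  }
})

test_that("link correlations recover planted structure", {
  links <- data.frame(te_id = sprintf("t%d", 1:1000),
                      gene_id = sprintf("g%d", 1:1000),
                      distance = round(seq(-9e4, 9e4, length.out = 1000)))
  # perfect coupling
  d <- simulate_link_deltas(1000, rho = 1, seed = 4)
  td <- stats::setNames(d$te_delta, links$te_id)
  gd <- stats::setNames(d$gene_delta, links$gene_id)
  expect_equal(link_correlation(links, td, gd)$r, 1)
  # independence: |r| small at n = 1000
  d0 <- simulate_link_deltas(1000, rho = 0, seed = 5)
  r0 <- link_correlation(links,
                         stats::setNames(d0$te_delta, links$te_id),
                         stats::setNames(d0$gene_delta, links$gene_id))
  expect_lt(abs(r0$r), 0.1)
  # planted rho = 0.5, n = 2000: within +-0.06 (Fisher-z scale)
  links2k <- data.frame(te_id = sprintf("t%d", 1:2000),
                        gene_id = sprintf("g%d", 1:2000), distance = 0L)
  d5 <- simulate_link_deltas(2000, rho = 0.5, seed = 6)
  r5 <- link_correlation(links2k,
                         stats::setNames(d5$te_delta, links2k$te_id),
                         stats::setNames(d5$gene_delta, links2k$gene_id))
  expect_lt(abs(r5$r - 0.5), 0.06)
  # < 3 pairs -> undefined, flagged
  expect_false(link_correlation(links[1:2, ], td, gd)$defined)
})

test_that("distance-binned profiles localize and flag sparse bins", {
  links <- data.frame(te_id = sprintf("t%d", 1:30),
                      gene_id = sprintf("g%d", 1:30),
                      distance = rep(10500L, 30))
  d <- simulate_link_deltas(30, rho = 1, seed = 2)
  td <- stats::setNames(d$te_delta, links$te_id)
  gd <- stats::setNames(d$gene_delta, links$gene_id)
  prof <- distance_binned_correlation(links, td, gd)
  expect_equal(nrow(prof), 20)
  filled <- prof[!is.na(prof$r), ]
  expect_equal(nrow(filled), 1)
  expect_equal(filled$bin_start, 10000)
  expect_equal(filled$r, 1)
  empty <- distance_binned_correlation(links[0, ], td, gd)
  expect_true(all(is.na(empty$r)))
  expect_error(distance_binned_correlation(links, td, gd, bin_width = 30001),
               "divide")
})

test_that("regulatory TE calls require upstream position plus active chromatin", {
  links <- data.frame(te_id = c("t1", "t2", "t3", "t4"),
                      gene_id = c("g1", "g2", "g3", "g4"),
                      distance = c(-5000L, 5000L, -5000L, -5000L))
  de_up <- c(t1 = TRUE, t2 = TRUE, t3 = TRUE, t4 = FALSE)
  active <- c(t1 = TRUE, t2 = TRUE, t3 = FALSE, t4 = TRUE)
  atac <- c(t1 = FALSE, t2 = FALSE, t3 = FALSE, t4 = FALSE)
  out <- classify_regulatory_te(links, de_up, active, atac)
  expect_equal(out$te_id, c("t1", "t2", "t3"))    # t4 not DE-up
  expect_equal(out$putative_regulatory, c(TRUE, FALSE, FALSE))
  # ATAC alone can substitute for the active mark
  atac2 <- c(t1 = FALSE, t2 = FALSE, t3 = TRUE, t4 = FALSE)
  out2 <- classify_regulatory_te(links, de_up, active, atac2)
  expect_true(out2$putative_regulatory[out2$te_id == "t3"])
})

test_that("correlation estimates fall inside Fisher-z intervals", {
  links <- data.frame(te_id = sprintf("t%d", 1:2000),
                      gene_id = sprintf("g%d", 1:2000), distance = 0L)
  inside <- vapply(1:40, function(s) {
    d <- simulate_link_deltas(2000, rho = 0.5, seed = s)
    r <- link_correlation(links, stats::setNames(d$te_delta, links$te_id),
                          stats::setNames(d$gene_delta, links$gene_id))$r
    abs(atanh(r) - atanh(0.5)) < stats::qnorm(0.995) / sqrt(2000 - 3)
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})
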
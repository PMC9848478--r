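test_that("occupancy is the conjunction of peak overlap and signal excess", {
  rg <- regions(c("a", "b", "c"), "chr1", c(0, 2000, 4000),
                c(1000, 3000, 5000))
  neg <- regions(c("n1", "n2"), "chr1", c(10000, 12000), c(11000, 13000))
  nc <- c(a = 5, b = 1, c = 10, n1 = 1.5, n2 = 2.5)   # negative mean 2.0
  pk <- data.frame(chrom = "chr1", start = c(100, 2100), end = c(300, 2300))
  occ <- call_occupancy(nc, pk, rg, neg)
  expect_equal(unname(occ), c(TRUE, FALSE, FALSE))  # b fails NC, c has no peak
  expect_error(call_occupancy(nc, pk, rg, neg[0, ]), "empty")
  # default negative set = peak-free regions of the same table (only c
  # here, so the threshold is nc[c])
  nc2 <- c(a = 5, b = 1, c = 2)
  occ2 <- call_occupancy(nc2, pk, rg)
  expect_equal(unname(occ2), c(TRUE, FALSE, FALSE))
})

test_that("occupancy matches the brute-force oracle on random fixtures", {
  set.seed(7)
  for (rep in 1:3) {
    rg <- rand_intervals(500, max_pos = 2e5, prefix = "q")
    neg <- rand_intervals(100, max_pos = 2e5, prefix = "neg")
    nc <- stats::setNames(rexp(600, 1), c(rg$id, neg$id))
    pk <- rand_intervals(80, max_pos = 2e5, prefix = "pk")
    got <- call_occupancy(nc, pk, rg, neg)
    expect_equal(unname(got), oracle_occupancy(nc, pk, rg, neg))
  }
})

test_that("5mC occupancy uses the methylation threshold with boundaries", {
  rm_tab <- data.frame(region_id = c("a", "b", "c"),
                       mean_meth = c(0.8, 0.5, NA),
                       n_cpgs_used = c(3L, 2L, 0L),
                       defined = c(TRUE, TRUE, FALSE))
  occ <- call_meth_occupancy(rm_tab, 0.5)
  expect_equal(as.logical(occ), c(TRUE, TRUE, FALSE))  # boundary occupied
  expect_equal(attr(occ, "undefined"), "c")
  expect_error(call_meth_occupancy(rm_tab, 1.2), "in \\(0,1\\)")
})

test_that("state assignment reports exact signatures and categories", {
  occ <- occupancy_matrix(list(
    `5mC` = c(r1 = TRUE, r2 = FALSE, r3 = FALSE, r4 = FALSE, r5 = FALSE),
    H3K9me3 = c(r1 = TRUE, r2 = FALSE, r3 = FALSE, r4 = FALSE, r5 = FALSE),
    H3K27me3 = c(r1 = FALSE, r2 = TRUE, r3 = FALSE, r4 = FALSE, r5 = FALSE),
    H2aK119ub = rep(FALSE, 5) |> stats::setNames(paste0("r", 1:5)),
    H3K4me3 = c(r1 = FALSE, r2 = TRUE, r3 = TRUE, r4 = FALSE, r5 = FALSE),
    H3K4me1 = c(r1 = FALSE, r2 = FALSE, r3 = FALSE, r4 = TRUE, r5 = FALSE),
    H3K27ac = rep(FALSE, 5) |> stats::setNames(paste0("r", 1:5)),
    ATAC = rep(FALSE, 5) |> stats::setNames(paste0("r", 1:5))))
  st <- assign_states(occ)
  expect_equal(st$signature,
               c("5mC+H3K9me3", "H3K27me3", "none", "none", "none"))
  expect_equal(st$category,
               c("repressive", "bivalent", "active", "neutral", "neutral"))
  expect_true(st$h3k4me1[4])  # H3K4me1-only region stays neutral, flagged
})

test_that("categories partition any random region set", {
  set.seed(21)
  for (rep in 1:5) {
    occ <- matrix(runif(100 * 8) < 0.3, 100, 8,
                  dimnames = list(sprintf("r%d", 1:100), mark_panel()))
    st <- assign_states(occ)
    expect_equal(sum(table(st$category)), 100)
    expect_false(any(is.na(st$category)))
    # bivalent iff both sides present
    has_rep <- rowSums(occ[, repressive_marks()]) > 0
    has_act <- rowSums(occ[, active_marks()]) > 0
    expect_equal(st$category == "bivalent", unname(has_rep & has_act))
  }
})

test_that("specificity labels partition region x mark", {
  set.seed(3)
  ids <- sprintf("r%d", 1:100)
  mk <- function() matrix(runif(100 * 3) < 0.5, 100, 3,
                          dimnames = list(ids, c("5mC", "H3K9me3", "H3K4me3")))
  a <- mk(); b <- mk()
  sp <- specificity(a, b, labels = c("fGSC", "fhPGC"))
  expect_equal(dim(sp), c(100, 3))
  for (m in colnames(sp)) {
    counts <- table(sp[, m])
    expect_equal(sum(counts), 100)
  }
  expect_true(all(sp[a & !b] == "fGSC-specific"))
  expect_true(all(sp[a & b] == "shared"))
  expect_error(specificity(a, b[, 1:2]), "share")
})

test_that("transition tables conserve regions and match dictionary counting", {
  mkstates <- function(sig) data.frame(id = sprintf("r%d", seq_along(sig)),
                                       signature = sig,
                                       stringsAsFactors = FALSE)
  a <- mkstates(rep("5mC", 10))
  b <- mkstates(rep("none", 10))
  tt <- transitions(a, b)
  expect_equal(as.numeric(tt["5mC", "none"]), 10)
  expect_equal(sum(tt), 10)

  set.seed(12)
  sigs <- c("5mC", "H3K9me3", "5mC+H3K9me3")
  a <- mkstates(sample(sigs, 200, TRUE))
  b <- mkstates(sample(sigs, 200, TRUE))
  tt <- transitions(a, b)
  expect_equal(sum(tt), 200)
  expect_equal(unname(rowSums(tt)),
               unname(as.vector(table(factor(a$signature, rownames(tt))))))
  oracle <- oracle_transitions(a$signature, b$signature)
  for (key in names(oracle)) {
    parts <- strsplit(key, "->", fixed = TRUE)[[1]]
    expect_equal(as.numeric(tt[parts[1], parts[2]]), unname(oracle[key]))
  }
  expect_error(transitions(a, b[1:100, ]), "identical region ids")
  # de novo: none in A, something in B
  dn <- de_novo_regions(a, b)
  expect_setequal(dn, a$id[a$signature == "none" & b$signature != "none"])
})

test_that("family enrichment matches the proportion formula", {
  bg <- data.frame(id = sprintf("t%d", 1:100),
                   te_family = rep(c("SVA", "L2"), c(10, 90)))
  sub <- bg[c(1:5, 11:15), ]  # 50% SVA vs 10% background
  fe <- family_enrichment(sub, bg)
  expect_equal(fe$enrichment[fe$family == "SVA"], 5)
  expect_equal(sum(fe$observed), nrow(sub))
  w <- attr(fe, "effect_size")
  # independent hand computation: E = (1, 9), O = (5, 5)
  chisq <- (5 - 1)^2 / 1 + (5 - 9)^2 / 9
  expect_equal(w$value, sqrt(chisq / 10))

  same <- family_enrichment(bg, bg)
  expect_true(all(same$enrichment == 1))
  expect_equal(attr(same, "effect_size")$value, 0)
  expect_error(family_enrichment(data.frame(id = "x", te_family = "SVA"), bg),
               "subset")
})

test_that("lower global abundance never increases the occupied count", {
  count_occ <- function(mult, seed = 31) {
    cfg <- synthetic_config(seed = seed, n_promoters = 40, n_tes = 80,
                            global_multiplier = list(
                              H3K4me3 = c(GSC = 1, PGC = mult)))
    ann <- simulate_annotation(cfg)
    tr <- simulate_truth(cfg, ann)
    ch <- simulate_chip(cfg, tr, ann, marks = "H3K4me3", fragments = FALSE)
    rg <- rbind(ann$promoters[1:6], ann$tes[1:6])
    fac <- spike_factors(ch$samples, "H3K4me3")
    sm <- normalize_signal(ch$ip_counts, ch$input_counts, ch$samples, fac, rg)
    nc <- signal_mean(sm, "H3K4me3", "PGC")
    # peaks stand-in: regions truly occupied in either cell carry a peak
    pk <- rg[tr$occA[rg$id, "H3K4me3"] | tr$occB[rg$id, "H3K4me3"], ]
    sum(call_occupancy(nc, pk, rg))
  }
  expect_lte(count_occ(0.3), count_occ(1))
})
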
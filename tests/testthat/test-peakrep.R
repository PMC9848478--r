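test_that("pseudoreplicate splits partition the fragments deterministically", {
  fr <- rand_intervals(10, prefix = "f")
  halves <- split_pseudoreplicates(fr, seed = 42)
  expect_equal(nrow(halves[[1]]), 5)
  expect_equal(nrow(halves[[2]]), 5)
  expect_setequal(c(halves[[1]]$id, halves[[2]]$id), fr$id)
  expect_length(intersect(halves[[1]]$id, halves[[2]]$id), 0)

  odd <- split_pseudoreplicates(rand_intervals(11), seed = 1)
  expect_equal(sort(vapply(odd, nrow, 0L)), c(5, 6))

  again <- split_pseudoreplicates(fr, seed = 42)
  expect_identical(halves, again)
  expect_false(identical(halves, split_pseudoreplicates(fr, seed = 43)))
  expect_error(split_pseudoreplicates(fr[1, ], 1), "at least 2")
})

test_that("the minimal caller finds Poisson-significant windows", {
  prof <- window_profile(data.frame(chrom = character(), start = integer(),
                                    end = integer()),
                         c(chr1 = 1000), 50, 25)
  prof$count <- rep(1L, nrow(prof))          # flat at background
  expect_equal(nrow(call_broad_peaks_minimal(prof, background_rate = 1)), 0)

  prof$count[10] <- 100L
  pk <- call_broad_peaks_minimal(prof, background_rate = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, prof$start[10])
  # oracle: direct Poisson tail evaluation
  expect_equal(pk$p, ppois(99, 1, lower.tail = FALSE))

  # merge rule: nearby significant windows become one peak
  prof2 <- prof; prof2$count[] <- 1L; prof2$count[c(10, 13)] <- 50L
  merged <- call_broad_peaks_minimal(prof2, 1, merge_gap = 25)
  expect_equal(nrow(merged), 1)                   # 25 bp gap, merged
  split2 <- call_broad_peaks_minimal(prof2, 1, merge_gap = 10)
  expect_equal(nrow(split2), 2)
  expect_error(call_broad_peaks_minimal(prof, 0), "background_rate")
})

test_that("retention implements the replicate-or-pseudoreplicate rescue", {
  pooled <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                       end = c(50, 150, 250, 350))
  hit <- function(at) data.frame(chrom = rep("chr1", length(at)),
                                 start = at, end = at + 10)
  out <- retain_reproducible(pooled,
                             rep1 = hit(c(10, 110)), rep2 = hit(c(20, 310)),
                             psr1 = hit(c(110, 210)), psr2 = hit(c(110, 230)))
  # peak1: rep1&rep2 -> retained; peak2: rep1&psr1&psr2 -> retained via psr
  # peak3: psr only both -> retained; peak4: rep2 only -> dropped
  expect_equal(out$retained, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$overlaps_rep1, c(TRUE, TRUE, FALSE, FALSE))
  # empty replicate lists: rescue can still occur via pseudoreplicates
  out2 <- retain_reproducible(pooled, hit(integer()), hit(integer()),
                              hit(c(10)), hit(c(15)))
  expect_equal(out2$retained, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("retention matches the brute-force oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:3) {
    pooled <- rand_intervals(400, max_pos = 5e4, max_len = 800)
    mk <- function() rand_intervals(150, max_pos = 5e4, max_len = 800)
    r1 <- mk(); r2 <- mk(); p1 <- mk(); p2 <- mk()
    got <- retain_reproducible(pooled, r1, r2, p1, p2)
    expect_equal(got$retained, oracle_retain(pooled, r1, r2, p1, p2))
  }
})

test_that("q filtering applies the assay-specific FDR cutoffs", {
  pk <- empty <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                            end = c(50, 150, 250),
                            q = c(5e-4, 5e-5, NA))
  expect_equal(suppressMessages(filter_q(pk, "histone"))$start, c(0, 100))
  expect_equal(suppressMessages(filter_q(pk, "atac"))$start, 100)
  expect_message(filter_q(pk, "histone"), "1 peak")
  expect_equal(nrow(filter_q(pk[0, ], "histone")), 0)
  # boundary: q exactly at the cutoff is dropped (strict <)
  at <- data.frame(chrom = "chr1", start = 0, end = 10, q = 1e-3)
  expect_equal(nrow(filter_q(at, "histone")), 0)
})

test_that("a strong synthetic peak survives the pseudoreplicate pipeline", {
  retained <- vapply(1:20, function(s) {
    set.seed(s)
    mkrep <- function(n_sig) {
      sig <- data.frame(chrom = "chr1",
                        start = as.integer(floor(runif(n_sig, 10000, 10800))),
                        end = 0L)
      sig$end <- sig$start + 150L
      bg <- data.frame(chrom = "chr1",
                       start = as.integer(floor(runif(60, 0, 99000))), end = 0L)
      bg$end <- bg$start + 150L
      rbind(sig, bg)
    }
    reps <- list(mkrep(120), mkrep(120))
    pooled <- rbind(reps[[1]], reps[[2]])
    psr <- split_pseudoreplicates(pooled, seed = s)
    call_one <- function(fr) {
      prof <- window_profile(fr, c(chr1 = 1e5), 50, 25)
      call_broad_peaks_minimal(prof, max(mean(prof$count), 0.05))
    }
    out <- retain_reproducible(call_one(pooled), call_one(reps[[1]]),
                               call_one(reps[[2]]), call_one(psr[[1]]),
                               call_one(psr[[2]]))
    any(out$retained & out$start < 11000 & out$end > 10000)
  }, TRUE)
  expect_true(all(retained))
})
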
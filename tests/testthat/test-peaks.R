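test_that("strand coverage matches the definition and conserves tags", {
  lib <- toy_library(fwd = c(500L), rev = integer(0))
  tr <- strand_coverage(lib, "chr", "+", 100L)
  expect_identical(coverage_at(tr, 500L), 1L)
  expect_identical(coverage_at(tr, 601L), 0L)
  expect_identical(coverage_at(tr, 400L), 1L)  # inclusive window edge

  expect_error(strand_coverage(lib, "chr", "+", 0L), "positive")
  expect_error(strand_coverage(lib, "nope", "+", 10L), "replicon")

  # conservation: per-position multiplicities sum to the strand tag count
  withr::with_seed(21, tags <- sort(sample.int(10000L, 400, replace = TRUE)))
  lib2 <- toy_library(fwd = tags, rev = integer(0))
  tr2 <- strand_coverage(lib2, "chr", "+", 50L)
  pos <- unique(tags)
  mult <- findInterval(pos, tags) - findInterval(pos - 1L, tags)
  expect_identical(sum(mult), length(tags))

  # brute-force recount oracle at 1,000 random positions
  withr::with_seed(22, x <- sample.int(10000L, 1000))
  expect_identical(as.numeric(coverage_at(tr2, x)), bf_coverage(tags, x, 50))
})

test_that("candidate peaks implement the continuity-corrected z rule", {
  # a = 100 at the peak; scaled input gives b = 10 -> z = 89 / sqrt(110)
  chip <- toy_library(fwd = rep(1000L, 100), rev = integer(0))
  input <- toy_library(fwd = c(rep(1000L, 10), rep(50000L, 90)),
                       rev = integer(0), sample = "input")
  pk <- candidate_peaks(strand_coverage(chip, "chr", "+", 100L),
                        strand_coverage(input, "chr", "+", 100L),
                        z_min = 4)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$location, 1000L)
  expect_equal(pk$a, 100)
  expect_equal(pk$b, 10)
  expect_equal(pk$z, 89 / sqrt(110))

  # no enrichment (a = b) is rejected: flat tags everywhere
  chip2 <- toy_library(fwd = seq(100L, 9900L, by = 100L), rev = integer(0))
  pk2 <- candidate_peaks(strand_coverage(chip2, "chr", "+", 100L),
                         strand_coverage(chip2, "chr", "+", 100L),
                         z_min = 4)
  expect_identical(nrow(pk2), 0L)

  expect_error(
    candidate_peaks(strand_coverage(chip, "chr", "+", 100L),
                    strand_coverage(toy_library(integer(0), integer(0),
                                                "input"),
                                    "chr", "+", 100L)),
    "zero tags")
})

test_that("uniform null libraries yield no candidates at z_min = 4", {
  runs <- withr::with_seed(404, {
    vapply(1:50, function(i) {
      L <- 100000L
      chip <- toy_library(fwd = sort(sample.int(L, rpois(1, 200),
                                                replace = TRUE)),
                          rev = integer(0))
      input <- toy_library(fwd = sort(sample.int(L, rpois(1, 1000),
                                                 replace = TRUE)),
                           rev = integer(0), sample = "input")
      nrow(candidate_peaks(strand_coverage(chip, "chr", "+", 100L),
                           strand_coverage(input, "chr", "+", 100L),
                           z_min = 4))
    }, integer(1))
  })
  expect_lte(mean(runs > 0), 0.01)
})

test_that("peak pairing is greedy, lag-bounded, and matches brute force", {
  fwd <- data.frame(strand = "+", location = 1000L, a = 50, b = 2, z = 6)
  rev <- data.frame(strand = "-", location = 1200L, a = 40, b = 2, z = 5)
  reg <- pair_peaks(fwd, rev)
  expect_identical(reg$start, 1000L)
  expect_identical(reg$end, 1200L)
  expect_identical(reg$location, 1100L)
  expect_equal(reg$a_pair, 90)

  # reverse upstream of forward only: no region
  expect_identical(nrow(pair_peaks(fwd, transform(rev, location = 900L))), 0L)
  expect_error(pair_peaks(fwd, rev, min_lag = 400L, max_lag = 300L),
               "min_lag")

  # randomized interleavings match an independent greedy implementation
  for (case in 1:20) {
    withr::with_seed(6000 + case, {
      nf <- sample(3:10, 1); nr <- sample(3:10, 1)
      f <- data.frame(strand = "+",
                      location = sort(sample.int(5000L, nf)),
                      a = rpois(nf, 50), b = 2, z = runif(nf, 4, 20))
      r <- data.frame(strand = "-",
                      location = sort(sample.int(5000L, nr)),
                      a = rpois(nr, 50), b = 2, z = runif(nr, 4, 20))
    })
    got <- pair_peaks(f, r, 50L, 400L)
    want <- bf_pair(f, r, 50L, 400L)
    expect_identical(got[c("start", "end")],
                     as.data.frame(lapply(want, as.integer)),
                     info = paste("case", case))
  }
})

test_that("paired region scoring works in log space at extreme z", {
  reg <- data.frame(replicon = "chr", start = 1000L, end = 1200L,
                    location = 1100L, midpoint = 1100L,
                    a_pair = 0, b_pair = 1)
  sc <- score_regions(reg)
  expect_lte(sc$z_pair, 0)
  expect_gte(sc$log10_p, log10(0.5))

  # frozen high-precision oracle values (200-digit erfc computation)
  oracle <- c(`5` = -6.54264567239065, `10` = -23.1180534054861,
              `50` = -544.966335861997, `200` = -8688.58976885156)
  got <- log10_normal_tail(c(5, 10, 50, 200))
  expect_equal(got, unname(oracle), tolerance = 1e-10)
  expect_equal(10^log10_normal_tail(10), 7.61985e-24, tolerance = 1e-5)

  # doubling both coverages with fixed background strictly increases z
  r1 <- score_regions(data.frame(a_pair = 60, b_pair = 5))
  r2 <- score_regions(data.frame(a_pair = 120, b_pair = 5))
  expect_gt(r2$z_pair, r1$z_pair)
  # minp is always at most p
  expect_lte(r1$log10_minp, r1$log10_p)

  expect_error(score_regions(data.frame(a_pair = 0, b_pair = 0)),
               "zero total")
})

test_that("call_binding_regions recovers planted sites end to end", {
  sim <- default_sim()
  reg <- call_binding_regions(sim$chip, sim$input)
  expect_gt(nrow(reg), 40)
  # sorted by NLQ descending, ids in genome order
  expect_true(all(diff(reg$nlq) <= 0))
  expect_identical(sort(reg$id), seq_len(nrow(reg)))
  expect_identical(reg$id[order(reg$start)], seq_len(nrow(reg)))
  # invariants: start <= location <= end, midpoint, finite non-negative NLQ
  expect_true(all(reg$start <= reg$location & reg$location <= reg$end))
  expect_identical(reg$midpoint, region_midpoint(reg$start, reg$end))
  expect_true(all(is.finite(reg$nlq) & reg$nlq >= 0))
  expect_true(all(reg$Q <= 0.05))
  # NLQ ranks exactly as ascending log10 p
  expect_true(all(diff(reg$log10_p[order(-reg$nlq)]) >= -1e-9) ||
              identical(order(reg$log10_p), order(-reg$nlq)))
  # strong planted sites are found close to their centers
  centers <- sim$truth$sites$start + 7
  strong <- sim$truth$sites$strength >= 50
  err <- vapply(centers[strong],
                function(c) min(abs(reg$location - c)), numeric(1))
  expect_gte(mean(err <= 25), 0.95)

  # empty ChIP library: no regions
  empty <- call_binding_regions(toy_library(integer(0), integer(0)),
                                sim$input)
  expect_identical(nrow(empty), 0L)
})

test_that("full pipeline equals staged brute-force recomputation on a toy replicon", {
  # 10-kb toy instance, recomputed stage by stage with the oracles
  withr::with_seed(77, {
    site_fwd <- as.integer(round(rnorm(80, 4900, 12)))
    site_rev <- as.integer(round(rnorm(80, 5100, 12)))
    bg_f <- sort(sample.int(10000L, 30, replace = TRUE))
    bg_r <- sort(sample.int(10000L, 30, replace = TRUE))
    in_f <- sort(sample.int(10000L, 150, replace = TRUE))
    in_r <- sort(sample.int(10000L, 150, replace = TRUE))
  })
  chip <- toy_library(fwd = sort(c(site_fwd, bg_f)),
                      rev = sort(c(site_rev, bg_r)))
  input <- toy_library(fwd = in_f, rev = in_r, sample = "input")
  params <- peak_params()
  reg <- call_binding_regions(chip, input, params)
  expect_identical(nrow(reg), 1L)
  # oracle recomputation of the paired statistic at the reported peaks
  a_f <- bf_coverage(chip$tags$chr$fwd, reg$start, 100)
  a_r <- bf_coverage(chip$tags$chr$rev, reg$end, 100)
  expect_equal(reg$a_pair, a_f + a_r)
  scale <- chip$library_size / input$library_size
  b_f <- max((bf_coverage(chip$tags$chr$fwd, reg$start - 200, 100) +
              bf_coverage(chip$tags$chr$fwd, reg$start + 200, 100)) / 2,
             bf_coverage(input$tags$chr$fwd, reg$start, 100) * scale)
  b_r <- max((bf_coverage(chip$tags$chr$rev, reg$end - 200, 100) +
              bf_coverage(chip$tags$chr$rev, reg$end + 200, 100)) / 2,
             bf_coverage(input$tags$chr$rev, reg$end, 100) * scale)
  expect_equal(reg$b_pair, b_f + b_r)
  z <- (reg$a_pair - reg$b_pair - 1) / sqrt(reg$a_pair + reg$b_pair)
  expect_equal(reg$z_pair, z)
  expect_equal(reg$log10_p, pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10))
  expect_identical(reg$location,
                   as.integer((reg$start + reg$end) %/% 2))
})
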
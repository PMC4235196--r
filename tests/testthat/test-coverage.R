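test_that("constant coverage yields no breakpoints", {
  tr <- coverage_track(rep(10, 2000))
  expect_equal(nrow(detect_breakpoints(tr)), 0L)
})

test_that("an ideal step yields one exact increase breakpoint with r = 1", {
  d <- c(rep(0, 4999), rep(100, 5001))
  bp <- detect_breakpoints(coverage_track(d))
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$position, 5000L)
  expect_equal(bp$kind, "increase")
  expect_equal(bp$r, 1)
  expect_equal(bp$p_value, 0)
  expect_equal(bp$fold_change, 101)

  # mirrored: a fall reports the last transcribed base
  d2 <- c(rep(100, 5000), rep(0, 5000))
  bp2 <- detect_breakpoints(coverage_track(d2))
  expect_equal(bp2$position, 5000L)
  expect_equal(bp2$kind, "decrease")
  expect_equal(bp2$r, -1)
})

test_that("a noisy Poisson step is found near the truth and matches the brute-force scan", {
  set.seed(42)
  d <- c(rpois(4999, 5), rpois(5001, 50))
  bp <- detect_breakpoints(coverage_track(d))
  inc <- bp[bp$kind == "increase", ]
  expect_equal(nrow(inc), 1L)
  expect_lt(abs(inc$position - 5000), 10)
  orc <- oracle_breakpoints(d)
  expect_equal(bp$position, orc$position)
  expect_equal(bp$r, orc$r, tolerance = 1e-9)
})

test_that("breakpoint detection is translation-equivariant", {
  set.seed(7)
  base <- c(rpois(800, 2), rpois(700, 60), rpois(1500, 2))
  for (s in c(100L, 333L)) {
    shifted <- c(base[(length(base) - s + 1):length(base)],
                 base[1:(length(base) - s)])
    bp0 <- detect_breakpoints(coverage_track(base))
    bps <- detect_breakpoints(coverage_track(shifted))
    away <- bp0$position > 150 & bp0$position < length(base) - s - 150
    expect_true(all((bp0$position[away] + s) %in% bps$position))
  }
})

test_that("stranded tracks are detected per strand", {
  dp <- c(rep(0, 999), rep(80, 1001))
  dm <- c(rep(50, 1200), rep(0, 800))
  tr <- coverage_track(dp + dm, strand_depth = list(`+` = dp, `-` = dm))
  bp <- detect_breakpoints(tr)
  expect_setequal(bp$strand, c("+", "-"))
  expect_equal(bp$position[bp$strand == "+"], 1000L)
  expect_equal(bp$position[bp$strand == "-"], 1200L)
})

test_that("correlation p-values follow the t transform", {
  expect_equal(correlation_pvalue(0, 100), 1)
  expect_equal(correlation_pvalue(1, 100), 0)
  expect_equal(correlation_pvalue(-1, 100), 0)
  # independent numeric evaluation of the t density integral for r = 0.7
  tval <- 0.7 * sqrt(98 / (1 - 0.49))
  p_num <- 2 * stats::integrate(function(x) stats::dt(x, 98), tval, Inf,
                                rel.tol = 1e-12)$value
  expect_equal(correlation_pvalue(0.7, 100), p_num, tolerance = 1e-10)
  expect_lt(correlation_pvalue(0.7, 100), 1e-7)
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
})

test_that("RPKM follows the stated formula and its invariances", {
  # uniform depth: identical RPKM for all intervals
  tr <- coverage_track(rep(4, 10000))
  iv <- data.frame(feature_id = c("a", "b"), kind = "CDS",
                   start = c(1L, 2001L), end = c(500L, 9000L))
  e <- compute_rpkm(tr, iv)
  expect_equal(e$rpkm[1], e$rpkm[2])

  # hand-evaluated example: C = 1000, N = 1e5, RPKM = 1e4
  d <- rep(0, 20000); d[1001:2000] <- 50
  d[3000:20000] <- (5e6 - 5e4) / length(3000:20000)
  tr2 <- coverage_track(d)
  expect_equal(tr2$total_mapped_bases, 5e6)
  e2 <- compute_rpkm(tr2, data.frame(feature_id = "x", kind = "CDS",
                                     start = 1001L, end = 2000L))
  expect_equal(e2$rpkm, 10000)
  expect_equal(e2$log2_rpkm, log2(10001))

  # scaling all depths cancels
  e3 <- compute_rpkm(coverage_track(7 * d),
                     data.frame(feature_id = "x", kind = "CDS",
                                start = 1001L, end = 2000L))
  expect_equal(e3$rpkm, e2$rpkm)

  expect_error(compute_rpkm(coverage_track(rep(0, 100)),
                            data.frame(feature_id = "x", kind = "CDS",
                                       start = 1L, end = 10L)),
               "empty library")
})

test_that("RPKM of a union interval is the length-weighted mean of its parts", {
  set.seed(11)
  tr <- coverage_track(rpois(5000, 20))
  a <- compute_rpkm(tr, data.frame(feature_id = "a", kind = "CDS",
                                   start = 101L, end = 400L))
  b <- compute_rpkm(tr, data.frame(feature_id = "b", kind = "CDS",
                                   start = 401L, end = 1000L))
  u <- compute_rpkm(tr, data.frame(feature_id = "u", kind = "CDS",
                                   start = 101L, end = 1000L))
  expect_equal(u$rpkm, (300 * a$rpkm + 600 * b$rpkm) / 900, tolerance = 1e-12)
})

test_that("expression thresholds use interpolated percentiles per feature class", {
  rec <- data.frame(feature_id = c(sprintf("c%d", 1:100), "i1", "i2"),
                    kind = c(rep("CDS", 100), "IGR", "IGR"),
                    start = 1L, end = 10L, rpkm = 0,
                    log2_rpkm = c(1:100, 5, 7))
  th <- expression_thresholds(rec, percentile = 10)
  expect_gte(th$cds_min, 10); expect_lte(th$cds_min, 11)
  expect_equal(th$igr_min, 5.2)          # interpolated between 5 and 7

  same <- rec; same$log2_rpkm <- 3
  th2 <- expression_thresholds(same)
  expect_equal(th2$cds_min, 3); expect_equal(th2$igr_min, 3)

  th0 <- expression_thresholds(rec, percentile = 0)
  expect_equal(th0$cds_min, 1)

  expect_error(expression_thresholds(rec[rec$kind == "CDS", ]), "IGR")
})
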
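make_confirm_inputs <- function(fx = fixture_operon()) {
  expr <- fixture_expression(fx)
  bp <- detect_breakpoints(fx$track)
  # fixed thresholds: the fixture's CDS depths are deliberately uniform, so
  # a percentile threshold would equal every value and reject all genes
  th <- list(cds_min = 1, igr_min = 1)
  list(fx = fx, expr = expr, bp = bp, th = th, cfg = detector_config())
}

test_that("adjacent pairs are same-strand chromosomal neighbours with IGR coordinates", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      start = c(1L, 151L, 400L, 700L),
                      end = c(100L, 300L, 650L, 800L),
                      strand = c("+", "+", "-", "+"),
                      stringsAsFactors = FALSE)
  p <- adjacent_pairs(genes)
  # b-c and c-d are opposite-strand: only a-b qualifies
  expect_equal(p$pair_id, "a|b")
  expect_equal(p$igr_start, 101L); expect_equal(p$igr_end, 150L)
  expect_equal(p$igr_len, 50L)
})

test_that("operon start points require fold change, expression, reference membership and UTR room", {
  ci <- make_confirm_inputs()
  osp <- select_osp(ci$bp, ci$expr, ci$fx$genes, ci$fx$ref, ci$th, ci$cfg)
  # the plateau rise at 451 anchors gA (gap 50 <= 300)
  expect_equal(nrow(osp), 1L)
  expect_equal(osp$gene_id, "gA")
  expect_equal(osp$operon_id, "op1")
  expect_equal(osp$gap, 50L)

  # low fold change is rejected
  weak <- ci$bp; weak$fold_change <- 1.5
  expect_equal(nrow(select_osp(weak, ci$expr, ci$fx$genes, ci$fx$ref,
                               ci$th, ci$cfg)), 0L)

  # gD's rise exists but gD is in no reference operon: not an anchor
  expect_false("gD" %in% osp$gene_id)

  # an unexpressed downstream gene is rejected
  e0 <- ci$expr
  e0$log2_rpkm[e0$feature_id == "gA"] <- 0
  expect_equal(nrow(select_osp(ci$bp, e0, ci$fx$genes, ci$fx$ref,
                               ci$th, ci$cfg)), 0L)
})

test_that("operon end points mirror start points downstream", {
  ci <- make_confirm_inputs()
  oep <- select_oep(ci$bp, ci$expr, ci$fx$genes, ci$fx$ref, ci$th, ci$cfg)
  expect_equal(oep$gene_id, "gC")       # plateau fall at 1760, 60 nt past gC
  expect_equal(oep$kind, "decrease")
  # increase breakpoints never become plus-strand end points
  inc_only <- ci$bp[ci$bp$kind == "increase", ]
  expect_equal(nrow(select_oep(inc_only, ci$expr, ci$fx$genes, ci$fx$ref,
                               ci$th, ci$cfg)), 0L)
})

test_that("linkage confirms the whole expressed operon and stops at broken rules", {
  ci <- make_confirm_inputs()
  osp <- select_osp(ci$bp, ci$expr, ci$fx$genes, ci$fx$ref, ci$th, ci$cfg)
  conf <- link_operons(osp, ci$fx$genes, ci$fx$ref, ci$expr, ci$bp, ci$th)
  expect_equal(conf$gene_id, c("gA", "gB", "gC"))
  expect_equal(conf$position, 1:3)

  # silent second IGR stops linkage after two genes
  e2 <- ci$expr
  e2$log2_rpkm[e2$feature_id == "gB|gC"] <- 0
  conf2 <- link_operons(osp, ci$fx$genes, ci$fx$ref, e2, ci$bp, ci$th)
  expect_equal(conf2$gene_id, c("gA", "gB"))

  # unexpressed second gene leaves a singleton: no confirmed operon
  e3 <- ci$expr
  e3$log2_rpkm[e3$feature_id == "gB"] <- 0
  expect_equal(nrow(link_operons(osp, ci$fx$genes, ci$fx$ref, e3, ci$bp,
                                 ci$th)), 0L)

  # a breakpoint inside an IGR breaks the link
  bp_split <- rbind(ci$bp, data.frame(position = 900L, kind = "decrease",
                                      r = -0.9, p_value = 1e-10,
                                      fold_change = 5, strand = "*"))
  conf3 <- link_operons(osp, ci$fx$genes, ci$fx$ref, ci$expr, bp_split, ci$th)
  expect_equal(nrow(conf3), 0L)   # gA alone is below the 2-gene minimum
})

test_that("confirmed operons are contiguous runs of their reference operon", {
  sim <- simulate_transcriptome(sim_config(seed = 21, noise = "none"))
  bp <- detect_breakpoints(sim$track)
  pairs0 <- adjacent_pairs(sim$genes)
  iv <- rbind(data.frame(feature_id = sim$genes$gene_id, kind = "CDS",
                         start = sim$genes$start, end = sim$genes$end,
                         stringsAsFactors = FALSE),
              data.frame(feature_id = pairs0$pair_id[pairs0$igr_len > 0],
                         kind = "IGR",
                         start = pairs0$igr_start[pairs0$igr_len > 0],
                         end = pairs0$igr_end[pairs0$igr_len > 0],
                         stringsAsFactors = FALSE))
  expr <- compute_rpkm(sim$track, iv)
  th <- expression_thresholds(expr)
  osp <- select_osp(bp, expr, sim$genes, sim$ref_operons, th)
  conf <- link_operons(osp, sim$genes, sim$ref_operons, expr, bp, th)
  expect_gt(nrow(conf), 0L)
  for (oid in unique(conf$operon_id)) {
    run <- conf[conf$operon_id == oid, ]
    run <- run[order(run$position), ]
    ref <- sim$ref_operons[sim$ref_operons$operon_id ==
                             run$reference_operon_id[1], ]
    ref <- ref[order(ref$position), ]
    idx <- match(run$gene_id, ref$gene_id)
    expect_false(anyNA(idx))
    expect_equal(idx, seq(idx[1], length.out = nrow(run)))  # contiguous run
  }
})

test_that("pair labels partition same-strand adjacencies with OP priority", {
  ci <- make_confirm_inputs()
  osp <- select_osp(ci$bp, ci$expr, ci$fx$genes, ci$fx$ref, ci$th, ci$cfg)
  conf <- link_operons(osp, ci$fx$genes, ci$fx$ref, ci$expr, ci$bp, ci$th)
  lp <- label_pairs(ci$fx$genes, conf, ci$fx$ref, ci$bp, ci$expr, ci$th)
  lab <- stats::setNames(lp$label, lp$pair_id)
  expect_equal(unname(lab[c("gA|gB", "gB|gC")]), c("OP", "OP"))
  # gC-gD: breakpoints (gC fall, gD rise) sit in the IGR -> NOP
  expect_equal(unname(lab["gC|gD"]), "NOP")
  expect_true(all(lp$label %in% c("OP", "NOP", "POP", "EGP", "unlabeled")))

  # with no breakpoints at all the NOP becomes expression-driven (POP here:
  # both expressed, not co-operonic in the reference)
  lp2 <- label_pairs(ci$fx$genes, conf, ci$fx$ref, ci$bp[0, ], ci$expr, ci$th)
  expect_equal(lp2$label[lp2$pair_id == "gC|gD"], "POP")

  # suppressing the operon start leaves the expressed reference pair an EGP
  lp3 <- label_pairs(ci$fx$genes, conf[0, ], ci$fx$ref, ci$bp[0, ], ci$expr,
                     ci$th)
  expect_equal(lp3$label[lp3$pair_id == "gA|gB"], "EGP")
})

test_that("minus-strand operons anchor and link in transcription order", {
  # mirror fixture: three-gene operon on the minus strand; transcription
  # runs right-to-left, so the 5' rise is a genomic-coordinate decrease at
  # the right edge of the plateau
  genes <- data.frame(gene_id = c("m1", "m2", "m3"),
                      start = c(1401L, 951L, 501L),
                      end = c(1700L, 1250L, 800L),
                      strand = "-", stringsAsFactors = FALSE)
  depth <- rep(0, 5000); depth[451:1760] <- 90
  track <- coverage_track(depth)
  ref <- data.frame(operon_id = "mop", gene_id = c("m1", "m2", "m3"),
                    position = 1:3, stringsAsFactors = FALSE)
  pairs0 <- adjacent_pairs(genes)
  iv <- rbind(data.frame(feature_id = genes$gene_id, kind = "CDS",
                         start = genes$start, end = genes$end,
                         stringsAsFactors = FALSE),
              data.frame(feature_id = pairs0$pair_id, kind = "IGR",
                         start = pairs0$igr_start, end = pairs0$igr_end,
                         stringsAsFactors = FALSE))
  expr <- compute_rpkm(track, iv)
  th <- list(cds_min = 1, igr_min = 1)
  bp <- detect_breakpoints(track)
  osp <- select_osp(bp, expr, genes, ref, th)
  expect_equal(osp$gene_id, "m1")
  expect_equal(osp$kind, "decrease")
  conf <- link_operons(osp, genes, ref, expr, bp, th)
  expect_equal(conf$gene_id, c("m1", "m2", "m3"))
})
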
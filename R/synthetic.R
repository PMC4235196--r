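# Synthetic prokaryotic transcriptome generator with full ground truth:
# genome annotation, CDS sequences with shared within-operon codon bias, a
# deliberately corrupted reference operon table, and step-shaped noisy
# per-base coverage. Every stage of the pipeline is testable against the
# emitted truth without external data.

#' Simulation configuration
#'
#' Defaults describe the data regime the method assumes: operons of 1-8
#' genes (truncated geometric sizes), short expressed intra-operon
#' intergenic regions, longer silent gaps between transcription units, per-TU
#' log2 depth drawn from a normal distribution, Poisson per-base noise over
#' a low background, and a reference operon table corrupted by splits and
#' merges to create putative/expressed-gene-pair cases.
#'
#' @param seed Master seed; genome layout and sequences depend only on it,
#'   expression is re-drawn per condition.
#' @param n_operons Number of transcription units laid on the genome.
#' @param size_p Geometric parameter of the operon size distribution,
#'   truncated to `[1, size_max]`.
#' @param size_max Maximum operon size (default 8).
#' @param within_igr_mean,within_igr_sd,within_igr_floor Normal parameters
#'   (nt) of intra-operon intergenic lengths; the floor allows overlaps
#'   (default mean 20, sd 15, floor -20).
#' @param between_igr_mean,between_igr_sd,between_igr_floor Normal
#'   parameters (nt) of gaps between transcription units (default mean 150,
#'   sd 60, floor 40).
#' @param expr_mean,expr_sd Per-TU log2 depth distribution (default N(6, 2)).
#' @param fraction_silent Fraction of TUs silent in a condition (default
#'   0.15).
#' @param noise `"poisson"` (default) or `"none"` (deterministic rounded
#'   depth); `nb_dispersion` switches Poisson to negative binomial with the
#'   given dispersion.
#' @param background_depth Mean depth outside transcribed spans (default
#'   0.2).
#' @param read_length Read length in nt for RPKM estimation (default 50).
#' @param boundary_sharpness Ramp width in nt over which coverage rises at
#'   TU edges (default 0 = ideal step).
#' @param annotation_error_rate Fraction of reference operons corrupted by
#'   splits/merges (default 0.10).
#' @param codon_bias_strength Dirichlet concentration of per-operon codon
#'   preferences; smaller values give stronger shared within-operon bias
#'   (default 0.5).
#' @param internal_start_rate Probability that an expressed multi-gene TU
#'   uses a condition-dependent internal start (default 0.10).
#' @param utr_range 5'/3' UTR length range in nt (default 20-80).
#' @param gene_codons_range Gene length range in codons (default 100-300).
#' @param nb_dispersion Optional negative-binomial dispersion (NULL =
#'   Poisson).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_operons = 120L, size_p = 0.45,
                       size_max = 8L,
                       within_igr_mean = 20, within_igr_sd = 15,
                       within_igr_floor = -20,
                       between_igr_mean = 150, between_igr_sd = 60,
                       between_igr_floor = 40,
                       expr_mean = 6, expr_sd = 2,
                       fraction_silent = 0.15,
                       noise = c("poisson", "none"),
                       background_depth = 0.2,
                       read_length = 50L,
                       boundary_sharpness = 0L,
                       annotation_error_rate = 0.10,
                       codon_bias_strength = 0.5,
                       internal_start_rate = 0.10,
                       utr_range = c(20L, 80L),
                       gene_codons_range = c(100L, 300L),
                       nb_dispersion = NULL) {
  noise <- match.arg(noise)
  stopifnot(fraction_silent >= 0, fraction_silent <= 1,
            annotation_error_rate >= 0, annotation_error_rate <= 1,
            internal_start_rate >= 0, internal_start_rate <= 1,
            n_operons >= 1, size_max >= 1)
  structure(as.list(environment()), class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, floor) pmax(round(stats::rnorm(n, mean, sd)), floor)

# per-operon codon sampling probabilities: uniform over amino acids, operon-
# specific Dirichlet preference within each synonymous family
operon_codon_probs <- function(concentration) {
  tab <- sense_codon_table()
  aa <- unname(tab)
  p <- numeric(length(tab))
  for (a in unique(aa)) {
    ii <- which(aa == a)
    w <- stats::rgamma(length(ii), shape = concentration)
    if (sum(w) <= 0) w <- rep(1, length(ii))
    p[ii] <- (w / sum(w)) / length(unique(aa))
  }
  stats::setNames(p, names(tab))
}

sample_cds <- function(n_codons, codon_probs) {
  body <- sample(names(codon_probs), n_codons - 2L, replace = TRUE,
                 prob = codon_probs)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Simulate a bacterial transcriptome with ground truth
#'
#' The genome layout (gene coordinates, strands, CDS sequences) and the
#' reference operon table (true operons corrupted at
#' `annotation_error_rate`: splits create putative-operon-pair
#' opportunities, merges create non-operon / expressed-gene-pair
#' opportunities) depend only on `cfg$seed`. Expression — the silent-TU set,
#' per-TU levels and internal-start usage — is re-drawn per `condition`, so
#' two conditions from the same config share the genome but differ in their
#' transcribed units, emulating condition-dependent operon structure.
#'
#' @param cfg A [sim_config()].
#' @param condition Condition index (default 1).
#' @return List with `genes` (annotation data.frame), `cds` (named character
#'   vector), `track` ([coverage_track()]), `ref_operons` (long-format
#'   reference table), `truth` (list `tus`, `pairs`), `genome_length`,
#'   `cfg`, `condition`.
#' @export
simulate_transcriptome <- function(cfg = sim_config(), condition = 1L) {
  stopifnot(inherits(cfg, "sim_config"))

  ## --- layout (seed only) ---------------------------------------------
  set.seed(derive_seed(cfg$seed, 1))
  sizes <- sample(seq_len(cfg$size_max), cfg$n_operons, replace = TRUE,
                  prob = stats::dgeom(seq_len(cfg$size_max) - 1L, cfg$size_p))
  strands <- sample(c("+", "-"), cfg$n_operons, replace = TRUE)
  n_genes <- sum(sizes)
  codons <- sample(seq(cfg$gene_codons_range[1], cfg$gene_codons_range[2]),
                   n_genes, replace = TRUE)
  gene_len <- 3L * codons
  margin <- 400L
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  op_id <- sprintf("op%03d", seq_len(cfg$n_operons))
  gstart <- integer(n_genes); gend <- integer(n_genes)
  gstrand <- character(n_genes); gop <- character(n_genes)
  pos <- margin
  k <- 0L
  op_first <- integer(cfg$n_operons)
  for (o in seq_len(cfg$n_operons)) {
    gap <- rtrunc_norm(1, cfg$between_igr_mean, cfg$between_igr_sd,
                       cfg$between_igr_floor)
    pos <- pos + gap
    op_first[o] <- k + 1L
    for (j in seq_len(sizes[o])) {
      k <- k + 1L
      if (j > 1L) {
        igr <- rtrunc_norm(1, cfg$within_igr_mean, cfg$within_igr_sd,
                           cfg$within_igr_floor)
        pos <- gend[k - 1L] + igr
      }
      gstart[k] <- pos + 1L
      gend[k] <- pos + gene_len[k]
      gstrand[k] <- strands[o]
      gop[k] <- op_id[o]
      pos <- gend[k]
    }
  }
  genome_length <- pos + margin
  genes <- data.frame(gene_id = gene_id, start = gstart, end = gend,
                      strand = gstrand, stringsAsFactors = FALSE)

  ## --- CDS sequences with shared within-operon codon bias --------------
  set.seed(derive_seed(cfg$seed, 2))
  cds <- character(n_genes)
  for (o in seq_len(cfg$n_operons)) {
    pr <- operon_codon_probs(cfg$codon_bias_strength)
    ii <- which(gop == op_id[o])
    for (i in ii) cds[i] <- sample_cds(codons[i], pr)
  }
  names(cds) <- gene_id

  ## --- true operons and corrupted reference table ----------------------
  # transcription order: genomic for +, reversed for -
  tx_order <- function(ii, strand) if (strand == "+") ii else rev(ii)
  true_ops <- lapply(seq_len(cfg$n_operons), function(o) {
    ii <- which(gop == op_id[o])
    gene_id[tx_order(ii, strands[o])]
  })
  set.seed(derive_seed(cfg$seed, 3))
  multi <- which(sizes >= 2L)
  split_set <- multi[stats::runif(length(multi)) < cfg$annotation_error_rate / 2]
  # merge adjacent same-strand TU pairs not involved in a split, no chaining
  merge_with_next <- rep(FALSE, cfg$n_operons)
  for (o in seq_len(cfg$n_operons - 1L)) {
    if (strands[o] == strands[o + 1L] &&
        !(o %in% split_set) && !((o + 1L) %in% split_set) &&
        !merge_with_next[o] && (o > 1L && !merge_with_next[o - 1L] || o == 1L) &&
        stats::runif(1) < cfg$annotation_error_rate / 2)
      merge_with_next[o] <- TRUE
  }
  ref_rows <- list()
  o <- 1L
  ref_i <- 0L
  while (o <= cfg$n_operons) {
    if (merge_with_next[o]) {
      # merged reference operon: concatenate in transcription order of the
      # merged span (5'-most TU first)
      a <- true_ops[[o]]; b <- true_ops[[o + 1L]]
      gl <- if (strands[o] == "+") c(a, b) else c(b, a)
      ref_i <- ref_i + 1L
      ref_rows[[length(ref_rows) + 1L]] <-
        data.frame(operon_id = sprintf("ref%03d", ref_i), gene_id = gl,
                   position = seq_along(gl), stringsAsFactors = FALSE)
      o <- o + 2L
    } else if (o %in% split_set) {
      gl <- true_ops[[o]]
      cut <- sample(seq_len(length(gl) - 1L), 1L)
      for (piece in list(gl[seq_len(cut)], gl[-seq_len(cut)])) {
        if (length(piece) >= 2L) {
          ref_i <- ref_i + 1L
          ref_rows[[length(ref_rows) + 1L]] <-
            data.frame(operon_id = sprintf("ref%03d", ref_i), gene_id = piece,
                       position = seq_along(piece), stringsAsFactors = FALSE)
        }
      }
      o <- o + 1L
    } else {
      gl <- true_ops[[o]]
      if (length(gl) >= 2L) {
        ref_i <- ref_i + 1L
        ref_rows[[length(ref_rows) + 1L]] <-
          data.frame(operon_id = sprintf("ref%03d", ref_i), gene_id = gl,
                     position = seq_along(gl), stringsAsFactors = FALSE)
      }
      o <- o + 1L
    }
  }
  ref_operons <- do.call(rbind, ref_rows)
  rownames(ref_operons) <- NULL

  ## --- condition-dependent expression ----------------------------------
  set.seed(derive_seed(cfg$seed, 4, condition))
  silent <- stats::runif(cfg$n_operons) < cfg$fraction_silent
  # expressed means expressed: the level of a transcribed TU is kept at
  # least ~20x background, so the truth label never describes a plateau
  # indistinguishable from noise (silence is governed by fraction_silent,
  # not by the tail of the level distribution)
  level_log2 <- pmax(stats::rnorm(cfg$n_operons, cfg$expr_mean, cfg$expr_sd), 2)
  int_start <- rep(1L, cfg$n_operons)
  for (o in which(!silent & sizes >= 2L)) {
    if (stats::runif(1) < cfg$internal_start_rate) {
      # an internal promoter needs intergenic sequence: only junctions with
      # a positive gap (in transcription order) are eligible start sites
      tx <- gene_id[tx_order(which(gop == op_id[o]), strands[o])]
      idx <- match(tx, gene_id)
      eligible <- which(vapply(2:length(tx), function(j) {
        a <- idx[j - 1L]; b <- idx[j]
        max(gstart[a], gstart[b]) - min(gend[a], gend[b]) - 1L > 0L
      }, logical(1))) + 1L
      if (length(eligible))
        int_start[o] <- eligible[sample.int(length(eligible), 1L)]
    }
  }
  utr5 <- sample(seq(cfg$utr_range[1], cfg$utr_range[2]), cfg$n_operons,
                 replace = TRUE)
  utr3 <- sample(seq(cfg$utr_range[1], cfg$utr_range[2]), cfg$n_operons,
                 replace = TRUE)

  depth_mean <- rep(cfg$background_depth, genome_length)
  tus <- list()
  covered <- character(0)
  # UTR extensions are bounded so that a silent stretch always remains
  # between neighbouring transcription units (reserve below): adjacent
  # transcripts must not fuse into one plateau
  reserve <- 60L
  for (o in seq_len(cfg$n_operons)) {
    ii <- which(gop == op_id[o])
    tx <- gene_id[tx_order(ii, strands[o])]
    use <- tx[int_start[o]:length(tx)]            # genes actually transcribed
    span_lo <- min(genes$start[match(use, genes$gene_id)])
    span_hi <- max(genes$end[match(use, genes$gene_id)])
    left_ends <- genes$end[genes$end < span_lo]
    avail_l <- if (length(left_ends)) span_lo - max(left_ends) - 1L
               else span_lo - 1L
    right_starts <- genes$start[genes$start > span_hi]
    avail_r <- if (length(right_starts)) min(right_starts) - span_hi - 1L
               else genome_length - span_hi
    # at least 1 nt of UTR whenever the gap allows it: transcription starts
    # and ends outside the coding sequence, so boundary breakpoints fall
    # strictly inside the intergenic region
    cap_l <- if (avail_l >= 2L) max(1L, (avail_l - reserve) %/% 2L) else 0L
    cap_r <- if (avail_r >= 2L) max(1L, (avail_r - reserve) %/% 2L) else 0L
    if (strands[o] == "+") {
      ext_l <- min(utr5[o], cap_l); ext_r <- min(utr3[o], cap_r)
    } else {
      ext_l <- min(utr3[o], cap_l); ext_r <- min(utr5[o], cap_r)
    }
    tu_start <- span_lo - ext_l; tu_end <- span_hi + ext_r
    expressed <- !silent[o]
    if (expressed) {
      d <- 2^level_log2[o]
      s <- cfg$boundary_sharpness
      depth_mean[tu_start:tu_end] <- d
      if (s > 0L) {
        ramp <- seq(cfg$background_depth, d, length.out = s + 2L)[2:(s + 1L)]
        depth_mean[tu_start:(tu_start + s - 1L)] <- ramp
        depth_mean[(tu_end - s + 1L):tu_end] <- rev(ramp)
      }
      covered <- c(covered, use)
    }
    tus[[o]] <- data.frame(
      tu_id = sprintf("tu%03d", o), operon_id = op_id[o],
      genes = paste(use, collapse = ","), n_genes = length(use),
      strand = strands[o], start = tu_start, end = tu_end,
      level_log2 = if (expressed) level_log2[o] else NA_real_,
      expressed = expressed, internal_start = int_start[o],
      stringsAsFactors = FALSE)
  }
  tus <- do.call(rbind, tus)

  depth <- switch(cfg$noise,
    none = round(depth_mean),
    poisson = if (is.null(cfg$nb_dispersion)) stats::rpois(genome_length, depth_mean)
              else stats::rnbinom(genome_length, mu = depth_mean,
                                  size = 1 / cfg$nb_dispersion))
  track <- coverage_track(depth, read_length = cfg$read_length)

  ## --- truth pair labels ------------------------------------------------
  ap <- adjacent_pairs(genes)
  same_tu <- gop[match(ap$gene_i, gene_id)] == gop[match(ap$gene_j, gene_id)]
  co <- same_tu & ap$gene_i %in% covered & ap$gene_j %in% covered
  truth_pairs <- data.frame(pair_id = ap$pair_id, gene_i = ap$gene_i,
                            gene_j = ap$gene_j, strand = ap$strand,
                            co_transcribed = co, stringsAsFactors = FALSE)

  list(genes = genes, cds = cds, track = track, ref_operons = ref_operons,
       truth = list(tus = tus, pairs = truth_pairs),
       genome_length = genome_length, cfg = cfg,
       condition = as.integer(condition))
}

#' Write a simulated dataset to standard-format files
#'
#' Emits `genes.gff3`, `cds.fasta`, `coverage.tsv` (position/depth),
#' `ref_operons.tsv`, `truth_tus.tsv` and `truth_pairs.tsv` into `dir`.
#'
#' @param sim [simulate_transcriptome()] output.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gff = file.path(dir, "genes.gff3"),
             fasta = file.path(dir, "cds.fasta"),
             coverage = file.path(dir, "coverage.tsv"),
             operons = file.path(dir, "ref_operons.tsv"),
             tus = file.path(dir, "truth_tus.tsv"),
             pairs = file.path(dir, "truth_pairs.tsv"))
  write_annotation(sim$genes, paths["gff"])
  write_cds(sim$cds, paths["fasta"])
  write_coverage(sim$track, paths["coverage"])
  write_operon_table(sim$ref_operons, paths["operons"])
  for (nm in c("tus", "pairs")) {
    tab <- sim$truth[[nm]]
    writeLines(paste0("# ", paste(names(tab), collapse = "\t")), paths[nm])
    utils::write.table(tab, paths[nm], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  }
  invisible(paths)
}

#' Fraction of true TU boundaries recovered by detected breakpoints
#'
#' A 5' boundary (genomic left edge of an expressed TU) counts as recovered
#' when an increase breakpoint lies within `tol` nt of it; a 3' (right) edge
#' needs a decrease breakpoint. Also returns the signed distances of the
#' matched breakpoints.
#'
#' @param breakpoints [detect_breakpoints()] output.
#' @param tus Truth TU table from [simulate_transcriptome()].
#' @param tol Matching tolerance in nt (default 50).
#' @return List `recovered` (fraction), `n_boundaries`, `distances`.
#' @export
boundary_recovery <- function(breakpoints, tus, tol = 50) {
  ex <- tus[tus$expressed, , drop = FALSE]
  edges <- rbind(data.frame(pos = ex$start, kind = "increase"),
                 data.frame(pos = ex$end, kind = "decrease"))
  if (!nrow(edges)) return(list(recovered = NaN, n_boundaries = 0L,
                                distances = numeric(0)))
  dist <- vapply(seq_len(nrow(edges)), function(i) {
    bp <- breakpoints[breakpoints$kind == edges$kind[i], , drop = FALSE]
    if (!nrow(bp)) return(Inf)
    d <- bp$position - edges$pos[i]
    d[which.min(abs(d))]
  }, numeric(1))
  hit <- abs(dist) <= tol
  list(recovered = mean(hit), n_boundaries = nrow(edges),
       distances = dist[is.finite(dist)])
}

#' Compare a predicted operon map against ground truth
#'
#' Junction-level precision (predicted OP junctions that are truly
#' co-transcribed) and recall (true co-transcribed junctions predicted),
#' plus boundary-distance quantiles when breakpoints and truth TUs are
#' supplied. Precision is `NaN` (flagged) for an empty prediction.
#'
#' @param map [assemble_map()] output.
#' @param truth Truth list from [simulate_transcriptome()] (`$pairs`,
#'   `$tus`).
#' @param breakpoints Optional [detect_breakpoints()] output for boundary
#'   accuracy.
#' @param tol Boundary matching tolerance (default 50 nt).
#' @return List `precision`, `recall`, `n_predicted`, `n_truth`, and
#'   optionally `boundary` (list from [boundary_recovery()]).
#' @export
truth_compare <- function(map, truth, breakpoints = NULL, tol = 50) {
  if (!all(c(map$gene_i, map$gene_j) %in%
           c(truth$pairs$gene_i, truth$pairs$gene_j)))
    stopf("predicted map contains gene ids absent from the truth")
  pred <- unique(map$pair_id)
  tru <- truth$pairs$pair_id[truth$pairs$co_transcribed]
  res <- list(
    precision = if (length(pred)) mean(pred %in% tru) else NaN,
    recall = if (length(tru)) mean(tru %in% pred) else NaN,
    n_predicted = length(pred), n_truth = length(tru))
  if (!is.null(breakpoints))
    res$boundary <- boundary_recovery(breakpoints, truth$tus, tol)
  res
}

#' Simulate a class-conditional feature table
#'
#' Draws OP and NOP pair features directly from class-conditional
#' distributions mirroring the regime the full generator produces
#' (short/expressed intergenic regions and similar expression within
#' operons; long/silent gaps and discordant expression between them),
#' for fast classifier experiments. Features excluded from `informative`
#' are drawn from the pooled (class-independent) distribution, so they carry
#' no signal.
#'
#' @param n_op,n_nop Pairs per class (defaults 200/200).
#' @param seed Seed.
#' @param informative Character vector of informative features (default all
#'   four).
#' @return Feature table with columns `pair_id`, `label` and the four
#'   features.
#' @export
simulate_pair_features <- function(n_op = 200L, n_nop = 200L, seed = 1L,
                                   informative = FEATURES) {
  set.seed(derive_seed(seed, 7))
  n <- n_op + n_nop
  lab <- c(rep("OP", n_op), rep("NOP", n_nop))
  draw <- function(f, class, k) {
    switch(f,
      igr_length = if (class == "OP") round(stats::rnorm(k, 20, 15))
                   else round(stats::rnorm(k, 150, 60)),
      cu_score = if (class == "OP") stats::rnorm(k, 90, 10)
                 else stats::rnorm(k, 70, 10),
      diff_expr = if (class == "OP") abs(stats::rnorm(k, 0, 0.6))
                  else abs(stats::rnorm(k, 3, 1.5)),
      igr_expr = if (class == "OP") stats::rnorm(k, 6, 1.5)
                 else pmax(stats::rnorm(k, 0.5, 0.7), 0))
  }
  tbl <- data.frame(pair_id = sprintf("p%04d", seq_len(n)), label = lab,
                    stringsAsFactors = FALSE)
  for (f in FEATURES) {
    if (f %in% informative) {
      tbl[[f]] <- c(draw(f, "OP", n_op), draw(f, "NOP", n_nop))
    } else {
      # class-independent: draw from the OP/NOP mixture for all rows
      mix <- sample(c("OP", "NOP"), n, replace = TRUE)
      v <- numeric(n)
      v[mix == "OP"] <- draw(f, "OP", sum(mix == "OP"))
      v[mix == "NOP"] <- draw(f, "NOP", sum(mix == "NOP"))
      tbl[[f]] <- v
    }
  }
  set.seed(derive_seed(seed, 8))
  tbl[sample(n), , drop = FALSE]
}
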
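# Operon confirmation: anchor operon start/end points at breakpoints, link
# confirmed operons through expressed intergenic regions, and label adjacent
# same-strand gene pairs as OP / NOP / POP / EGP.

#' Enumerate adjacent same-strand gene pairs
#'
#' Pairs are formed by genes that are consecutive on the chromosome (no gene
#' of either strand in between) and lie on the same strand. The intergenic
#' region is `[end_i + 1, start_j - 1]` in genomic coordinates; `igr_len <= 0`
#' marks abutting or overlapping genes (no region).
#'
#' @param genes Annotation data.frame ([read_annotation()]).
#' @return data.frame `pair_id`, `gene_i`, `gene_j` (genomic order: i
#'   upstream), `strand`, `igr_start`, `igr_end`, `igr_len`.
#' @export
adjacent_pairs <- function(genes) {
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  n <- nrow(genes)
  empty <- data.frame(pair_id = character(), gene_i = character(),
                      gene_j = character(), strand = character(),
                      igr_start = integer(), igr_end = integer(),
                      igr_len = integer(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  i <- seq_len(n - 1L)
  same <- genes$strand[i] == genes$strand[i + 1L]
  i <- i[same]
  if (!length(i)) return(empty)
  igr_len <- genes$start[i + 1L] - genes$end[i] - 1L
  data.frame(pair_id = pair_id(genes$gene_id[i], genes$gene_id[i + 1L]),
             gene_i = genes$gene_id[i], gene_j = genes$gene_id[i + 1L],
             strand = genes$strand[i],
             igr_start = genes$end[i] + 1L,
             igr_end = genes$start[i + 1L] - 1L,
             igr_len = as.integer(igr_len),
             stringsAsFactors = FALSE)
}

# IGR intervals (positive length only) of a pair table, as expression input
igr_intervals <- function(pairs) {
  keep <- pairs$igr_len > 0L
  data.frame(feature_id = pairs$pair_id[keep], kind = "IGR",
             start = pairs$igr_start[keep], end = pairs$igr_end[keep],
             strand = pairs$strand[keep], stringsAsFactors = FALSE)
}

# breakpoint strand compatible with a gene/pair strand
strand_compatible <- function(bp_strand, strand) {
  bp_strand == "*" | bp_strand == strand
}

# For a gene on the minus strand the transcript runs right-to-left in genome
# coordinates, so its 5' rise appears as a genomic-coordinate *decrease* and
# its 3' fall as an *increase*; anchoring logic below mirrors accordingly.
anchor_points <- function(breakpoints, expression, genes, ref_operons, cfg,
                          role = c("start", "end"), first_gene_only = FALSE,
                          cds_min) {
  role <- match.arg(role)
  e_cds <- expression[expression$kind == "CDS", , drop = FALSE]
  expr_of <- stats::setNames(e_cds$log2_rpkm, e_cds$feature_id)
  op_of <- stats::setNames(ref_operons$operon_id, ref_operons$gene_id)
  pos_of <- stats::setNames(ref_operons$position, ref_operons$gene_id)
  out <- list()
  for (k in seq_len(nrow(breakpoints))) {
    bp <- breakpoints[k, ]
    if (bp$fold_change <= cfg$fold_change_min) next
    # which gene strand does this breakpoint serve in this role?
    g_strand <- if (role == "start") {
      if (bp$kind == "increase") "+" else "-"
    } else {
      if (bp$kind == "increase") "-" else "+"
    }
    if (!strand_compatible(bp$strand, g_strand)) next
    cand <- genes[genes$strand == g_strand, , drop = FALSE]
    if (!nrow(cand)) next
    five_prime_side <- (role == "start" & g_strand == "+") |
                       (role == "end" & g_strand == "-")
    if (five_prime_side) {
      gap <- cand$start - bp$position       # breakpoint left of gene start
    } else {
      gap <- bp$position - cand$end         # breakpoint right of gene end
    }
    ok <- gap >= 0L & gap <= cfg$max_utr
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    g <- cand[which.min(gap[ok]), ]         # nearest gene in transcription order
    lv <- expr_of[g$gene_id]
    if (is.na(lv) || lv <= cds_min) next    # gene must be transcribed
    oid <- op_of[g$gene_id]
    if (is.na(oid)) next                    # must be a reference structural gene
    if (first_gene_only) {
      members <- ref_operons[ref_operons$operon_id == oid, , drop = FALSE]
      if (pos_of[g$gene_id] != min(members$position)) next
    }
    out[[length(out) + 1L]] <- data.frame(
      position = bp$position, kind = bp$kind, r = bp$r,
      fold_change = bp$fold_change, gene_id = g$gene_id,
      operon_id = unname(oid), gap = min(gap[ok]),
      strand = g_strand, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(position = integer(), kind = character(),
                                      r = numeric(), fold_change = numeric(),
                                      gene_id = character(),
                                      operon_id = character(), gap = integer(),
                                      strand = character(),
                                      stringsAsFactors = FALSE)
  unique(res)
}

#' Select operon start points (OSPs)
#'
#' An increase-type breakpoint (decrease-type for minus-strand genes) becomes
#' an operon start point when (i) its depth fold change exceeds
#' `cfg$fold_change_min`, (ii) the nearest downstream gene in transcription
#' order is expressed above the CDS threshold, (iii) that gene is a
#' structural gene of a reference operon, and (iv) the gap to the gene leaves
#' room for a 5' UTR of at most `cfg$max_utr` nt.
#'
#' @param breakpoints [detect_breakpoints()] output.
#' @param expression [compute_rpkm()] output with CDS records.
#' @param genes Annotation data.frame.
#' @param ref_operons Reference operon table ([read_operon_table()]).
#' @param thresholds [expression_thresholds()] output.
#' @param cfg [detector_config()].
#' @param first_gene_only Restrict anchoring to the first gene of the
#'   reference operon (default `FALSE`: any structural gene may anchor,
#'   supporting condition-dependent internal starts).
#' @return data.frame of anchors: `position`, `kind`, `r`, `fold_change`,
#'   `gene_id`, `operon_id`, `gap`, `strand`.
#' @export
select_osp <- function(breakpoints, expression, genes, ref_operons,
                       thresholds, cfg = detector_config(),
                       first_gene_only = FALSE) {
  anchor_points(breakpoints, expression, genes, ref_operons, cfg,
                role = "start", first_gene_only = first_gene_only,
                cds_min = thresholds$cds_min)
}

#' Select operon end points (OEPs)
#'
#' Mirror image of [select_osp()]: decrease-type breakpoints (increase-type
#' for minus-strand genes) anchored at the nearest upstream gene in
#' transcription order, with a 3' gap within `[0, cfg$max_utr]`.
#'
#' @inheritParams select_osp
#' @return data.frame of anchors as in [select_osp()].
#' @export
select_oep <- function(breakpoints, expression, genes, ref_operons,
                       thresholds, cfg = detector_config(),
                       first_gene_only = FALSE) {
  anchor_points(breakpoints, expression, genes, ref_operons, cfg,
                role = "end", first_gene_only = FALSE,
                cds_min = thresholds$cds_min)
}

#' Link confirmed operons from operon start anchors
#'
#' Starting from each anchored structural gene, the next gene of the
#' reference operon (in transcription order) is appended while all three
#' linkage rules hold: the intergenic region is expressed above the IGR
#' threshold, the next gene is expressed above the CDS threshold, and no
#' breakpoint falls inside the intergenic region. Junctions without an
#' intergenic region (abutting/overlapping genes) satisfy rules 1 and 3
#' vacuously. No end-point check is made after the last linked gene. Runs of
#' fewer than two genes are discarded, as are runs fully contained in another
#' confirmed run of the same reference operon.
#'
#' @param osp_anchors [select_osp()] output.
#' @param genes Annotation data.frame.
#' @param ref_operons Reference operon table.
#' @param expression Expression table with CDS and IGR records (IGR
#'   `feature_id` = pair id).
#' @param breakpoints [detect_breakpoints()] output.
#' @param thresholds [expression_thresholds()] output.
#' @return data.frame `operon_id` (confirmed-run id, the reference id with a
#'   `.k` suffix when one reference operon yields several runs),
#'   `reference_operon_id`, `gene_id`, `position` (rank within the confirmed
#'   run), `osp_position`; one row per confirmed gene, long format like the
#'   reference table.
#' @export
link_operons <- function(osp_anchors, genes, ref_operons, expression,
                         breakpoints, thresholds) {
  pairs <- adjacent_pairs(genes)
  empty <- data.frame(operon_id = character(),
                      reference_operon_id = character(),
                      gene_id = character(), position = integer(),
                      osp_position = integer(), stringsAsFactors = FALSE)
  if (nrow(osp_anchors) == 0L) return(empty)
  e_cds <- expression[expression$kind == "CDS", , drop = FALSE]
  expr_of <- stats::setNames(e_cds$log2_rpkm, e_cds$feature_id)
  e_igr <- expression[expression$kind == "IGR", , drop = FALSE]
  igr_of <- stats::setNames(e_igr$log2_rpkm, e_igr$feature_id)
  runs <- list()
  for (k in seq_len(nrow(osp_anchors))) {
    a <- osp_anchors[k, ]
    members <- ref_operons[ref_operons$operon_id == a$operon_id, , drop = FALSE]
    members <- members[order(members$position), , drop = FALSE]
    i0 <- match(a$gene_id, members$gene_id)
    linked <- members$gene_id[i0]
    i <- i0
    while (i < nrow(members)) {
      g_cur <- members$gene_id[i]
      g_nxt <- members$gene_id[i + 1L]
      # junction in genomic orientation (transcription order may be mirrored)
      pr <- pairs[(pairs$gene_i == g_cur & pairs$gene_j == g_nxt) |
                  (pairs$gene_i == g_nxt & pairs$gene_j == g_cur), , drop = FALSE]
      if (nrow(pr) != 1L) break               # not chromosomally adjacent
      if (pr$igr_len > 0L) {
        lv_igr <- igr_of[pr$pair_id]
        if (is.na(lv_igr) || lv_igr <= thresholds$igr_min) break
        in_igr <- breakpoints$position >= pr$igr_start &
                  breakpoints$position <= pr$igr_end &
                  strand_compatible(breakpoints$strand, pr$strand)
        if (any(in_igr)) break
      }
      lv_nxt <- expr_of[g_nxt]
      if (is.na(lv_nxt) || lv_nxt <= thresholds$cds_min) break
      linked <- c(linked, g_nxt)
      i <- i + 1L
    }
    if (length(linked) >= 2L)
      runs[[length(runs) + 1L]] <- list(operon_id = a$operon_id,
                                        genes = linked,
                                        osp_position = a$position)
  }
  if (!length(runs)) return(empty)
  # drop runs contained in a longer confirmed run of the same reference operon
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) for (j in seq_along(runs)) {
    if (i == j || !keep[i]) next
    if (runs[[i]]$operon_id == runs[[j]]$operon_id &&
        all(runs[[i]]$genes %in% runs[[j]]$genes) &&
        length(runs[[i]]$genes) < length(runs[[j]]$genes))
      keep[i] <- FALSE
  }
  runs <- runs[keep]
  # dedupe identical runs (two anchors can confirm the same run)
  sig <- vapply(runs, function(r) paste(r$operon_id,
                                        paste(r$genes, collapse = ",")),
                character(1))
  runs <- runs[!duplicated(sig)]
  refs <- vapply(runs, `[[`, character(1), "operon_id")
  run_id <- refs
  for (dupref in unique(refs[duplicated(refs)])) {
    ii <- which(refs == dupref)
    run_id[ii] <- paste0(dupref, ".", seq_along(ii))
  }
  out <- do.call(rbind, lapply(seq_along(runs), function(i)
    data.frame(operon_id = run_id[i], reference_operon_id = refs[i],
               gene_id = runs[[i]]$genes,
               position = seq_along(runs[[i]]$genes),
               osp_position = runs[[i]]$osp_position,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Label adjacent same-strand gene pairs
#'
#' Every adjacent same-strand pair receives exactly one label:
#' \describe{
#'   \item{OP}{both genes are consecutive members of a confirmed operon;}
#'   \item{NOP}{a transcription breakpoint lies inside the intergenic region
#'     (expression of the genes is not required);}
#'   \item{POP}{both genes expressed above the CDS threshold and the pair is
#'     not co-operonic in the reference annotation (including extensions past
#'     the last structural gene of a reference operon);}
#'   \item{EGP}{both genes expressed and annotated co-operonic in the
#'     reference, but not linked to any identified operon start point;}
#'   \item{unlabeled}{anything else.}
#' }
#' A pair matching both OP and NOP takes OP (confirmation uses more
#' evidence) and a warning is issued.
#'
#' @param genes Annotation data.frame.
#' @param confirmed [link_operons()] output.
#' @param ref_operons Reference operon table.
#' @param breakpoints [detect_breakpoints()] output.
#' @param expression Expression table with CDS records.
#' @param thresholds [expression_thresholds()] output.
#' @return The [adjacent_pairs()] table with an added `label` column.
#' @export
label_pairs <- function(genes, confirmed, ref_operons, breakpoints,
                        expression, thresholds) {
  pairs <- adjacent_pairs(genes)
  if (nrow(pairs) == 0L) { pairs$label <- character(); return(pairs) }
  e_cds <- expression[expression$kind == "CDS", , drop = FALSE]
  expr_of <- stats::setNames(e_cds$log2_rpkm, e_cds$feature_id)

  consecutive_in <- function(tbl, gi, gj) {
    # both genes in the same operon of tbl at adjacent positions
    oi <- tbl[tbl$gene_id == gi, c("operon_id", "position")]
    oj <- tbl[tbl$gene_id == gj, c("operon_id", "position")]
    if (!nrow(oi) || !nrow(oj)) return(FALSE)
    m <- merge(oi, oj, by = "operon_id")
    any(abs(m$position.x - m$position.y) == 1L)
  }
  co_operonic <- function(gi, gj) {
    oi <- ref_operons$operon_id[ref_operons$gene_id == gi]
    oj <- ref_operons$operon_id[ref_operons$gene_id == gj]
    length(oi) > 0L && length(oj) > 0L && oi[1] == oj[1]
  }

  label <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    p <- pairs[k, ]
    is_op <- nrow(confirmed) > 0L && consecutive_in(confirmed, p$gene_i, p$gene_j)
    has_bp <- p$igr_len > 0L && any(
      breakpoints$position >= p$igr_start & breakpoints$position <= p$igr_end &
      strand_compatible(breakpoints$strand, p$strand))
    if (is_op) {
      if (has_bp) warnf("pair %s is confirmed but has a breakpoint in its IGR; labeled OP",
                        p$pair_id)
      label[k] <- "OP"
      next
    }
    if (has_bp) { label[k] <- "NOP"; next }
    both_expressed <-
      !is.na(expr_of[p$gene_i]) && expr_of[p$gene_i] > thresholds$cds_min &&
      !is.na(expr_of[p$gene_j]) && expr_of[p$gene_j] > thresholds$cds_min
    if (both_expressed) {
      label[k] <- if (co_operonic(p$gene_i, p$gene_j)) "EGP" else "POP"
    } else {
      label[k] <- "unlabeled"
    }
  }
  pairs$label <- label
  pairs
}

#' Write confirmed operons
#' @param confirmed [link_operons()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confirmed <- function(confirmed, path) {
  ids <- unique(confirmed$operon_id)
  lines <- vapply(ids, function(oid) {
    g <- confirmed[confirmed$operon_id == oid, , drop = FALSE]
    g <- g[order(g$position), , drop = FALSE]
    paste(oid, paste(g$gene_id, collapse = ","), g$osp_position[1], sep = "\t")
  }, character(1))
  writeLines(c("# operon_id\tgene_ids\tosp_position", lines), path)
  invisible(path)
}

#' Write labeled pairs
#' @param pairs [label_pairs()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  writeLines(paste0("# ", paste(names(pairs), collapse = "\t")), path)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
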
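# Final stage: chain OP junctions into condition-dependent operon calls and
# verify the absence of regulatory signals in their intergenic regions.

#' Assemble the condition-dependent operon map
#'
#' Chains adjacent gene pairs whose junction status is confirmed-OP (label
#' `OP` from the confirmation stage) or voted-OP (majority vote on POP/EGP
#' pairs) into maximal operon calls. A call's status is `confirmed` when all
#' its junctions are confirmed, `putative` when all are voted, `mixed`
#' otherwise. Genes in no OP junction are not reported. Assembly is
#' order-independent: pairs are sorted genomically first.
#'
#' @param pairs Labeled pair table ([label_pairs()] output, or any table with
#'   `pair_id`, `gene_i`, `gene_j`, `strand`, `igr_start`, `igr_end`,
#'   `igr_len`, `label`).
#' @param votes Optional [vote()] data.frame with `pair_id` and
#'   `final_class` for the unlabeled-status pairs (POP/EGP).
#' @param genes Annotation data.frame (defines genomic order).
#' @return data.frame, one row per junction of each call: `call_id`,
#'   `gene_i`, `gene_j`, `strand`, `status` (call level), `provenance`
#'   (`confirmed-OP`/`voted-OP`), `pair_id`.
#' @export
assemble_map <- function(pairs, votes = NULL, genes) {
  prov <- rep(NA_character_, nrow(pairs))
  prov[pairs$label == "OP"] <- "confirmed-OP"
  if (!is.null(votes) && nrow(votes)) {
    voted_op <- votes$pair_id[votes$final_class == "OP"]
    prov[pairs$pair_id %in% voted_op & pairs$label %in% c("POP", "EGP")] <-
      "voted-OP"
  }
  keep <- !is.na(prov)
  empty <- data.frame(call_id = character(), gene_i = character(),
                      gene_j = character(), strand = character(),
                      status = character(), provenance = character(),
                      pair_id = character(), stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  jp <- pairs[keep, , drop = FALSE]
  jp$provenance <- prov[keep]
  ord <- order(match(jp$gene_i, genes$gene_id[order(genes$start)]))
  jp <- jp[ord, , drop = FALSE]
  # maximal chains: consecutive junctions share the middle gene
  n <- nrow(jp)
  new_chain <- c(TRUE, jp$gene_i[-1] != jp$gene_j[-n])
  chain <- cumsum(new_chain)
  jp$call_id <- sprintf("OPN%04d", chain)
  status <- vapply(split(jp$provenance, chain), function(pv) {
    if (all(pv == "confirmed-OP")) "confirmed"
    else if (all(pv == "voted-OP")) "putative"
    else "mixed"
  }, character(1))
  jp$status <- status[as.character(chain)]
  rownames(jp) <- NULL
  jp[, c("call_id", "gene_i", "gene_j", "strand", "status", "provenance",
         "pair_id")]
}

#' Gene lists of assembled operon calls
#' @param map [assemble_map()] output.
#' @return data.frame `call_id`, `genes` (comma-joined, genomic order),
#'   `n_genes`, `strand`, `status`.
#' @export
map_calls <- function(map) {
  if (nrow(map) == 0L)
    return(data.frame(call_id = character(), genes = character(),
                      n_genes = integer(), strand = character(),
                      status = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(map, map$call_id), function(m) {
    data.frame(call_id = m$call_id[1],
               genes = paste(c(m$gene_i, m$gene_j[nrow(m)]), collapse = ","),
               n_genes = nrow(m) + 1L, strand = m$strand[1],
               status = m$status[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$call_id), , drop = FALSE]
}

#' Check operon junctions for promoter/terminator signals
#'
#' A junction is flagged when any predicted signal interval overlaps its
#' intergenic region by at least 1 bp; stranded signals must match the
#' operon strand, unstranded signals (`"*"`) match both. Flanking regions of
#' the operon are not checked. Flagged junctions stay in the map; the
#' summary reports, per signal source, the percentage of OP junctions with
#' no overlapping signal.
#'
#' @param map [assemble_map()] output.
#' @param signals Signal data.frame ([read_signals()]).
#' @param pairs Pair table supplying IGR coordinates for the map's pair ids.
#' @return List with `map` (input plus a logical `signal_clean` column and
#'   one `clean_<source>` column per source) and `summary` (data.frame
#'   `source`, `n_junctions`, `n_clean`, `pct_clean`).
#' @export
check_signals <- function(map, signals, pairs) {
  sources <- unique(signals$source)
  igr <- pairs[match(map$pair_id, pairs$pair_id), , drop = FALSE]
  overlaps_src <- function(src) {
    sg <- signals[signals$source == src, , drop = FALSE]
    if (nrow(map) == 0L || nrow(sg) == 0L) return(rep(FALSE, nrow(map)))
    has_igr <- igr$igr_len > 0L
    q <- IRanges::IRanges(ifelse(has_igr, igr$igr_start, 1L),
                          ifelse(has_igr, igr$igr_end, 0L))
    s <- IRanges::IRanges(sg$start, sg$end)
    hits <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    ok_strand <- sg$strand[S4Vectors::subjectHits(hits)] == "*" |
                 sg$strand[S4Vectors::subjectHits(hits)] ==
                   map$strand[S4Vectors::queryHits(hits)]
    flagged <- rep(FALSE, nrow(map))
    flagged[unique(S4Vectors::queryHits(hits)[ok_strand])] <- TRUE
    flagged
  }
  flags <- lapply(stats::setNames(sources, sources), overlaps_src)
  any_flag <- if (length(flags)) Reduce(`|`, flags) else rep(FALSE, nrow(map))
  map$signal_clean <- !any_flag
  for (src in sources) map[[paste0("clean_", src)]] <- !flags[[src]]
  summary <- data.frame(
    source = sources,
    n_junctions = rep(nrow(map), length(sources)),
    n_clean = vapply(sources, function(s) sum(!flags[[s]]), integer(1)),
    stringsAsFactors = FALSE)
  summary$pct_clean <- if (nrow(map)) 100 * summary$n_clean / nrow(map)
                       else rep(100, length(sources))
  rownames(summary) <- NULL
  list(map = map, summary = summary)
}

#' Summarize a condition-dependent operon map
#'
#' @param map [assemble_map()] output.
#' @param pairs Labeled pair table (defines the universe of same-strand
#'   adjacent pairs for the percentages).
#' @return List of counts: `confirmed_junctions`, `putative_junctions`,
#'   `total_junctions`, `n_operons`, and the corresponding percentages over
#'   all same-strand adjacent pairs.
#' @export
summarize_map <- function(map, pairs) {
  n_pairs <- nrow(pairs)
  conf <- sum(map$provenance == "confirmed-OP")
  put <- sum(map$provenance == "voted-OP")
  pct <- function(x) if (n_pairs > 0) 100 * x / n_pairs else NaN
  list(confirmed_junctions = conf,
       putative_junctions = put,
       total_junctions = conf + put,
       n_operons = length(unique(map$call_id)),
       pct_confirmed = pct(conf), pct_putative = pct(put),
       pct_total = pct(conf + put))
}

#' Write an operon map
#' @param map [assemble_map()] output (possibly signal-annotated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  writeLines(paste0("# ", paste(names(map), collapse = "\t")), path)
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
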
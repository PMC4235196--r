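# The four per-pair features: intergenic distance, codon-usage similarity,
# expression difference, intergenic expression.

sense_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]                       # 61 sense codons, named by codon
}

#' Intergenic distance between two adjacent genes
#'
#' Number of base pairs separating two consecutive same-strand genes:
#' `start_j - end_i - 1` with gene i upstream in genomic order. Negative for
#' co-directionally overlapping genes. (Some printed statements of this
#' quantity sum the coordinates instead; that cannot be a distance and is not
#' followed here.)
#'
#' @param gene_i,gene_j Single-row gene data.frames (or lists) with `start`,
#'   `end`, `strand`; `gene_i` upstream in genomic order.
#' @return Integer distance in nt.
#' @export
igr_length <- function(gene_i, gene_j) {
  if (gene_i$strand != gene_j$strand) stopf("igr_length needs same-strand genes")
  if (gene_j$start <= gene_i$start) stopf("gene_i must be upstream of gene_j in genomic order")
  as.integer(gene_j$start - gene_i$end - 1L)
}

#' Relative synonymous codon usage vector of a coding sequence
#'
#' For codon c encoding amino acid a: `RSCU_c = n_c * k_a / n_a` where `n_c`
#' is the count of c in the CDS, `n_a` the total count over a's synonymous
#' codons and `k_a` the family size. Stop codons are excluded (a terminal
#' stop is ignored silently; internal stops are skipped with a warning, as
#' are codons containing non-ACGT bases). Codons of amino acids absent from
#' the gene get RSCU 0 by convention, so every vector is total over the 61
#' sense codons of the standard code.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Named numeric vector of length 61 (sense codons, alphabetical).
#' @export
rscu_vector <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stopf("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  tab <- sense_codon_table()
  bad <- !codons %in% names(Biostrings::GENETIC_CODE)
  if (any(bad)) {
    warnf("%d codon(s) with ambiguous bases skipped", sum(bad))
    codons <- codons[!bad]
  }
  is_stop <- Biostrings::GENETIC_CODE[codons] == "*"
  if (any(is_stop)) {
    internal <- is_stop & seq_along(codons) < length(codons)
    if (any(internal)) warnf("%d internal stop codon(s) skipped", sum(internal))
    codons <- codons[!is_stop]
  }
  counts <- table(factor(codons, levels = names(tab)))
  aa <- factor(unname(tab), levels = unique(unname(tab)))
  n_a <- tapply(as.numeric(counts), aa, sum)[aa]
  k_a <- tapply(rep(1, length(tab)), aa, sum)[aa]
  rscu <- ifelse(n_a > 0, as.numeric(counts) * k_a / n_a, 0)
  stats::setNames(as.numeric(rscu), names(tab))
}

#' Codon usage similarity of two genes
#'
#' Inner product of the two RSCU vectors. At the default `level = "codon"`
#' the sum runs over the 61 sense codons; `level = "amino_acid"` first
#' averages RSCU within each synonymous family and sums the 20 products.
#' Symmetric in its arguments.
#'
#' @param u,v RSCU vectors from [rscu_vector()].
#' @param level Summation index, `"codon"` (default) or `"amino_acid"`.
#' @return Non-negative similarity score.
#' @export
cu_score <- function(u, v, level = c("codon", "amino_acid")) {
  level <- match.arg(level)
  stopifnot(length(u) == length(v))
  if (level == "codon") return(sum(u * v))
  aa <- unname(sense_codon_table())
  sum(tapply(u, aa, mean) * tapply(v, aa, mean))
}

#' Absolute difference in log2 expression of two genes
#' @param e_i,e_j Expression records (rows of the [compute_rpkm()] output).
#' @return `|log2_rpkm_i - log2_rpkm_j|`.
#' @export
diff_expr <- function(e_i, e_j) abs(e_i$log2_rpkm - e_j$log2_rpkm)

#' Expression level of the intergenic region of a pair
#'
#' Returns the IGR's log2(RPKM+1). When the genes abut or overlap there is no
#' region to measure; the fallback is the smaller of the two gene expression
#' values (a co-transcribed overlapping pair behaves like a maximally
#' expressed IGR relative to its genes).
#'
#' @param pair Single-row adjacent-pair data.frame with `pair_id`, `gene_i`,
#'   `gene_j`, `igr_len`.
#' @param expression Expression table from [compute_rpkm()] containing CDS
#'   records for both genes and, when `igr_len > 0`, an IGR record with
#'   `feature_id` equal to the pair id.
#' @return The IGR log2 expression value.
#' @export
igr_expr <- function(pair, expression) {
  if (pair$igr_len > 0L) {
    hit <- expression$feature_id == pair$pair_id & expression$kind == "IGR"
    if (!any(hit)) stopf("missing IGR expression record for pair %s", pair$pair_id)
    return(expression$log2_rpkm[which(hit)[1]])
  }
  gi <- expression$log2_rpkm[expression$feature_id == pair$gene_i &
                             expression$kind == "CDS"]
  gj <- expression$log2_rpkm[expression$feature_id == pair$gene_j &
                             expression$kind == "CDS"]
  if (!length(gi) || !length(gj))
    stopf("missing CDS expression for pair %s", pair$pair_id)
  min(gi[1], gj[1])
}

#' Build the per-pair feature table
#'
#' One row per adjacent same-strand gene pair with its label and the four
#' features. Pairs whose CDS sequence is missing are dropped with a warning.
#' Row order is genomic, so the table is deterministic for fixed inputs.
#'
#' @param pairs Labeled adjacent pairs ([label_pairs()]).
#' @param genes Annotation data.frame.
#' @param expression Expression table ([compute_rpkm()]) with CDS and IGR
#'   records.
#' @param cds Named character vector of CDS sequences keyed by gene id.
#' @return data.frame `pair_id`, `gene_i`, `gene_j`, `strand`, `label`,
#'   `igr_length`, `cu_score`, `diff_expr`, `igr_expr`.
#' @export
build_feature_table <- function(pairs, genes, expression, cds) {
  cols <- c("pair_id", "gene_i", "gene_j", "strand", "label",
            "igr_length", "cu_score", "diff_expr", "igr_expr")
  if (nrow(pairs) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(replicate(5, character(), simplify = FALSE),
        list(integer()), replicate(3, numeric(), simplify = FALSE)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  have_cds <- pairs$gene_i %in% names(cds) & pairs$gene_j %in% names(cds)
  if (any(!have_cds))
    warnf("%d pair(s) dropped: missing CDS sequence", sum(!have_cds))
  pairs <- pairs[have_cds, , drop = FALSE]
  rscu_cache <- new.env(parent = emptyenv())
  get_rscu <- function(g) {
    if (!exists(g, envir = rscu_cache, inherits = FALSE))
      rscu_cache[[g]] <- rscu_vector(cds[[g]])
    rscu_cache[[g]]
  }
  e_cds <- expression[expression$kind == "CDS", , drop = FALSE]
  exp_of <- stats::setNames(e_cds$log2_rpkm, e_cds$feature_id)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs[k, ]
    data.frame(pair_id = p$pair_id, gene_i = p$gene_i, gene_j = p$gene_j,
               strand = p$strand, label = p$label,
               igr_length = p$igr_len,
               cu_score = cu_score(get_rscu(p$gene_i), get_rscu(p$gene_j)),
               diff_expr = abs(exp_of[[p$gene_i]] - exp_of[[p$gene_j]]),
               igr_expr = igr_expr(p, expression),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table
#' @param table Feature table from [build_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  writeLines(paste0("# ", paste(names(table), collapse = "\t")), path)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
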
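#' Read gene annotation from a GFF3 file
#'
#' Parses a GFF3 file and returns the gene-level annotation used throughout the
#' pipeline. Coordinates are kept in the GFF convention (1-based, inclusive),
#' which is also the package-internal convention. Only single-replicon genomes
#' are supported; multi-chromosome input is rejected.
#'
#' @param path Path to a GFF3 file. Features of type `gene` or `CDS` are used;
#'   each must carry a unique `ID` (or `locus_tag`) attribute.
#' @return A data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   sorted by `start`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
#'   "chr\tsrc\tgene\t151\t300\t.\t+\t.\tID=gB"), gff)
#' read_annotation(gff)
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("failed to parse GFF3 '%s': %s",
                                           path, conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  seqn <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(seqn) > 1L)
    stopf("multi-replicon annotation not supported (found seqnames: %s)",
          paste(seqn, collapse = ", "))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    lt <- gr$locus_tag
    if (!is.null(lt)) ids <- ifelse(is.na(ids %||% NA), lt, ids)
  }
  if (is.null(ids) || anyNA(ids)) stopf("GFF3 features without an ID attribute")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stopf("GFF3 feature(s) missing strand: %s",
                                paste(ids[strand == "*"], collapse = ", "))
  # keep one record per ID (gene + its CDS share an ID in some dialects)
  keep <- !duplicated(paste(ids, BiocGenerics::start(gr), BiocGenerics::end(gr)))
  genes <- data.frame(gene_id = as.character(ids)[keep],
                      start = BiocGenerics::start(gr)[keep],
                      end = BiocGenerics::end(gr)[keep],
                      strand = strand[keep],
                      stringsAsFactors = FALSE)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stopf("duplicated gene ID(s): %s",
                         paste(unique(dup), collapse = ", "))
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene annotation to GFF3
#'
#' @param genes Annotation data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @param seqname Sequence (replicon) name to write, default `"chr"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(seqname,
          IRanges::IRanges(genes$start, genes$end),
          strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a reference operon table
#'
#' Reads a minimal two-column projection of a DOOR-style operon table:
#' `operon_id TAB comma-separated gene ids`, one operon per row, gene ids in
#' transcription order. Lines starting with `#` are ignored. Rows with a
#' single gene are dropped with a warning (an operon pair needs two genes);
#' rows whose genes mix strands or are unknown to the annotation are errors.
#' A converter from the full DOOR flat file only needs to project its operon
#' id and gene synonym columns into this layout.
#'
#' @param path Path to the tab-delimited table.
#' @param genes Annotation data.frame ([read_annotation()]).
#' @return A long-format data.frame with columns `operon_id`, `gene_id`,
#'   `position` (1-based rank of the gene inside the operon, in transcription
#'   order).
#' @export
read_operon_table <- function(path, genes) {
  if (!file.exists(path)) stopf("operon table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  seen_gene <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) stopf("operon table line %d: expected 2 tab fields", i)
    gids <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    gids <- gids[nzchar(gids)]
    unknown <- setdiff(gids, genes$gene_id)
    if (length(unknown)) stopf("operon '%s' references unknown gene id(s): %s",
                               f[1], paste(unknown, collapse = ", "))
    if (length(gids) < 2L) {
      warnf("operon '%s' has fewer than 2 genes; row dropped", f[1])
      next
    }
    st <- genes$strand[match(gids, genes$gene_id)]
    if (length(unique(st)) > 1L) stopf("operon '%s' mixes strands", f[1])
    reused <- intersect(gids, seen_gene)
    if (length(reused)) stopf("gene id(s) in more than one operon: %s",
                              paste(reused, collapse = ", "))
    seen_gene <- c(seen_gene, gids)
    out[[i]] <- data.frame(operon_id = f[1], gene_id = gids,
                           position = seq_along(gids),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(operon_id = character(),
                                      gene_id = character(),
                                      position = integer(),
                                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a reference operon table
#' @param operons Long-format operon data.frame ([read_operon_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operon_table <- function(operons, path) {
  ids <- unique(operons$operon_id)
  lines <- vapply(ids, function(oid) {
    g <- operons[operons$operon_id == oid, , drop = FALSE]
    g <- g[order(g$position), , drop = FALSE]
    paste0(oid, "\t", paste(g$gene_id, collapse = ","))
  }, character(1))
  writeLines(c("# operon_id\tgene_ids", lines), path)
  invisible(path)
}

#' Read a per-base coverage track
#'
#' Accepts either a samtools-style pileup (first four columns: reference name,
#' 1-based position, reference base, depth) or a headerless 2-column
#' position/depth table; a 3-column position/depth/strand table is read as a
#' strand-specific track. Positions absent from the file get depth 0.
#'
#' @param path Coverage file.
#' @param genome_length Genome length in nt; all positions must lie in
#'   `[1, genome_length]`.
#' @param read_length Read length in nt used for RPKM read-count estimation.
#' @return A `coverage_track` object; see [coverage_track()].
#' @export
read_coverage <- function(path, genome_length, read_length = 50L) {
  if (!file.exists(path)) stopf("coverage file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    return(coverage_track(numeric(genome_length), read_length = read_length))
  nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = if (nf >= 4L)
                             c("character", "integer", "character", "numeric",
                               rep("NULL", nf - 4L))
                           else NA)
  if (nf >= 4L) {            # pileup: ref pos base depth ...
    pos <- tab[[2]]; depth <- tab[[4]]; strand <- NULL
  } else if (nf == 2L) {     # position depth
    pos <- tab[[1]]; depth <- tab[[2]]; strand <- NULL
  } else if (nf == 3L) {     # position depth strand
    pos <- tab[[1]]; depth <- tab[[2]]; strand <- as.character(tab[[3]])
    assert_strand(strand)
  } else stopf("unrecognized coverage format in %s", path)
  if (any(pos < 1L | pos > genome_length))
    stopf("coverage position out of range [1, %d]", genome_length)
  if (any(depth < 0)) stopf("negative coverage depth at position %d",
                            pos[which(depth < 0)[1]])
  if (is.null(strand)) {
    d <- numeric(genome_length)
    d[pos] <- d[pos] + depth    # pileup rows are unique per pos; += is safe
    coverage_track(d, read_length = read_length)
  } else {
    dp <- numeric(genome_length); dm <- numeric(genome_length)
    ip <- strand == "+"
    dp[pos[ip]] <- dp[pos[ip]] + depth[ip]
    dm[pos[!ip]] <- dm[pos[!ip]] + depth[!ip]
    coverage_track(dp + dm, strand_depth = list(`+` = dp, `-` = dm),
                   read_length = read_length)
  }
}

#' Write a coverage track as a position/depth table
#'
#' Zero-depth positions are omitted; stranded tracks are written as
#' position/depth/strand.
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  if (is.null(track$strand_depth)) {
    nz <- which(track$depth > 0)
    utils::write.table(data.frame(nz, track$depth[nz]), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(c("+", "-"), function(s) {
      d <- track$strand_depth[[s]]
      nz <- which(d > 0)
      if (!length(nz)) return(NULL)
      data.frame(pos = nz, depth = d[nz], strand = s)
    }))
    rows <- rows[order(rows$pos, rows$strand), , drop = FALSE]
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read promoter/terminator intervals from BED
#'
#' BED intervals (0-based, half-open) are converted to the internal 1-based
#' inclusive convention. The BED name field is used as the signal source tag
#' (e.g. `pp`, `pt`, `tt` for different predictors); names of the form
#' `source:kind` split into source and kind, otherwise the kind is guessed
#' from the name (`term`/`tt` implies terminator, anything else promoter).
#'
#' @param path BED file.
#' @return data.frame with columns `kind`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `"*"` for unstranded), `source`.
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stopf("signal BED not found: %s", path)
  empty <- data.frame(kind = character(), start = integer(), end = integer(),
                      strand = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) return(empty)
  if (any(BiocGenerics::width(gr) < 1L)) stopf("BED interval with end <= start")
  nm <- gr$name %||% rep("signal", length(gr))
  nm[is.na(nm)] <- "signal"
  has_kind <- grepl(":", nm, fixed = TRUE)
  source <- ifelse(has_kind, sub(":.*$", "", nm), nm)
  kind_raw <- ifelse(has_kind, sub("^.*:", "", nm), nm)
  kind <- ifelse(grepl("term|^tt", kind_raw, ignore.case = TRUE),
                 "terminator", "promoter")
  data.frame(kind = kind,
             start = BiocGenerics::start(gr),  # rtracklayer yields 1-based
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             source = source,
             stringsAsFactors = FALSE)
}

#' Write signal intervals to BED
#' @param signals data.frame as from [read_signals()].
#' @param path Output path.
#' @param seqname Sequence name, default `"chr"`.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path, seqname = "chr") {
  if (nrow(signals) == 0L) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(seqname,
          IRanges::IRanges(signals$start, signals$end),
          strand = signals$strand)
  gr$name <- paste(signals$source, signals$kind, sep = ":")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read CDS sequences from FASTA, keyed by gene id
#'
#' @param path FASTA file whose record names are gene ids (first whitespace
#'   token).
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_cds <- function(path) {
  if (!file.exists(path)) stopf("CDS FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write CDS sequences to FASTA
#' @param cds Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path, width = 70L)
  invisible(path)
}
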
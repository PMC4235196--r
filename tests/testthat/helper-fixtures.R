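# Small constructed fixtures shared across tests. Everything is built in
# code; no data files.

# three-gene plus-strand operon with one downstream singleton, plateau
# covering the operon, clean background elsewhere
fixture_operon <- function(depth_high = 100, genome_length = 5000L) {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    start = c(501L, 951L, 1401L, 3001L),
    end = c(800L, 1250L, 1700L, 3300L),
    strand = "+",
    stringsAsFactors = FALSE)
  depth <- rep(0, genome_length)
  depth[451:1760] <- depth_high          # TU: 50 nt 5'UTR, 60 nt 3'UTR
  depth[2951:3360] <- depth_high         # singleton TU for gD
  track <- coverage_track(depth)
  ref <- data.frame(operon_id = "op1", gene_id = c("gA", "gB", "gC"),
                    position = 1:3, stringsAsFactors = FALSE)
  list(genes = genes, track = track, ref = ref)
}

fixture_expression <- function(fx) {
  pairs <- adjacent_pairs(fx$genes)
  intervals <- rbind(
    data.frame(feature_id = fx$genes$gene_id, kind = "CDS",
               start = fx$genes$start, end = fx$genes$end,
               stringsAsFactors = FALSE),
    data.frame(feature_id = pairs$pair_id[pairs$igr_len > 0], kind = "IGR",
               start = pairs$igr_start[pairs$igr_len > 0],
               end = pairs$igr_end[pairs$igr_len > 0],
               stringsAsFactors = FALSE))
  compute_rpkm(fx$track, intervals)
}
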
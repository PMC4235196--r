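# End-to-end orchestration: coverage -> confirmation -> features ->
# classification/voting -> map, with every intermediate written as TSV and a
# run manifest recording versions, seeds and parameters.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every source of randomness.
#' @param gff,cds_fasta,coverage,operon_table,signals_bed Input paths
#'   (`signals_bed` optional). Leave `NULL` and set `simulate = TRUE` to run
#'   on a simulated dataset instead.
#' @param genome_length Genome length (required with file inputs).
#' @param simulate Simulate the inputs with [simulate_transcriptome()].
#' @param sim Optional [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param condition Simulated condition index.
#' @param detector [detector_config()].
#' @param train [train_config()] (its seed is overridden by `seed`).
#' @param percentile Expression-threshold percentile (default 10).
#' @param first_gene_only Restrict operon start anchoring to first structural
#'   genes.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("operomap_run_"), seed = 1L,
                       gff = NULL, cds_fasta = NULL, coverage = NULL,
                       operon_table = NULL, signals_bed = NULL,
                       genome_length = NULL,
                       simulate = is.null(gff), sim = NULL, condition = 1L,
                       detector = detector_config(), train = train_config(),
                       percentile = 10, first_gene_only = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full operon-prediction pipeline
#'
#' Executes the five stages — coverage analysis (breakpoints, RPKM,
#' thresholds), operon confirmation and pair labelling, feature extraction,
#' three-classifier training with majority voting on uncertain pairs, and
#' map assembly with optional signal verification — writing every
#' intermediate table plus a `manifest.yaml` into `config$out_dir`.
#'
#' @param config A [run_config()], or a path to a YAML file whose keys match
#'   [run_config()] arguments.
#' @return Invisibly, a list with all intermediate objects (`sim`, `genes`,
#'   `track`, `breakpoints`, `expression`, `thresholds`, `osp`, `confirmed`,
#'   `pairs`, `features`, `votes`, `map`, `signal_check`, `summary`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    keys <- yaml::read_yaml(config)
    config <- do.call(run_config, keys)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  manifest <- list(package = "operomap",
                   version = as.character(utils::packageVersion("operomap")),
                   seed = config$seed,
                   parameters = list(
                     detector = unclass(config$detector)[
                       setdiff(names(config$detector), "template")],
                     percentile = config$percentile,
                     first_gene_only = config$first_gene_only,
                     train = unclass(config$train)))

  ## stage 1: inputs
  if (isTRUE(config$simulate)) {
    sim_cfg <- config$sim %||% sim_config(seed = config$seed)
    sim <- simulate_transcriptome(sim_cfg, condition = config$condition)
    genes <- sim$genes; cds <- sim$cds; track <- sim$track
    ref_operons <- sim$ref_operons
    signals <- NULL
    write_simulation(sim, file.path(config$out_dir, "inputs"))
    manifest$parameters$sim <- unclass(sim_cfg)
    manifest$condition <- config$condition
  } else {
    for (f in c("gff", "cds_fasta", "coverage", "operon_table")) {
      if (is.null(config[[f]])) stopf("input path '%s' is required", f)
      if (!file.exists(config[[f]])) stopf("input file not found: %s", config[[f]])
    }
    if (is.null(config$genome_length))
      stopf("genome_length is required with file inputs")
    sim <- NULL
    genes <- read_annotation(config$gff)
    cds <- read_cds(config$cds_fasta)
    track <- read_coverage(config$coverage, config$genome_length)
    ref_operons <- read_operon_table(config$operon_table, genes)
    signals <- if (!is.null(config$signals_bed)) read_signals(config$signals_bed)
  }
  stages <- c(stages, "inputs")

  ## stage 2: breakpoints + expression
  breakpoints <- detect_breakpoints(track, config$detector)
  pairs0 <- adjacent_pairs(genes)
  intervals <- rbind(
    data.frame(feature_id = genes$gene_id, kind = "CDS", start = genes$start,
               end = genes$end, strand = genes$strand,
               stringsAsFactors = FALSE),
    igr_intervals(pairs0))
  expression <- compute_rpkm(track, intervals)
  thresholds <- expression_thresholds(expression, config$percentile)
  write_breakpoints(breakpoints, file.path(config$out_dir, "breakpoints.tsv"))
  write_expression(expression, file.path(config$out_dir, "expression.tsv"))
  stages <- c(stages, "coverage")

  ## stage 3: confirmation + labels
  osp <- select_osp(breakpoints, expression, genes, ref_operons, thresholds,
                    config$detector, config$first_gene_only)
  oep <- select_oep(breakpoints, expression, genes, ref_operons, thresholds,
                    config$detector)
  confirmed <- link_operons(osp, genes, ref_operons, expression, breakpoints,
                            thresholds)
  pairs <- label_pairs(genes, confirmed, ref_operons, breakpoints, expression,
                       thresholds)
  write_confirmed(confirmed, file.path(config$out_dir, "confirmed_operons.tsv"))
  write_pairs(pairs, file.path(config$out_dir, "labeled_pairs.tsv"))
  stages <- c(stages, "confirm")

  ## stage 4: features + classifiers + vote
  features <- build_feature_table(pairs, genes, expression, cds)
  write_feature_table(features, file.path(config$out_dir, "features.tsv"))
  train_tbl <- features[features$label %in% c("OP", "NOP"), , drop = FALSE]
  uncertain <- features[features$label %in% c("POP", "EGP"), , drop = FALSE]
  cfg_t <- config$train
  cfg_t$seed <- config$seed
  vp <- vote_predictions(train_tbl, uncertain, cfg_t)
  utils::write.table(vp$votes, file.path(config$out_dir, "votes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "classify")

  ## stage 5: map assembly + signals
  map <- assemble_map(pairs, vp$votes, genes)
  signal_check <- NULL
  if (!is.null(signals) && nrow(signals)) {
    signal_check <- check_signals(map, signals, pairs)
    map <- signal_check$map
    utils::write.table(signal_check$summary,
                       file.path(config$out_dir, "signal_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_map(map, file.path(config$out_dir, "operon_map.tsv"))
  summary <- summarize_map(map, pairs)
  yaml::write_yaml(summary, file.path(config$out_dir, "map_summary.yaml"))
  stages <- c(stages, "map")

  manifest$stages_completed <- stages
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(sim = sim, genes = genes, cds = cds, track = track,
                 ref_operons = ref_operons, breakpoints = breakpoints,
                 expression = expression, thresholds = thresholds,
                 osp = osp, oep = oep, confirmed = confirmed, pairs = pairs,
                 features = features, models = vp$models, votes = vp$votes,
                 map = map, signal_check = signal_check, summary = summary,
                 manifest = manifest, out_dir = config$out_dir))
}
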
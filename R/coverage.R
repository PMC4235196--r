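#' Construct a per-base coverage track
#'
#' The track stores read depth at every genomic position (1-based). For
#' strand-specific libraries the per-strand arrays are kept alongside the
#' combined track; detection and expression then run per strand.
#'
#' @param depth Numeric vector of per-base depth (combined track).
#' @param strand_depth Optional named list `list("+" = ..., "-" = ...)` of
#'   per-strand depth vectors summing to `depth`.
#' @param read_length Read length in nt (default 50), used to convert summed
#'   depth into estimated read counts for RPKM.
#' @return An object of class `coverage_track` with fields `depth`,
#'   `strand_depth`, `genome_length`, `read_length`, `total_mapped_bases`.
#' @export
coverage_track <- function(depth, strand_depth = NULL, read_length = 50L) {
  if (any(depth < 0)) stopf("coverage depth must be non-negative")
  if (!is.null(strand_depth)) {
    stopifnot(setequal(names(strand_depth), c("+", "-")),
              length(strand_depth[["+"]]) == length(depth),
              length(strand_depth[["-"]]) == length(depth))
  }
  structure(list(depth = as.numeric(depth),
                 strand_depth = strand_depth,
                 genome_length = length(depth),
                 read_length = as.integer(read_length),
                 total_mapped_bases = sum(depth)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d nt, %.0f mapped bases (%sstranded), read length %d\n",
              x$genome_length, x$total_mapped_bases,
              if (is.null(x$strand_depth)) "un" else "", x$read_length))
  invisible(x)
}

#' Detector configuration
#'
#' The breakpoint detector slides a fixed window along the depth profile and
#' correlates each window with a step-shaped template of zeros followed by
#' ones. Windows whose Pearson correlation exceeds the threshold with a
#' significant two-sided test p-value are candidate transcription start
#' (positive r) or end (negative r) points.
#'
#' @param window_length Window length in nt; must be even (default 100, i.e.
#'   a template of 50 zeros and 50 ones).
#' @param r_threshold Absolute correlation threshold (default 0.7).
#' @param p_threshold Correlation-test significance level (default 1e-7).
#' @param fold_change_min Minimum depth fold change between the window halves
#'   used downstream when anchoring operon start/end points (default 2).
#' @param max_utr Maximum allowed 5'/3' UTR length in nt between a breakpoint
#'   and the anchored gene (default 300).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(window_length = 100L, r_threshold = 0.7,
                            p_threshold = 1e-7, fold_change_min = 2,
                            max_utr = 300L) {
  window_length <- as.integer(window_length)
  if (window_length < 4L || window_length %% 2L != 0L)
    stopf("window_length must be an even integer >= 4")
  if (r_threshold <= 0 || r_threshold >= 1) stopf("r_threshold must be in (0,1)")
  structure(list(window_length = window_length,
                 template = rep(c(0, 1), each = window_length / 2L),
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 fold_change_min = fold_change_min,
                 max_utr = as.integer(max_utr)),
            class = "detector_config")
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the t statistic `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom; `|r| = 1` maps to p = 0.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of paired observations (window length); must be >= 3.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3L)) stopf("correlation test needs n >= 3")
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# windowed Pearson r against the half-zero/half-one template, all offsets,
# via cumulative sums; returns NA where the depth segment has zero variance
window_correlations <- function(depth, w) {
  n <- length(depth)
  h <- w %/% 2L
  if (n < w) stopf("window (%d nt) longer than genome (%d nt)", w, n)
  cs <- c(0, cumsum(depth))
  cs2 <- c(0, cumsum(depth^2))
  starts <- seq_len(n - w + 1L)
  sum_w <- cs[starts + w] - cs[starts]
  sum_r <- cs[starts + w] - cs[starts + h]
  sum_l <- sum_w - sum_r
  sxx <- cs2[starts + w] - cs2[starts] - sum_w^2 / w
  sxy <- (sum_r - sum_l) / 2
  syy <- w / 4                       # template sum of squares about its mean
  r <- rep(NA_real_, length(starts))
  pos_var <- sxx > 1e-12
  r[pos_var] <- sxy[pos_var] / sqrt(sxx[pos_var] * syy)
  r <- pmin(1, pmax(-1, r))
  list(starts = starts, r = r, mean_left = sum_l / h, mean_right = sum_r / h)
}

detect_breakpoints_one <- function(depth, cfg, strand) {
  w <- cfg$window_length
  h <- w %/% 2L
  wc <- window_correlations(depth, w)
  p <- correlation_pvalue(wc$r, w)
  sig <- !is.na(wc$r) & abs(wc$r) > cfg$r_threshold & p < cfg$p_threshold
  idx <- which(sig)
  empty <- data.frame(position = integer(), kind = character(), r = numeric(),
                      p_value = numeric(), fold_change = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  sgn <- sign(wc$r[idx])
  # maximal runs of adjacent significant windows with the same sign
  brk <- c(TRUE, diff(idx) > 1L | diff(sgn) != 0)
  run <- cumsum(brk)
  picked <- vapply(split(seq_along(idx), run), function(ii) {
    jj <- idx[ii]
    jj[which.max(abs(wc$r[jj]))]   # which.max is leftmost on ties
  }, integer(1))
  r <- wc$r[picked]
  ml <- wc$mean_left[picked]
  mr <- wc$mean_right[picked]
  inc <- r > 0
  # localize the change point inside the selected window by the CUSUM
  # statistic: exact on a clean step and stable under counting noise. The
  # reported base is on the transcribed side: first base of the plateau for
  # increases, last base for decreases.
  position <- vapply(seq_along(picked), function(i) {
    s <- wc$starts[picked[i]]
    seg <- depth[s:(s + w - 1L)]
    cs <- cumsum(seg - mean(seg))
    if (inc[i]) s + which.min(cs) else s + which.max(cs) - 1L
  }, numeric(1))
  data.frame(position = as.integer(position),
             kind = ifelse(inc, "increase", "decrease"),
             r = r,
             p_value = correlation_pvalue(r, w),
             fold_change = ifelse(inc, (mr + 1) / (ml + 1), (ml + 1) / (mr + 1)),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Detect transcription breakpoints by sliding-window correlation
#'
#' Slides a `window_length` window (stride 1 nt) along the depth profile and
#' computes the Pearson correlation of each depth segment against the step
#' template. Significant positively correlated windows mark sharp coverage
#' increases (transcription-start-like points), negatively correlated windows
#' sharp decreases (transcription-end-like points). Overlapping or adjacent
#' significant windows of the same sign are merged into one run and the
#' center point of the run's strongest window (maximal `|r|`, leftmost on
#' ties) is reported. Zero-variance windows are skipped. For stranded tracks
#' detection runs per strand.
#'
#' @param track A [coverage_track()].
#' @param cfg A [detector_config()].
#' @return data.frame with columns `position`, `kind` (`increase`/`decrease`),
#'   `r`, `p_value`, `fold_change` (mean depth of the rising half + 1 over the
#'   falling half + 1), `strand` (`"*"` for unstranded tracks).
#' @export
detect_breakpoints <- function(track, cfg = detector_config()) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(track$strand_depth)) {
    bp <- detect_breakpoints_one(track$depth, cfg, "*")
  } else {
    bp <- rbind(detect_breakpoints_one(track$strand_depth[["+"]], cfg, "+"),
                detect_breakpoints_one(track$strand_depth[["-"]], cfg, "-"))
  }
  bp <- bp[order(bp$position), , drop = FALSE]
  rownames(bp) <- NULL
  bp
}

#' Compute RPKM expression for genomic intervals
#'
#' The estimated read count of an interval is the summed depth over the
#' interval divided by the read length; the library size is the total mapped
#' bases divided by the read length. `RPKM = C / ((L/1000) * (N/1e6))` with
#' interval length L in nt; `log2_rpkm = log2(RPKM + 1)`.
#'
#' @param track A [coverage_track()].
#' @param intervals data.frame with columns `feature_id`, `kind`
#'   (`"CDS"`/`"IGR"`), `start`, `end` and optionally `strand` (used when the
#'   track is stranded).
#' @return data.frame `feature_id`, `kind`, `start`, `end`, `rpkm`,
#'   `log2_rpkm`.
#' @export
compute_rpkm <- function(track, intervals) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$total_mapped_bases <= 0) stopf("empty library: no mapped bases")
  if (nrow(intervals) == 0L)
    return(cbind(intervals[, c("feature_id", "kind", "start", "end")],
                 rpkm = numeric(0), log2_rpkm = numeric(0)))
  if (any(intervals$start < 1L | intervals$end > track$genome_length |
          intervals$end < intervals$start))
    stopf("interval outside genome or with end < start")
  n_reads <- track$total_mapped_bases / track$read_length
  use_strand <- !is.null(track$strand_depth) && "strand" %in% names(intervals)
  sum_depth <- function(d) {
    cs <- c(0, cumsum(d))
    cs[intervals$end + 1L] - cs[intervals$start]
  }
  if (use_strand) {
    sp <- sum_depth(track$strand_depth[["+"]])
    sm <- sum_depth(track$strand_depth[["-"]])
    s <- ifelse(intervals$strand == "-", sm, sp)
  } else {
    s <- sum_depth(track$depth)
  }
  len <- intervals$end - intervals$start + 1L
  counts <- s / track$read_length
  rpkm <- counts / ((len / 1000) * (n_reads / 1e6))
  data.frame(feature_id = intervals$feature_id, kind = intervals$kind,
             start = intervals$start, end = intervals$end,
             rpkm = rpkm, log2_rpkm = log2(rpkm + 1),
             stringsAsFactors = FALSE)
}

#' Minimum expression thresholds for CDS and IGR features
#'
#' Returns the given percentile (default 10th) of the log2(RPKM+1)
#' distribution, computed separately over CDS and IGR records, with linear
#' interpolation between order statistics (type-7 quantile).
#'
#' @param records Expression data.frame from [compute_rpkm()].
#' @param percentile Percentile in `[0, 100]` (default 10).
#' @return Named list `cds_min`, `igr_min`.
#' @export
expression_thresholds <- function(records, percentile = 10) {
  cds <- records$log2_rpkm[records$kind == "CDS"]
  igr <- records$log2_rpkm[records$kind == "IGR"]
  if (!length(cds)) stopf("no CDS expression records")
  if (!length(igr)) stopf("no IGR expression records")
  list(cds_min = unname(stats::quantile(cds, percentile / 100, type = 7)),
       igr_min = unname(stats::quantile(igr, percentile / 100, type = 7)))
}

#' Write a breakpoint table
#' @param breakpoints data.frame from [detect_breakpoints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(breakpoints, path) {
  writeLines("# position\tkind\tr\tp_value\tfold_change\tstrand", path)
  utils::write.table(breakpoints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write an expression table
#' @param records data.frame from [compute_rpkm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(records, path) {
  writeLines("# feature_id\tkind\tstart\tend\trpkm\tlog2_rpkm", path)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
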
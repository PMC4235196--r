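# Independent brute-force oracles used to pin expected values. These are
# deliberately simple (explicit loops, base R) and share no code with the
# package internals they check.

# per-offset Pearson scan against the step template, followed by the same
# published output convention (run merge by sign, max-|r| window, CUSUM
# localization) implemented from scratch
oracle_breakpoints <- function(depth, window = 100L, r_thr = 0.7,
                               p_thr = 1e-7) {
  h <- window %/% 2L
  template <- rep(c(0, 1), each = h)
  n <- length(depth)
  offs <- seq_len(n - window + 1L)
  r <- rep(NA_real_, length(offs))
  for (i in offs) {
    seg <- depth[i:(i + window - 1L)]
    if (stats::var(seg) > 0) r[i] <- stats::cor(seg, template)
  }
  tval <- r * sqrt((window - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = window - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  sig <- which(!is.na(r) & abs(r) > r_thr & p < p_thr)
  if (!length(sig)) {
    return(data.frame(position = integer(), kind = character(), r = numeric(),
                      p_value = numeric()))
  }
  out <- list()
  run_start <- 1L
  sgn <- sign(r[sig])
  flush_run <- function(idx) {
    best <- idx[which.max(abs(r[idx]))]
    seg <- depth[best:(best + window - 1L)]
    cs <- cumsum(seg - mean(seg))
    inc <- r[best] > 0
    pos <- if (inc) best + which.min(cs) else best + which.max(cs) - 1L
    data.frame(position = pos, kind = if (inc) "increase" else "decrease",
               r = r[best],
               p_value = if (abs(r[best]) >= 1) 0 else
                 2 * stats::pt(-abs(r[best] * sqrt((window - 2) /
                                                   (1 - r[best]^2))),
                               df = window - 2))
  }
  for (k in seq_along(sig)) {
    if (k > 1L && (sig[k] - sig[k - 1L] > 1L || sgn[k] != sgn[k - 1L])) {
      out[[length(out) + 1L]] <- flush_run(sig[run_start:(k - 1L)])
      run_start <- k
    }
  }
  out[[length(out) + 1L]] <- flush_run(sig[run_start:length(sig)])
  res <- do.call(rbind, out)
  res[order(res$position), , drop = FALSE]
}

# codon-counting RSCU oracle
oracle_rscu <- function(cds) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  codons <- codons[codons %in% sense]
  out <- stats::setNames(numeric(length(sense)), sense)
  for (c1 in sense) {
    aa <- gc_tab[[c1]]
    fam <- sense[gc_tab[sense] == aa]
    n_a <- sum(codons %in% fam)
    if (n_a > 0) out[c1] <- sum(codons == c1) * length(fam) / n_a
  }
  out
}

# random valid CDS: ATG + sense codons + TAA
random_cds <- function(n_codons) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

oracle_metrics <- function(tp, fn, fp, tn) {
  div <- function(a, b) if (b == 0) NaN else a / b
  list(tpr = div(tp, tp + fn), ppv = div(tp, tp + fp),
       fpr_paper = div(fp, fp + fn), fpr_standard = div(fp, fp + tn),
       error_rate = (fp + fn) / (tp + fn + fp + tn),
       accuracy = (tp + tn) / (tp + fn + fp + tn))
}
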
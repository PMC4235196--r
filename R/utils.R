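# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) stopf("invalid strand value(s): %s",
                      paste(unique(strand[bad]), collapse = ", "))
  invisible(strand)
}

# deterministic child seeds derived from one master seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o) * 1013904223) %% 2147483647
  as.integer(s)
}

pair_id <- function(gene_i, gene_j) paste(gene_i, gene_j, sep = "|")
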
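# Shared helpers: classed conditions, sequence utilities, coordinate checks.

abort_alkscan <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "alkscan_error")))
}

#' @useDynLib alkscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, uppercase).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a DNA string
#'
#' Ambiguous bases (anything outside A/C/G/T) are ignored in the denominator.
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(x) {
  vapply(x, function(s) {
    gc <- nchar(gsub("[^GCgc]", "", s))
    at <- nchar(gsub("[^ATat]", "", s))
    if (gc + at == 0) return(NA_real_)
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

# nearest-boundary distance between two 0-based half-open intervals on one
# replicon; 0 when they overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2, s2 - e1))
}

# deterministic RNG scope: run `expr` under `seed`, restore the caller's state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
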
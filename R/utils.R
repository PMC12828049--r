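#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbinom rpois runif setNames fisher.test
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string (A/C/G/T/N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open interval as a plain list; the whole package keeps
# this convention internally and converts to 1-based only for display.
interval <- function(contig, start, end, strand = "+") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  list(contig = contig, start = as.integer(start), end = as.integer(end),
       strand = strand)
}

interval_width <- function(iv) iv$end - iv$start

# data.frame(start, end) of 0-based half-open intervals -> merged union,
# sorted. Empty input allowed.
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Overlap width between one interval [s,e) and a merged interval set.
overlap_width <- function(s, e, merged) {
  if (nrow(merged) == 0) return(0L)
  w <- pmin(e, merged$end) - pmax(s, merged$start)
  sum(pmax(w, 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
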
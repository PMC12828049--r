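#' Default promoter-alignment scoring parameters
#'
#' Global affine-gap alignment scores used for promoter-vs-promoter
#' comparison: match +1, mismatch -1, gap open -5, gap extend -0.5.
#' N mismatches every base, including itself.
#'
#' @return List of alignment parameters.
#' @export
alignment_params <- function(match = 1, mismatch = -1,
                             gap_open = 5, gap_extend = 0.5) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.subst_matrix <- function(params) {
  m <- matrix(params$mismatch, 5, 5,
              dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  diag(m)[1:4] <- params$match
  m
}

#' Globally align two promoter sequences
#'
#' Needleman-Wunsch with affine gaps (via Biostrings). Both sequences must
#' be in promoter orientation. The result carries the two gapped strings
#' plus coordinate maps between ungapped positions in either sequence.
#'
#' @param ref,other Character strings over A/C/G/T/N.
#' @param params Scoring parameters from [alignment_params()].
#' @return Object of class \code{pairwise_alignment} with fields
#'   \code{ref_gapped}, \code{other_gapped}, \code{score}, and per-column
#'   0-based coordinate vectors \code{ref_pos}, \code{other_pos}
#'   (NA at gap columns).
#' @export
align_pair <- function(ref, other, params = alignment_params()) {
  if (!nzchar(ref) || !nzchar(other)) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(other),
    type = "global", substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  rg <- as.character(Biostrings::alignedPattern(aln))
  og <- as.character(Biostrings::alignedSubject(aln))
  rc <- strsplit(rg, "")[[1]]
  oc <- strsplit(og, "")[[1]]
  ref_pos <- ifelse(rc != "-", cumsum(rc != "-") - 1L, NA_integer_)
  other_pos <- ifelse(oc != "-", cumsum(oc != "-") - 1L, NA_integer_)
  structure(list(ref_gapped = rg, other_gapped = og,
                 score = Biostrings::score(aln),
                 ref_pos = as.integer(ref_pos),
                 other_pos = as.integer(other_pos)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global pairwise alignment:", nchar(x$ref_gapped), "columns, score",
      x$score, "\n")
  invisible(x)
}

# Per-column match indicator: both non-gap, equal, and neither is N.
.column_matches <- function(aln) {
  rc <- strsplit(aln$ref_gapped, "")[[1]]
  oc <- strsplit(aln$other_gapped, "")[[1]]
  rc == oc & rc != "-" & rc != "N"
}

#' Call conserved segments from a pairwise alignment by windowed identity
#'
#' Slides a window of \code{window} alignment columns in steps of one
#' column and anchors each window's identity (matching columns / window)
#' at its center column, the convention of VISTA-style conservation
#' curves; center columns whose window identity reaches
#' \code{min_identity} are marked, and maximal marked runs of reference
#' positions become segments. Center anchoring keeps segment boundaries
#' within about half a window of the underlying conserved block, where
#' whole-window marking would push them outward by up to a full window.
#' Segments shorter than \code{window} reference bases are discarded. If
#' the alignment is shorter than the window, the whole alignment is one
#' window and all its columns are marked when it passes.
#'
#' @param aln A [align_pair()] result.
#' @param window Window size in alignment columns (>= 20).
#' @param min_identity Identity threshold in (0, 1].
#' @return data.frame with columns start, end (0-based half-open,
#'   reference promoter coordinates) and mean_identity.
#' @export
window_identity_segments <- function(aln, window = 100L, min_identity = 0.7) {
  stopifnot(window >= 20, min_identity > 0, min_identity <= 1)
  match <- .column_matches(aln)
  ncol <- length(match)
  w <- min(as.integer(window), ncol)
  # rolling count of matches per window of w columns
  cs <- c(0, cumsum(match))
  nw <- ncol - w + 1L
  wins <- cs[(w + 1L):(w + nw)] - cs[1:nw]
  good <- wins / w >= min_identity
  marked <- logical(ncol)
  if (w == ncol) {
    # degenerate single-window case: mark everything when it passes
    if (good[1]) marked[] <- TRUE
  } else if (any(good)) {
    marked[which(good) + w %/% 2L] <- TRUE
  }
  ref_here <- !is.na(aln$ref_pos)
  keep <- marked & ref_here
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_identity = numeric(0)))
  pos <- aln$ref_pos[keep]
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  segs <- lapply(runs, function(p) {
    s <- p[1]; e <- p[length(p)] + 1L
    cols <- which(!is.na(aln$ref_pos) & aln$ref_pos >= s & aln$ref_pos < e)
    span <- seq(min(cols), max(cols))
    data.frame(start = s, end = e,
               mean_identity = mean(match[span]))
  })
  out <- do.call(rbind, segs)
  out <- out[out$end - out$start >= w, , drop = FALSE]  # w: effective window
  rownames(out) <- NULL
  out
}

#' Project a reference interval into the other species' coordinates
#'
#' Maps both endpoints through the alignment columns; endpoints that fall
#' in a gap of the other sequence slide inward to the nearest aligned
#' position.
#'
#' @param start,end 0-based half-open reference interval.
#' @param aln A [align_pair()] result.
#' @return c(start, end) in other-species 0-based coordinates.
#' @export
project_to_species <- function(start, end, aln) {
  stopifnot(start < end)
  cols <- which(!is.na(aln$ref_pos) & aln$ref_pos >= start & aln$ref_pos < end)
  if (length(cols) == 0)
    stop("interval [", start, ",", end, ") outside the aligned range")
  other <- aln$other_pos[seq(min(cols), max(cols))]
  other <- other[!is.na(other)]
  if (length(other) == 0)
    stop("projection of [", start, ",", end,
         ") collapses to length 0 in the other species")
  c(min(other), max(other) + 1L)
}
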
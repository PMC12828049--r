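#' Convert a position frequency matrix to a position weight matrix
#'
#' Adds the pseudocount to every cell, converts to column probabilities and
#' then to log2 odds against the background. The attainable score range
#' (sum of column minima / maxima) is stored for relative (min-max
#' normalized) scoring.
#'
#' @param pfm 4 x W non-negative count matrix, rows A,C,G,T.
#' @param motif_id Motif identifier carried into hits.
#' @param pseudocount Added to every cell (default 0.8).
#' @param background Background base probabilities (A,C,G,T), summing to 1.
#' @return Object of class \code{pwm}: list with \code{log_odds},
#'   \code{s_min}, \code{s_max}, \code{width}, \code{col_min}.
#' @export
pfm_to_pwm <- function(pfm, motif_id = "motif", pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  stopifnot(nrow(pfm) == 4, ncol(pfm) >= 1, pseudocount > 0)
  if (any(background <= 0)) stop("background frequencies must be positive")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (any(pfm < 0) || any(colSums(pfm) <= 0))
    stop("PFM must be non-negative with positive column totals")
  p <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  lo <- log2(p / background)
  rownames(lo) <- DNA_BASES
  structure(list(motif_id = motif_id, log_odds = lo,
                 s_min = sum(apply(lo, 2, min)),
                 s_max = sum(apply(lo, 2, max)),
                 col_min = apply(lo, 2, min),
                 width = ncol(lo),
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: width %d, score range [%.3f, %.3f]\n",
              x$motif_id, x$width, x$s_min, x$s_max))
  invisible(x)
}

#' Min-max normalized (relative) score of one sequence window
#'
#' Returns (S - s_min) / (s_max - s_min) where S is the summed log-odds of
#' the window. Columns holding N contribute the column minimum. A
#' degenerate motif (s_max == s_min) scores 1 with a warning.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param window String of length \code{pwm$width}.
#' @return Relative score in [0, 1].
#' @export
relative_score <- function(pwm, window) {
  stopifnot(nchar(window) == pwm$width)
  idx <- match(strsplit(toupper(window), "")[[1]], DNA_BASES)
  s <- 0
  for (j in seq_len(pwm$width))
    s <- s + if (is.na(idx[j])) pwm$col_min[j] else pwm$log_odds[idx[j], j]
  rng <- pwm$s_max - pwm$s_min
  if (rng == 0) {
    warning("degenerate motif '", pwm$motif_id,
            "' (constant score); relative score defined as 1")
    return(1)
  }
  unname((s - pwm$s_min) / rng)
}

# Integer encoding of a sequence (A=1..T=4, N/other = NA).
.encode_seq <- function(seq) match(strsplit(seq, "")[[1]], DNA_BASES)

# Relative scores of all windows on one strand of an encoded sequence.
.scan_strand <- function(pwm, idx) {
  w <- pwm$width
  n <- length(idx) - w + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n - 1L)]
    col <- pwm$log_odds[, j]
    v <- col[b]
    v[is.na(b)] <- pwm$col_min[j]
    s <- s + v
  }
  rng <- pwm$s_max - pwm$s_min
  if (rng == 0) rep(1, n) else (s - pwm$s_min) / rng
}

#' Scan a CNCS sequence for motif occurrences on both strands
#'
#' Every window start on the given sequence and its reverse complement is
#' scored; windows with relative score >= 1 - deficit (inclusive) are
#' reported. Minus-strand hits are reported with coordinates on the given
#' (promoter-orientation) sequence. The normalized position is the window
#' midpoint divided by sequence length.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param seq CNCS sequence (promoter orientation).
#' @param deficit Relative-score deficit threshold (default 0.15; hits need
#'   relative score >= 0.85).
#' @param species,cncs_id Labels carried into the hit table.
#' @return data.frame: motif_id, species, cncs_id, start (0-based), end,
#'   strand, relative_score, norm_pos.
#' @export
scan_cncs <- function(pwm, seq, deficit = 0.15, species = NA_character_,
                      cncs_id = NA_character_) {
  stopifnot(deficit >= 0, deficit < 1)
  L <- nchar(seq)
  w <- pwm$width
  empty <- data.frame(motif_id = character(0), species = character(0),
                      cncs_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      relative_score = numeric(0), norm_pos = numeric(0))
  if (L < w) {
    warning("sequence shorter than motif width (", L, " < ", w, ")")
    return(empty)
  }
  thr <- 1 - deficit
  fwd <- .scan_strand(pwm, .encode_seq(seq))
  rev <- .scan_strand(pwm, .encode_seq(revcomp(seq)))
  keep_f <- which(fwd >= thr)
  keep_r <- which(rev >= thr)
  hits <- rbind(
    if (length(keep_f))
      data.frame(start = keep_f - 1L, strand = "+",
                 relative_score = fwd[keep_f]),
    if (length(keep_r))
      data.frame(start = L - w - (keep_r - 1L), strand = "-",
                 relative_score = rev[keep_r]))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  out <- data.frame(motif_id = pwm$motif_id, species = species,
                    cncs_id = cncs_id, start = hits$start,
                    end = hits$start + w, strand = hits$strand,
                    relative_score = hits$relative_score,
                    norm_pos = (hits$start + w / 2) / L)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every species' sequence of every CNCS with a motif set
#'
#' @param cncs_set A [detect_cncs()] result.
#' @param pwms List of [pfm_to_pwm()] objects.
#' @param deficit Relative-score deficit threshold.
#' @return Combined hit data.frame (see [scan_cncs()]).
#' @export
scan_cncs_set <- function(cncs_set, pwms, deficit = 0.15) {
  res <- list()
  for (c_ in cncs_set$cncs)
    for (sp in names(c_$per_species))
      for (pwm in pwms)
        res[[length(res) + 1L]] <- scan_cncs(
          pwm, c_$per_species[[sp]]$sequence, deficit = deficit,
          species = sp, cncs_id = c_$cncs_id)
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(motif_id = character(0), species = character(0),
                      cncs_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      relative_score = numeric(0), norm_pos = numeric(0))
  rownames(out) <- NULL
  out
}
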
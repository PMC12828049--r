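# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (loops, enumeration)
# kept separate from the package's code paths.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc <- function(x) {
  chartr_out <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(chartr_out, "")[[1]]), collapse = "")
}

# A sharp PFM whose consensus is the given string (count 97 consensus / 1 other).
consensus_pfm <- function(consensus, hi = 97, lo = 1) {
  chars <- strsplit(consensus, "")[[1]]
  m <- t(sapply(BASES, function(b) ifelse(chars == b, hi, lo)))
  rownames(m) <- BASES
  m
}

random_pfm <- function(width) {
  m <- matrix(sample(0:50, 4 * width, replace = TRUE), 4,
              dimnames = list(BASES, NULL))
  # guarantee positive column totals
  m[1, colSums(m) == 0] <- 1
  m
}

# --- Gotoh affine-gap global alignment score (O(nm) DP, score only) -----
# Penalty convention mirrors the package: opening a gap of length k costs
# gap_open + k * gap_extend.
gotoh_score <- function(s1, s2, match = 1, mismatch = -1,
                        gap_open = 5, gap_extend = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  go <- -(gap_open + gap_extend)   # cost of first gapped position
  ge <- -gap_extend
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in s2 (s1 char unpaired)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in s1
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- go + (i - 2) * ge
  for (j in 2:(m + 1)) Y[1, j] <- go + (j - 2) * ge
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      Y[i, j] <- max(M[i, j - 1] + go, Y[i, j - 1] + ge, X[i, j - 1] + go)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- brute-force PWM window scorer -------------------------------------
oracle_scan <- function(pfm, seq, deficit, pseudocount = 0.8) {
  p <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  lo <- log2(p / 0.25)
  s_min <- sum(apply(lo, 2, min)); s_max <- sum(apply(lo, 2, max))
  w <- ncol(lo); L <- nchar(seq)
  score1 <- function(win) {
    ch <- strsplit(win, "")[[1]]
    s <- 0
    for (j in seq_len(w)) {
      if (ch[j] %in% BASES) s <- s + lo[ch[j], j]
      else s <- s + min(lo[, j])
    }
    (s - s_min) / (s_max - s_min)
  }
  rows <- list()
  for (start in 0:(L - w)) {
    win <- substr(seq, start + 1, start + w)
    rs <- score1(win)
    if (rs >= 1 - deficit)
      rows[[length(rows) + 1]] <- data.frame(start = start, strand = "+",
                                             relative_score = rs)
    rsr <- score1(rc(win))
    if (rsr >= 1 - deficit)
      rows[[length(rows) + 1]] <- data.frame(start = start, strand = "-",
                                             relative_score = rsr)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      relative_score = numeric(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- exhaustive cross-species positional match -------------------------
oracle_match <- function(hits, ref_species, margin) {
  others <- setdiff(unique(hits$species), ref_species)
  ref <- hits[hits$species == ref_species, , drop = FALSE]
  keep <- logical(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    h <- ref[i, ]
    ok <- TRUE
    for (sp in others) {
      cand <- hits[hits$species == sp & hits$motif_id == h$motif_id &
                     hits$cncs_id == h$cncs_id, , drop = FALSE]
      if (!any(abs(cand$norm_pos - h$norm_pos) <= margin)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  ref[keep, , drop = FALSE]
}

# --- per-base bitmap interval intersection -----------------------------
oracle_intersect <- function(segments_by_species, universe, min_len) {
  bit <- rep(TRUE, universe)
  for (df in segments_by_species) {
    b <- rep(FALSE, universe)
    for (k in seq_len(nrow(df)))
      b[seq(df$start[k] + 1, df$end[k])] <- TRUE
    bit <- bit & b
  }
  if (!any(bit)) return(data.frame(start = integer(0), end = integer(0)))
  pos <- which(bit) - 1L
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  out <- do.call(rbind, lapply(runs, function(p)
    data.frame(start = p[1], end = p[length(p)] + 1L)))
  out <- out[out$end - out$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- column-walking interval projection --------------------------------
oracle_project <- function(start, end, aln) {
  rcv <- strsplit(aln$ref_gapped, "")[[1]]
  ocv <- strsplit(aln$other_gapped, "")[[1]]
  rpos <- -1L; opos <- -1L
  hit <- integer(0)
  for (col in seq_along(rcv)) {
    if (ocv[col] != "-") opos <- opos + 1L
    if (rcv[col] != "-") {
      rpos <- rpos + 1L
      if (rpos >= start && rpos < end && ocv[col] != "-")
        hit <- c(hit, opos)
    }
  }
  c(min(hit), max(hit) + 1L)
}

# --- hypergeometric tail p-value by direct summation -------------------
oracle_fisher_greater <- function(n11, n12, n21, n22) {
  m <- n11 + n21; n <- n12 + n22; k <- n11 + n12
  lo <- n11; hi <- min(m, k)
  sum(vapply(lo:hi, function(x) dhyper(x, m, n, k), 1.0))
}
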
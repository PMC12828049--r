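#' Annotate homology hits with C-scores
#'
#' The C-score of a hit (a, b) is its score divided by the larger of the
#' two genes' best scores over all their hits; mutual best hits score 1.
#'
#' @param hits data.frame with columns geneA, geneB, score (score > 0).
#' @return The input with a \code{c_score} column added.
#' @export
compute_c_scores <- function(hits) {
  if (nrow(hits) == 0) stop("empty homology hit table")
  stopifnot(all(hits$score > 0))
  bestA <- tapply(hits$score, hits$geneA, max)
  bestB <- tapply(hits$score, hits$geneB, max)
  hits$c_score <- hits$score /
    pmax(bestA[as.character(hits$geneA)], bestB[as.character(hits$geneB)])
  hits$c_score <- unname(hits$c_score)
  hits
}

#' Filter homology hits to putative ortholog pairs
#'
#' Keeps hits with C-score >= \code{threshold} (inclusive; 0.99
#' approximates reciprocal best hits, 0.7 is the relaxed setting used
#' across whole-genome duplications) and attaches chromosome labels.
#' Genes lacking a chromosome assignment are excluded and audited.
#'
#' @param hits Output of [compute_c_scores()].
#' @param chromA,chromB Named vectors: gene id -> chromosome label.
#' @param threshold C-score cutoff in (0, 1].
#' @return List with \code{pairs} (geneA, geneB, c_score, chromA, chromB)
#'   and \code{audit} (excluded hits with reasons).
#' @export
filter_pairs <- function(hits, chromA, chromB, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!"c_score" %in% names(hits)) hits <- compute_c_scores(hits)
  kept <- hits[hits$c_score >= threshold, , drop = FALSE]
  cA <- chromA[as.character(kept$geneA)]
  cB <- chromB[as.character(kept$geneB)]
  unassigned <- is.na(cA) | is.na(cB)
  audit <- kept[unassigned, , drop = FALSE]
  if (nrow(audit) > 0) audit$reason <- "no chromosome assignment"
  else audit$reason <- character(0)
  pairs <- kept[!unassigned, , drop = FALSE]
  pairs$chromA <- unname(cA[!unassigned])
  pairs$chromB <- unname(cB[!unassigned])
  rownames(pairs) <- rownames(audit) <- NULL
  list(pairs = pairs, audit = audit)
}

#' Chromosome-correspondence tests between two species
#'
#' For every chromosome pair (x, y) sharing at least one ortholog pair, a
#' 2x2 contingency table (on x & on y / on x only / on y only / neither)
#' is tested for enrichment with a one-sided Fisher exact test, and
#' p-values are Bonferroni-corrected by the number of pairs tested.
#'
#' @param pairs The \code{pairs} data.frame from [filter_pairs()] (needs
#'   chromA, chromB columns).
#' @param alpha Significance level on the adjusted p-value (default 0.05;
#'   the lenient setting for very distant comparisons is 0.2).
#' @param bonferroni_all_pairs Use |A| x |B| as the correction factor
#'   instead of the number of tested pairs.
#' @return Object of class \code{synteny_result}: list with \code{tests}
#'   (chromA, chromB, n11, n12, n21, n22, p_raw, p_adjusted, significant),
#'   \code{n_tested}, \code{alpha}.
#' @export
correspondence_test <- function(pairs, alpha = 0.05,
                                bonferroni_all_pairs = FALSE) {
  stopifnot(nrow(pairs) >= 1, alpha > 0, alpha < 1)
  tab <- table(pairs$chromA, pairs$chromB)
  total <- sum(tab)
  idx <- which(tab >= 1, arr.ind = TRUE)
  m <- if (bonferroni_all_pairs) nrow(tab) * ncol(tab) else nrow(idx)
  rows <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    n11 <- tab[i, j]
    n12 <- sum(tab[i, ]) - n11
    n21 <- sum(tab[, j]) - n11
    n22 <- total - n11 - n12 - n21
    degenerate <- (n12 + n22 == 0) || (n21 + n22 == 0)
    p <- if (degenerate) 1.0 else
      fisher.test(matrix(c(n11, n12, n21, n22), 2, byrow = TRUE),
                  alternative = "greater")$p.value
    rows[[k]] <- data.frame(
      chromA = rownames(tab)[i], chromB = colnames(tab)[j],
      n11 = n11, n12 = n12, n21 = n21, n22 = n22,
      p_raw = p, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  tests$p_adjusted <- pmin(1, tests$p_raw * m)
  tests$significant <- tests$p_adjusted < alpha
  tests <- tests[order(tests$p_adjusted, tests$chromA, tests$chromB), ,
                 drop = FALSE]
  rownames(tests) <- NULL
  structure(list(tests = tests, n_tested = nrow(idx),
                 bonferroni_factor = m, alpha = alpha,
                 n_pairs = total),
            class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  sig <- x$tests[x$tests$significant, , drop = FALSE]
  cat("Chromosome correspondence:", x$n_pairs, "ortholog pairs,",
      x$n_tested, "chromosome pairs tested (Bonferroni x",
      x$bonferroni_factor, "),", nrow(sig),
      "significant at adjusted p <", x$alpha, "\n")
  if (nrow(sig) > 0)
    print(sig[, c("chromA", "chromB", "n11", "p_raw", "p_adjusted")],
          digits = 3)
  invisible(x)
}

#' @export
summary.synteny_result <- function(object, ...) {
  cat("Tested chromosome pairs:\n")
  print(object$tests, digits = 3)
  invisible(object$tests)
}

#' Ribbon-plot style dot matrix of significant chromosome pairs
#'
#' @param x A [correspondence_test()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.synteny_result <- function(x, ...) {
  t <- x$tests
  ca <- sort(unique(t$chromA)); cb <- sort(unique(t$chromB))
  graphics::plot(NA, xlim = c(0.5, length(ca) + 0.5),
                 ylim = c(0.5, length(cb) + 0.5), xaxt = "n", yaxt = "n",
                 xlab = "species A chromosome", ylab = "species B chromosome",
                 main = "Chromosome correspondence", ...)
  graphics::axis(1, seq_along(ca), ca, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(cb), cb, las = 1, cex.axis = 0.7)
  cex <- 0.4 + 2.6 * sqrt(t$n11 / max(t$n11))
  graphics::points(match(t$chromA, ca), match(t$chromB, cb), cex = cex,
                   pch = 19,
                   col = ifelse(t$significant, "firebrick", "grey70"))
  invisible(x)
}

#' Run the macrosynteny comparison end-to-end
#'
#' C-score annotation, threshold filtering, correspondence testing, and
#' report-level exclusion of pairs outside significant chromosome pairs.
#'
#' @param hits data.frame geneA, geneB, score.
#' @param chromA,chromB Named gene -> chromosome vectors.
#' @param c_threshold C-score cutoff (default 0.99; 0.7 relaxed).
#' @param alpha Adjusted-p significance level (default 0.05; 0.2 lenient).
#' @param outdir Optional directory for TSV reports.
#' @return A \code{synteny_result} with the filtered pairs and, when
#'   \code{outdir} is given, written report paths in \code{files}.
#' @export
run_synteny <- function(hits, chromA, chromB, c_threshold = 0.99,
                        alpha = 0.05, outdir = NULL) {
  if (nrow(hits) == 0) stop("empty homology hit table")
  fp <- filter_pairs(compute_c_scores(hits), chromA, chromB, c_threshold)
  res <- correspondence_test(fp$pairs, alpha = alpha)
  res$pairs <- fp$pairs
  res$audit <- fp$audit
  sig <- res$tests[res$tests$significant, c("chromA", "chromB")]
  inkey <- paste(fp$pairs$chromA, fp$pairs$chromB) %in%
    paste(sig$chromA, sig$chromB)
  res$pairs_in_significant <- fp$pairs[inkey, , drop = FALSE]
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- c(tests = file.path(outdir, "chromosome_pair_tests.tsv"),
               significant = file.path(outdir, "significant_pairs.tsv"),
               ribbon = file.path(outdir, "ribbon_data.tsv"))
    write.table(res$tests, files["tests"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(res$tests[res$tests$significant, , drop = FALSE],
                files["significant"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(res$tests[res$tests$significant,
                          c("chromA", "chromB", "n11"), drop = FALSE],
                files["ribbon"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$files <- files
  }
  res
}
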
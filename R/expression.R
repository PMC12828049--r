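#' Mean expression across selected stages
#'
#' @param expr Genes x conditions numeric matrix.
#' @param stages Condition labels to average.
#' @return Named per-gene mean vector (all genes retained).
#' @export
stage_mean <- function(expr, stages) {
  missing <- setdiff(stages, colnames(expr))
  if (length(missing) > 0)
    stop("unknown stage label(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(colnames(expr), collapse = ", "))
  rowMeans(expr[, stages, drop = FALSE])
}

#' Linear-interpolation percentile threshold over a per-gene vector
#'
#' Computed over all genes, zeros included (the transcriptome-wide
#' convention); downstream comparisons are strict (\code{>}), so a gene
#' exactly at the threshold does not pass.
#'
#' @param values Per-gene numeric vector (length >= 2).
#' @param percentile Percentile in (0, 100).
#' @return The interpolated threshold (a single number).
#' @export
percentile_threshold <- function(values, percentile) {
  if (length(values) == 0) stop("empty expression vector")
  stopifnot(percentile > 0, percentile < 100)
  unname(quantile(values, percentile / 100, type = 7, names = FALSE))
}

#' Pseudobulk mean across single-cell clusters
#'
#' Per cluster, raw counts are summed over that cluster's cells
#' (aggregation); the per-cluster sums are then averaged over the selected
#' clusters.
#'
#' @param sc Genes x cells numeric count matrix.
#' @param cluster_labels Named vector mapping cell id (column name) to
#'   cluster id.
#' @param clusters Cluster ids to use.
#' @return Named per-gene mean-of-sums vector.
#' @export
pseudobulk_mean <- function(sc, cluster_labels, clusters) {
  sums <- sapply(clusters, function(cl) {
    cells <- names(cluster_labels)[cluster_labels == cl]
    cells <- intersect(cells, colnames(sc))
    if (length(cells) == 0) stop("cluster '", cl, "' has no cells")
    rowSums(sc[, cells, drop = FALSE])
  })
  rowMeans(as.matrix(sums))
}

#' Expression verdicts for a set of genes against percentile thresholds
#'
#' @param means Named per-gene vector (stage mean or pseudobulk mean) over
#'   the whole transcriptome.
#' @param percentile Percentile defining the threshold (bulk default 25,
#'   single-cell default 50).
#' @param threshold Optional absolute override; when given the percentile
#'   is ignored (the published analyses approximated their computed
#'   percentiles as fixed cutoffs, e.g. 17 and 250).
#' @return data.frame: gene_id, mean, threshold, pass (strict >).
#' @export
expression_verdicts <- function(means, percentile = 25, threshold = NULL) {
  thr <- threshold %||% percentile_threshold(means, percentile)
  data.frame(gene_id = names(means), mean = unname(means),
             threshold = thr, pass = unname(means) > thr,
             stringsAsFactors = FALSE)
}

#' Gate conserved TFBSs by transcription-factor expression
#'
#' A conserved site is retained iff at least one TF gene mapped to its
#' motif passes the bulk filter (mode \code{"bulk_only"}) or both the bulk
#' and single-cell filters (mode \code{"bulk_and_sc"}). Motifs with no
#' gene mapping are excluded and audited as "unmapped".
#'
#' @param conserved Output of [cross_species_match()].
#' @param tf_map Named list: motif id -> character vector of TF gene ids.
#' @param bulk_verdicts,sc_verdicts [expression_verdicts()] data.frames
#'   (sc_verdicts may be NULL in bulk_only mode).
#' @param mode "bulk_only" or "bulk_and_sc".
#' @return List with \code{retained} (subset of \code{conserved} plus
#'   passing-gene column) and \code{audit} (excluded rows with reasons).
#' @export
gate_tfbs <- function(conserved, tf_map, bulk_verdicts, sc_verdicts = NULL,
                      mode = c("bulk_and_sc", "bulk_only")) {
  mode <- match.arg(mode)
  if (mode == "bulk_and_sc" && is.null(sc_verdicts))
    stop("mode 'bulk_and_sc' requires single-cell verdicts")
  passes <- function(verdicts, gene)
    gene %in% verdicts$gene_id[verdicts$pass]
  keep <- logical(nrow(conserved))
  reason <- character(nrow(conserved))
  gene_col <- character(nrow(conserved))
  for (i in seq_len(nrow(conserved))) {
    motif <- conserved$motif_id[i]
    genes <- tf_map[[motif]]
    if (is.null(genes) || length(genes) == 0) {
      reason[i] <- "unmapped"
      next
    }
    bulk_ok <- genes[vapply(genes, passes, TRUE, verdicts = bulk_verdicts)]
    if (length(bulk_ok) == 0) {
      reason[i] <- "expression"
      next
    }
    if (mode == "bulk_and_sc") {
      both_ok <- bulk_ok[vapply(bulk_ok, passes, TRUE,
                                verdicts = sc_verdicts)]
      if (length(both_ok) == 0) {
        reason[i] <- "expression"
        next
      }
      gene_col[i] <- paste(both_ok, collapse = ",")
    } else {
      gene_col[i] <- paste(bulk_ok, collapse = ",")
    }
    keep[i] <- TRUE
  }
  retained <- conserved[keep, , drop = FALSE]
  if (nrow(retained) > 0) retained$tf_genes <- gene_col[keep]
  audit <- conserved[!keep, c("motif_id", "cncs_id"), drop = FALSE]
  if (nrow(audit) > 0) audit$reason <- reason[!keep]
  else audit$reason <- character(0)
  rownames(retained) <- rownames(audit) <- NULL
  list(retained = retained, audit = audit)
}
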
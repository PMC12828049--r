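#' Configuration for a footprinting run
#'
#' Collects every tunable the pipeline uses: conservation window and
#' identity, minimum CNCS length, alignment scores, scanner deficit,
#' positional margin, expression percentiles with optional absolute
#' overrides, and ATAC gating behaviour.
#'
#' @param ref_species Reference species (CNCS coordinates are defined on
#'   its promoter and projected outward).
#' @param window,min_identity,min_len Conservation parameters (defaults
#'   100 bp, 0.70, 100 bp).
#' @param deficit Motif-scanner relative-score deficit (default 0.15).
#' @param margin Positional-conservation margin on normalized positions
#'   (default 0.10).
#' @param bulk_percentile,sc_percentile Expression percentiles (defaults
#'   25 and 50).
#' @param bulk_threshold,sc_threshold Optional absolute overrides of the
#'   percentile thresholds (the published analyses approximated theirs at
#'   17 and 250).
#' @param mode Expression gating mode ("bulk_and_sc" or "bulk_only").
#' @param min_overlap Minimum ATAC overlap in bp.
#' @param align_params See [alignment_params()].
#' @param seed Seed recorded in the manifest.
#' @return List of class \code{footprint_config}.
#' @export
footprint_config <- function(ref_species, window = 100L, min_identity = 0.7,
                             min_len = 100L, deficit = 0.15, margin = 0.10,
                             bulk_percentile = 25, sc_percentile = 50,
                             bulk_threshold = NULL, sc_threshold = NULL,
                             mode = "bulk_and_sc", min_overlap = 1L,
                             align_params = alignment_params(), seed = 1L) {
  structure(list(ref_species = ref_species, window = window,
                 min_identity = min_identity, min_len = min_len,
                 deficit = deficit, margin = margin,
                 bulk_percentile = bulk_percentile,
                 sc_percentile = sc_percentile,
                 bulk_threshold = bulk_threshold,
                 sc_threshold = sc_threshold, mode = mode,
                 min_overlap = min_overlap, align_params = align_params,
                 seed = as.integer(seed)),
            class = "footprint_config")
}

#' Read a footprinting configuration from a YAML file
#'
#' Keys mirror the arguments of [footprint_config()].
#'
#' @param path Path to a YAML file.
#' @return A \code{footprint_config}.
#' @export
read_footprint_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  do.call(footprint_config, vals)
}

#' Run the conserved-TFBS footprinting pipeline end-to-end
#'
#' Executes CNCS detection (alignment, windowed identity, cross-species
#' intersection, optional ATAC gating), per-species motif scanning,
#' cross-species positional filtering, and expression gating, returning
#' one classed object holding every intermediate plus per-stage counters.
#'
#' @param promoters Named character vector of promoter sequences (one per
#'   species, promoter orientation), or a named list of such vectors for
#'   several genes.
#' @param pfms Named list of PFM count matrices (see [read_jaspar()]).
#' @param config A [footprint_config()].
#' @param peak_sets Optional per-stage ATAC peak data.frames in reference
#'   promoter coordinates.
#' @param tf_map Named list motif id -> TF gene ids; NULL skips expression
#'   gating.
#' @param bulk,bulk_stages Bulk expression matrix and the stage columns to
#'   average.
#' @param sc,cluster_labels,sc_clusters Single-cell count matrix, cell ->
#'   cluster labels and the clusters to pseudobulk.
#' @param gene_id Gene label for the run.
#' @return Object of class \code{footprint_run}.
#' @export
run_footprint <- function(promoters, pfms, config, peak_sets = NULL,
                          tf_map = NULL, bulk = NULL, bulk_stages = NULL,
                          sc = NULL, cluster_labels = NULL,
                          sc_clusters = NULL, gene_id = "gene") {
  t0 <- Sys.time()
  cncs <- detect_cncs(promoters, config$ref_species, gene_id = gene_id,
                      window = config$window,
                      min_identity = config$min_identity,
                      min_len = config$min_len, peak_sets = peak_sets,
                      min_overlap = config$min_overlap,
                      align_params = config$align_params)
  pwms <- lapply(names(pfms), function(id)
    pfm_to_pwm(pfms[[id]], motif_id = id))
  hits <- scan_cncs_set(cncs, pwms, deficit = config$deficit)
  conserved <- if (nrow(hits) > 0 &&
                   config$ref_species %in% hits$species)
    cross_species_match(hits, config$ref_species, margin = config$margin)
  else
    cross_species_match(
      data.frame(motif_id = "none", species = config$ref_species,
                 cncs_id = "none", start = 0L, end = 1L, strand = "+",
                 relative_score = 1, norm_pos = 0.5),
      config$ref_species, margin = config$margin)[0, ]
  bulk_verdicts <- sc_verdicts <- NULL
  gated <- list(retained = conserved, audit = NULL)
  if (!is.null(tf_map) && !is.null(bulk)) {
    bv <- expression_verdicts(stage_mean(bulk, bulk_stages),
                              percentile = config$bulk_percentile,
                              threshold = config$bulk_threshold)
    sv <- NULL
    if (!is.null(sc) && config$mode == "bulk_and_sc")
      sv <- expression_verdicts(
        pseudobulk_mean(sc, cluster_labels, sc_clusters),
        percentile = config$sc_percentile,
        threshold = config$sc_threshold)
    gated <- gate_tfbs(conserved, tf_map, bv, sv, mode = config$mode)
    bulk_verdicts <- bv; sc_verdicts <- sv
  }
  counters <- c(
    species = length(promoters),
    cncs = length(cncs$cncs),
    motif_hits = nrow(hits),
    conserved_sites = nrow(conserved),
    final_candidates = nrow(gated$retained))
  structure(list(gene_id = gene_id, config = config, cncs = cncs,
                 hits = hits, conserved = conserved,
                 retained = gated$retained, audit = gated$audit,
                 bulk_verdicts = bulk_verdicts,
                 sc_verdicts = sc_verdicts,
                 counters = counters,
                 elapsed = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
            class = "footprint_run")
}

#' @export
print.footprint_run <- function(x, ...) {
  cat("Conserved-TFBS footprinting run for", x$gene_id, "\n")
  cat(sprintf("  species: %d | CNCSs: %d | motif hits: %d | conserved: %d | final: %d\n",
              x$counters["species"], x$counters["cncs"],
              x$counters["motif_hits"], x$counters["conserved_sites"],
              x$counters["final_candidates"]))
  invisible(x)
}

#' @export
summary.footprint_run <- function(object, ...) {
  print(object)
  cat("\nCNCSs:\n"); print(object$cncs)
  if (nrow(object$retained) > 0) {
    cat("\nFinal candidate conserved TFBSs:\n")
    print(object$retained[, c("motif_id", "cncs_id", "mean_norm_pos",
                              "max_deviation",
                              intersect("tf_genes",
                                        names(object$retained)))],
          digits = 3)
  } else cat("\nNo candidates survived all filters.\n")
  if (!is.null(object$audit) && nrow(object$audit) > 0) {
    cat("\nExcluded at expression gating:\n")
    print(object$audit)
  }
  invisible(object)
}

#' Barplot of conserved-site positions along each CNCS
#'
#' One panel row per CNCS; conserved sites are drawn at their mean
#' normalized position.
#'
#' @param x A [run_footprint()] result.
#' @param final_only Plot only sites surviving expression gating.
#' @param ... Ignored.
#' @export
plot.footprint_run <- function(x, final_only = FALSE, ...) {
  d <- if (final_only) x$retained else x$conserved
  ids <- vapply(x$cncs$cncs, `[[`, "", "cncs_id")
  if (length(ids) == 0) { graphics::plot.new(); return(invisible(x)) }
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0.5, length(ids) + 0.5),
                 yaxt = "n", xlab = "normalized position in CNCS",
                 ylab = "", main = paste("Conserved TFBSs:", x$gene_id))
  graphics::axis(2, seq_along(ids), ids, las = 1, cex.axis = 0.8)
  graphics::abline(h = seq_along(ids), col = "grey85")
  if (nrow(d) > 0) {
    y <- match(d$cncs_id, ids)
    graphics::points(d$mean_norm_pos, y, pch = 19, col = "firebrick")
    graphics::text(d$mean_norm_pos, y + 0.18, d$motif_id, cex = 0.7)
  }
  invisible(x)
}

#' Write all artifacts of a footprinting run with a content manifest
#'
#' Writes the CNCS catalog (BED/TSV/FASTA), the motif hit table, the
#' conserved-site table, the final candidate table, the audit table, and
#' a manifest listing every file with its MD5 hash plus the seed and
#' parameter values. Reruns with identical inputs and config are
#' byte-identical.
#'
#' @param run A [run_footprint()] result.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_footprint_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_cncs(run$cncs, dir)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(files,
             tsv(run$hits, "motif_hits.tsv"),
             tsv(run$conserved, "conserved_tfbs.tsv"),
             tsv(run$retained, "final_candidates.tsv"))
  if (!is.null(run$audit)) files <- c(files, tsv(run$audit, "audit.tsv"))
  cfg <- run$config
  manifest <- file.path(dir, "manifest.tsv")
  md <- data.frame(file = basename(files),
                   md5 = unname(tools::md5sum(files)))
  hdr <- c(sprintf("# gene=%s seed=%d window=%d min_identity=%g deficit=%g margin=%g mode=%s",
                   run$gene_id, cfg$seed, cfg$window, cfg$min_identity,
                   cfg$deficit, cfg$margin, cfg$mode))
  writeLines(c(hdr, paste(md$file, md$md5, sep = "\t")), manifest)
  invisible(manifest)
}
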
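#' Intersect conserved segments across species
#'
#' Returns the maximal reference intervals covered by at least one
#' conserved segment from every non-reference species.
#'
#' @param segments_by_species Named list (one entry per non-reference
#'   species) of data.frames with start/end columns (0-based half-open,
#'   reference coordinates).
#' @param min_len Minimum interval length to keep.
#' @return data.frame with start, end columns.
#' @export
intersect_across_species <- function(segments_by_species, min_len = 100L) {
  if (length(segments_by_species) == 0)
    stop("no species segment lists supplied")
  covs <- lapply(segments_by_species, function(df) {
    m <- merge_intervals(df)
    IRanges::IRanges(start = m$start + 1L, end = m$end)
  })
  acc <- covs[[1]]
  for (ir in covs[-1]) acc <- IRanges::intersect(acc, ir)
  out <- data.frame(start = IRanges::start(acc) - 1L, end = IRanges::end(acc))
  out[out$end - out$start >= min_len, , drop = FALSE]
}

#' Gate candidate intervals by ATAC open-chromatin support
#'
#' Unions the peaks of all stages, merges overlaps, and flags each
#' interval as supported iff its overlap with the union is at least
#' \code{min_overlap} bp. With \code{drop_unsupported = TRUE} the
#' unsupported intervals are removed. With no peak data every interval
#' passes with \code{atac_supported = FALSE}.
#'
#' @param intervals data.frame with start/end (promoter coordinates).
#' @param peak_sets List of data.frames with start/end (one per stage), or
#'   NULL / empty for "no peak data".
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param drop_unsupported Drop intervals lacking support?
#' @return The input data.frame plus a logical \code{atac_supported}
#'   column (filtered if \code{drop_unsupported}).
#' @export
atac_gate <- function(intervals, peak_sets = NULL, min_overlap = 1L,
                      drop_unsupported = TRUE) {
  total <- sum(vapply(peak_sets %||% list(),
                      function(p) nrow(p) %||% 0L, 1L))
  if (is.null(peak_sets) || length(peak_sets) == 0 || total == 0) {
    intervals$atac_supported <- rep(FALSE, nrow(intervals))
    return(intervals)
  }
  union <- merge_intervals(do.call(rbind, lapply(peak_sets, function(p)
    p[, c("start", "end"), drop = FALSE])))
  ov <- mapply(overlap_width, intervals$start, intervals$end,
               MoreArgs = list(merged = union))
  intervals$atac_supported <- as.logical(ov >= min_overlap)
  if (drop_unsupported)
    intervals <- intervals[intervals$atac_supported, , drop = FALSE]
  rownames(intervals) <- NULL
  intervals
}

#' Detect conserved non-coding sequences in a multi-species promoter set
#'
#' Aligns the reference promoter against every other species, calls
#' windowed-identity conserved segments per pair, intersects them across
#' all species, optionally gates by ATAC peaks, and projects each
#' resulting CNCS into every species' own coordinates.
#'
#' @param promoters Named character vector (or list) of promoter sequences
#'   (promoter orientation), one per species, reference included.
#' @param ref_species Name of the reference species.
#' @param gene_id Gene label carried into the CNCS records.
#' @param window,min_identity Conservation window (bp) and identity
#'   threshold (defaults 100 bp / 0.70).
#' @param min_len Minimum CNCS length (default 100 bp).
#' @param peak_sets Optional list of per-stage peak data.frames in
#'   reference promoter coordinates (see [atac_gate()]).
#' @param min_overlap Minimum ATAC overlap in bp.
#' @param align_params Scoring parameters from [alignment_params()].
#' @return Object of class \code{cncs_set}: list with \code{cncs} (a list
#'   of CNCS records: cncs_id, gene_id, ref_start, ref_end,
#'   atac_supported, per_species intervals/sequences/identity) and
#'   \code{alignments} (per non-reference species).
#' @export
detect_cncs <- function(promoters, ref_species, gene_id = "gene",
                        window = 100L, min_identity = 0.7, min_len = 100L,
                        peak_sets = NULL, min_overlap = 1L,
                        align_params = alignment_params()) {
  promoters <- as.list(promoters)
  if (!ref_species %in% names(promoters))
    stop("reference species '", ref_species, "' not among promoters")
  others <- setdiff(names(promoters), ref_species)
  if (length(others) == 0) stop("need at least one non-reference species")
  alns <- lapply(others, function(sp)
    align_pair(promoters[[ref_species]], promoters[[sp]], align_params))
  names(alns) <- others
  segs <- lapply(alns, window_identity_segments,
                 window = window, min_identity = min_identity)
  shared <- intersect_across_species(segs, min_len = min_len)
  shared <- atac_gate(shared, peak_sets, min_overlap = min_overlap,
                      drop_unsupported = !is.null(peak_sets))
  cncs <- vector("list", nrow(shared))
  for (i in seq_len(nrow(shared))) {
    s <- shared$start[i]; e <- shared$end[i]
    per <- list()
    per[[ref_species]] <- list(
      start = s, end = e,
      sequence = substr(promoters[[ref_species]], s + 1L, e),
      mean_identity = NA_real_)
    for (sp in others) {
      pr <- project_to_species(s, e, alns[[sp]])
      ident <- .interval_identity(alns[[sp]], s, e)
      per[[sp]] <- list(
        start = pr[1], end = pr[2],
        sequence = substr(promoters[[sp]], pr[1] + 1L, pr[2]),
        mean_identity = ident)
    }
    cncs[[i]] <- list(
      cncs_id = sprintf("%s_CNCS%d", gene_id, i),
      gene_id = gene_id,
      ref_species = ref_species,
      ref_start = s, ref_end = e,
      atac_supported = shared$atac_supported[i],
      per_species = per)
  }
  structure(list(cncs = cncs, alignments = alns,
                 ref_species = ref_species, gene_id = gene_id,
                 params = list(window = window, min_identity = min_identity,
                               min_len = min_len)),
            class = "cncs_set")
}

# Mean column identity of a ref interval within one alignment.
.interval_identity <- function(aln, start, end) {
  cols <- which(!is.na(aln$ref_pos) & aln$ref_pos >= start &
                  aln$ref_pos < end)
  span <- seq(min(cols), max(cols))
  mean(.column_matches(aln)[span])
}

#' @export
print.cncs_set <- function(x, ...) {
  cat("CNCS set for gene", x$gene_id, "(reference:", x$ref_species, "):",
      length(x$cncs), "conserved non-coding sequence(s)\n")
  for (c_ in x$cncs)
    cat(sprintf("  %s  ref [%d,%d)  %d bp  ATAC=%s\n", c_$cncs_id,
                c_$ref_start, c_$ref_end, c_$ref_end - c_$ref_start,
                c_$atac_supported))
  invisible(x)
}

#' Export a CNCS catalog as BED and TSV tables
#'
#' @param x A [detect_cncs()] result.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_cncs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(x$gene_id, "_cncs.bed"))
  tsv <- file.path(dir, paste0(x$gene_id, "_cncs.tsv"))
  fa <- file.path(dir, paste0(x$gene_id, "_cncs.fasta"))
  bdf <- do.call(rbind, lapply(x$cncs, function(c_)
    data.frame(contig = paste0(x$ref_species, "_promoter"),
               start = c_$ref_start, end = c_$ref_end, name = c_$cncs_id)))
  write.table(bdf, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tdf <- do.call(rbind, lapply(x$cncs, function(c_)
    do.call(rbind, lapply(names(c_$per_species), function(sp) {
      p <- c_$per_species[[sp]]
      data.frame(cncs_id = c_$cncs_id, species = sp, start = p$start,
                 end = p$end, mean_identity = p$mean_identity,
                 atac_supported = c_$atac_supported)
    }))))
  write.table(tdf, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- unlist(lapply(x$cncs, function(c_)
    setNames(vapply(c_$per_species, `[[`, "", "sequence"),
             paste(c_$cncs_id, names(c_$per_species), sep = "|"))))
  write_fasta(seqs, fa)
  invisible(c(bed, tsv, fa))
}
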
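#' Retain motif hits conserved in position across all species
#'
#' For each reference-species hit, a conserved site is emitted iff every
#' other species has at least one hit of the same motif in the same CNCS
#' whose normalized position lies within \code{margin} of the reference
#' hit (inclusive). When several qualify the nearest is recorded (ties
#' break to the smaller start). Strand is not required to match.
#'
#' @param hits data.frame from [scan_cncs()] / [scan_cncs_set()] covering
#'   all species.
#' @param ref_species Reference species name.
#' @param margin Maximum |difference in normalized position| (default 0.10).
#' @return data.frame of conserved sites: motif_id, cncs_id, reference hit
#'   columns (ref_start, ref_strand, ref_score, ref_norm_pos),
#'   mean_norm_pos, max_deviation, n_species, plus one
#'   \code{<species>_norm_pos} column per non-reference species.
#' @export
cross_species_match <- function(hits, ref_species, margin = 0.10) {
  stopifnot(margin > 0, margin < 1)
  species <- unique(hits$species)
  if (!ref_species %in% species)
    stop("reference species '", ref_species, "' has no hits in the table")
  others <- setdiff(species, ref_species)
  ref_hits <- hits[hits$species == ref_species, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ref_hits))) {
    h <- ref_hits[i, ]
    matched <- list()
    ok <- TRUE
    for (sp in others) {
      cand <- hits[hits$species == sp & hits$motif_id == h$motif_id &
                     hits$cncs_id == h$cncs_id, , drop = FALSE]
      cand <- cand[abs(cand$norm_pos - h$norm_pos) <= margin, , drop = FALSE]
      if (nrow(cand) == 0) { ok <- FALSE; break }
      d <- abs(cand$norm_pos - h$norm_pos)
      best <- cand[order(d, cand$start), , drop = FALSE][1, ]
      matched[[sp]] <- best
    }
    if (!ok) next
    pos <- c(h$norm_pos, vapply(matched, function(m) m$norm_pos, 1))
    row <- data.frame(motif_id = h$motif_id, cncs_id = h$cncs_id,
                      ref_start = h$start, ref_strand = h$strand,
                      ref_score = h$relative_score,
                      ref_norm_pos = h$norm_pos,
                      mean_norm_pos = mean(pos),
                      max_deviation = max(abs(pos[-1] - h$norm_pos)),
                      n_species = length(pos))
    for (sp in others) row[[paste0(sp, "_norm_pos")]] <- matched[[sp]]$norm_pos
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(motif_id = character(0), cncs_id = character(0),
                      ref_start = integer(0), ref_strand = character(0),
                      ref_score = numeric(0), ref_norm_pos = numeric(0),
                      mean_norm_pos = numeric(0), max_deviation = numeric(0),
                      n_species = integer(0))
    for (sp in others) res[[paste0(sp, "_norm_pos")]] <- numeric(0)
  }
  rownames(res) <- NULL
  res
}

#' Summarize conserved sites per CNCS and motif
#'
#' @param conserved Output of [cross_species_match()].
#' @return data.frame: cncs_id, motif_id, n_sites, mean positions
#'   (comma-separated when several sites share the key).
#' @export
summarize_by_cncs <- function(conserved) {
  if (nrow(conserved) == 0)
    return(data.frame(cncs_id = character(0), motif_id = character(0),
                      n_sites = integer(0), positions = character(0)))
  key <- interaction(conserved$cncs_id, conserved$motif_id, drop = TRUE)
  rows <- lapply(split(conserved, key), function(g)
    data.frame(cncs_id = g$cncs_id[1], motif_id = g$motif_id[1],
               n_sites = nrow(g),
               positions = paste(sprintf("%.3f", sort(g$mean_norm_pos)),
                                 collapse = ",")))
  out <- do.call(rbind, rows)
  out <- out[order(out$cncs_id, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
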
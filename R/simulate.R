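#' Configuration for the multi-species promoter simulator
#'
#' The defaults emulate the study design the pipeline targets: five
#' species, 5000-bp promoters, three 300-bp conserved blocks (0.02
#' substitutions/site) in a strongly diverged background (0.40
#' substitutions/site), which is cleanly separable at the default
#' 100 bp / 70% conservation criterion.
#'
#' @param n_species Number of species (reference included).
#' @param promoter_length Promoter length in bp.
#' @param blocks data.frame with columns start, length, rate (per-site
#'   substitution probability inside the block).
#' @param background_rate Per-site substitution probability outside blocks.
#' @param indel_rate Per-site indel probability (suppressed inside planted
#'   motifs so positional truth stays exact).
#' @param motifs List of planted motifs, each a list with fields
#'   \code{consensus} (string), \code{block} (block index),
#'   \code{rel_pos} (normalized position inside the block, in [0,1]) and
#'   \code{species} (character vector of carrying species, or NULL for
#'   all). Species not carrying a motif get random sequence over its
#'   footprint.
#' @param seed Random seed.
#' @return List of class \code{promoter_sim_config}.
#' @export
promoter_sim_config <- function(n_species = 5, promoter_length = 5000,
                                blocks = data.frame(
                                  start = c(800, 2300, 3900),
                                  length = c(300, 300, 300),
                                  rate = 0.02),
                                background_rate = 0.4,
                                indel_rate = 0.002,
                                motifs = list(), seed = 1L) {
  stopifnot(n_species >= 2, promoter_length > 0,
            all(blocks$rate >= 0 & blocks$rate <= 1),
            background_rate >= 0, background_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  ends <- blocks$start + blocks$length
  if (any(ends > promoter_length) || any(blocks$start < 0))
    stop("blocks must lie inside the promoter")
  if (nrow(blocks) > 1 && any(blocks$start[-1] < ends[-nrow(blocks)]))
    stop("blocks overlap")
  # motif footprints must not collide within a block
  spans <- lapply(motifs, function(m) {
    b <- blocks[m$block, ]
    w <- nchar(m$consensus)
    s <- b$start + round(m$rel_pos * (b$length - w))
    c(s, s + w, m$block)
  })
  if (length(spans) > 1) {
    for (i in seq_along(spans)) for (j in seq_along(spans)) {
      if (i < j && spans[[i]][3] == spans[[j]][3] &&
          spans[[i]][1] < spans[[j]][2] && spans[[j]][1] < spans[[i]][2])
        stop("planted motifs ", i, " and ", j, " collide within block ",
             spans[[i]][3])
    }
  }
  structure(list(n_species = n_species, promoter_length = promoter_length,
                 blocks = blocks, background_rate = background_rate,
                 indel_rate = indel_rate, motifs = motifs,
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

.sub_base <- function(base) {
  # substitute with a uniformly chosen different base
  alt <- lapply(DNA_BASES, function(b) setdiff(DNA_BASES, b))
  names(alt) <- DNA_BASES
  vapply(base, function(b) sample(alt[[b]], 1), "")
}

#' Simulate a multi-species promoter set with planted conserved blocks
#'
#' The reference sequence is drawn uniformly; every other species is
#' derived from it by per-site substitution (block rate inside conserved
#' blocks, background rate outside) and indels outside planted motifs.
#' Planted motif consensus sequences are written verbatim into every
#' carrying species at the same position within the block; non-carrying
#' species receive random sequence over that footprint. Deterministic for
#' a fixed seed.
#'
#' @param config A [promoter_sim_config()].
#' @return List with \code{sequences} (named character vector, species_1
#'   is the reference) and \code{truth}: block intervals per species,
#'   planted motif instances (species, consensus, start, block,
#'   norm_pos_in_block), and the config.
#' @export
simulate_promoters <- function(config) {
  set.seed(config$seed)
  L <- config$promoter_length
  species <- paste0("species_", seq_len(config$n_species))
  ref <- sample(DNA_BASES, L, replace = TRUE)
  # per-site substitution rate vector
  rate <- rep(config$background_rate, L)
  in_block <- rep(FALSE, L)
  for (b in seq_len(nrow(config$blocks))) {
    idx <- seq(config$blocks$start[b] + 1L,
               config$blocks$start[b] + config$blocks$length[b])
    rate[idx] <- config$blocks$rate[b]
    in_block[idx] <- TRUE
  }
  # plant motifs into the reference (positions are 0-based)
  motif_spans <- list()
  for (k in seq_along(config$motifs)) {
    m <- config$motifs[[k]]
    b <- config$blocks[m$block, ]
    w <- nchar(m$consensus)
    s <- b$start + round(m$rel_pos * (b$length - w))
    carriers <- m$species %||% species
    motif_spans[[k]] <- list(start = s, width = w, consensus = m$consensus,
                             carriers = carriers, block = m$block)
    if (species[1] %in% carriers)
      ref[(s + 1):(s + w)] <- strsplit(m$consensus, "")[[1]]
  }
  protect <- rep(FALSE, L)  # no indels over any motif footprint
  for (sp_ in motif_spans)
    protect[(sp_$start + 1):(sp_$start + sp_$width)] <- TRUE

  seqs <- list()
  truth_motifs <- list()
  truth_blocks <- list()
  seqs[[species[1]]] <- paste(ref, collapse = "")
  truth_blocks[[species[1]]] <- data.frame(
    start = config$blocks$start,
    end = config$blocks$start + config$blocks$length)
  for (k in seq_along(motif_spans)) {
    sp_ <- motif_spans[[k]]
    if (species[1] %in% sp_$carriers)
      truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
        species = species[1], motif = k, consensus = sp_$consensus,
        start = sp_$start, block = sp_$block)
  }

  for (si in seq(2, config$n_species)) {
    sp <- species[si]
    derived <- ref
    mut <- runif(L) < rate
    if (any(mut)) derived[mut] <- .sub_base(derived[mut])
    # rewrite motif footprints: consensus for carriers, random otherwise
    for (k in seq_along(motif_spans)) {
      m <- motif_spans[[k]]
      idx <- (m$start + 1):(m$start + m$width)
      if (sp %in% m$carriers) {
        derived[idx] <- strsplit(m$consensus, "")[[1]]
      } else {
        derived[idx] <- sample(DNA_BASES, m$width, replace = TRUE)
      }
    }
    # indels outside protected footprints: deletions or short insertions
    indel_at <- which(runif(L) < config$indel_rate & !protect)
    pieces <- as.list(derived)
    for (pos in indel_at) {
      if (runif(1) < 0.5) pieces[[pos]] <- ""           # deletion
      else pieces[[pos]] <- paste0(                      # insertion (1-3 bp)
        derived[pos],
        paste(sample(DNA_BASES, sample(1:3, 1), replace = TRUE),
              collapse = ""))
    }
    # realized coordinates after indels
    lens <- vapply(pieces, nchar, 1L)
    offset <- cumsum(c(0L, lens))[seq_len(L)]  # new 0-based pos of ref pos i-1
    seqs[[sp]] <- paste(unlist(pieces), collapse = "")
    ends0 <- config$blocks$start + config$blocks$length  # 0-based exclusive
    new_end <- ifelse(ends0 < L, offset[pmin(ends0, L - 1L) + 1L], sum(lens))
    truth_blocks[[sp]] <- data.frame(
      start = offset[config$blocks$start + 1L],
      end = new_end)
    for (k in seq_along(motif_spans)) {
      m <- motif_spans[[k]]
      if (sp %in% m$carriers)
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          species = sp, motif = k, consensus = m$consensus,
          start = offset[m$start + 1L], block = m$block)
    }
  }
  list(sequences = unlist(seqs),
       truth = list(blocks = truth_blocks,
                    motifs = do.call(rbind, truth_motifs),
                    config = config))
}

#' Simulate bulk and single-cell expression with known pass/fail truth
#'
#' Filler genes populate the transcriptome so percentile thresholds are
#' well defined; TFs in \code{expressed_set} draw bulk stage means above
#' the transcriptome's 25th percentile by construction, other TFs draw
#' below it. Single-cell counts are Poisson around cluster means, with the
#' TFs in \code{sc_expressed_set} switched on in the selected clusters.
#'
#' @param tfs Character vector of TF gene ids.
#' @param stages Bulk condition labels.
#' @param clusters Cluster ids for the single-cell data.
#' @param expressed_set TFs that should pass the bulk filter.
#' @param sc_expressed_set TFs that should also pass the single-cell
#'   filter (default: same as \code{expressed_set}).
#' @param n_filler Number of filler transcriptome genes (>= 100 advised).
#' @param cells_per_cluster Cells simulated per cluster.
#' @param seed Random seed.
#' @return List: \code{bulk} (matrix), \code{sc} (matrix),
#'   \code{cluster_labels}, \code{truth} (expected pass flags).
#' @export
simulate_expression <- function(tfs, stages = c("stage1", "stage2"),
                                clusters = c("c1", "c2"),
                                expressed_set = character(0),
                                sc_expressed_set = expressed_set,
                                n_filler = 500, cells_per_cluster = 40,
                                seed = 1L) {
  stopifnot(all(expressed_set %in% tfs), all(sc_expressed_set %in% tfs))
  if (n_filler < 100)
    warning("fewer than 100 filler genes; percentile thresholds unstable")
  set.seed(seed)
  genes <- c(tfs, paste0("filler_", seq_len(n_filler)))
  # bulk: filler spans a wide lognormal range incl. zeros
  bulk <- matrix(0, length(genes), length(stages),
                 dimnames = list(genes, stages))
  filler_means <- c(rep(0, round(n_filler * 0.2)),
                    exp(runif(n_filler - round(n_filler * 0.2),
                              log(1), log(2000))))
  filler_means <- sample(filler_means)
  for (s in seq_along(stages))
    bulk[-seq_along(tfs), s] <- filler_means * exp(runif(n_filler, -0.2, 0.2))
  q25 <- quantile(rowMeans(bulk[-seq_along(tfs), , drop = FALSE]), 0.25,
                  type = 7)
  hi <- q25 * runif(length(tfs), 4, 20) + 10
  lo <- q25 * runif(length(tfs), 0, 0.5)
  for (i in seq_along(tfs)) {
    m <- if (tfs[i] %in% expressed_set) hi[i] else lo[i]
    bulk[i, ] <- m * exp(runif(length(stages), -0.1, 0.1))
  }
  # single cell: Poisson counts per cell
  cells <- paste0("cell_", seq_len(length(clusters) * cells_per_cluster))
  cluster_labels <- setNames(rep(clusters, each = cells_per_cluster), cells)
  sc <- matrix(0L, length(genes), length(cells),
               dimnames = list(genes, cells))
  filler_sc <- exp(runif(n_filler, log(0.05), log(12)))
  for (j in seq_along(cells))
    sc[-seq_along(tfs), j] <- rpois(n_filler, filler_sc)
  for (i in seq_along(tfs)) {
    lam <- if (tfs[i] %in% sc_expressed_set) 25 else 0.02
    sc[i, ] <- rpois(length(cells), lam)
  }
  list(bulk = bulk, sc = sc, cluster_labels = cluster_labels,
       truth = data.frame(
         gene_id = tfs,
         bulk_pass = tfs %in% expressed_set,
         sc_pass = tfs %in% sc_expressed_set))
}

#' Simulate a block-structured ortholog table between two species
#'
#' A fraction (1 - noise) of pairs follow the supplied chromosome
#' correspondence map; the rest are placed uniformly at random. Scores are
#' drawn so every emitted pair is a mutual best hit (C-score 1).
#'
#' @param n_chrom_A,n_chrom_B Chromosome counts.
#' @param n_pairs Number of ortholog pairs.
#' @param correspondence_map Named vector chromosome-of-A -> chromosome-of-B
#'   (defaults to the identity map on min(n_chrom_A, n_chrom_B)).
#' @param noise_fraction Fraction of uniformly placed pairs in [0, 1].
#' @param seed Random seed.
#' @return List: \code{hits} (geneA, geneB, score), \code{chromA},
#'   \code{chromB} (named gene -> chromosome vectors), \code{truth}
#'   (the map as a data.frame).
#' @export
simulate_orthologs <- function(n_chrom_A = 19, n_chrom_B = 19,
                               n_pairs = 500, correspondence_map = NULL,
                               noise_fraction = 0, seed = 1L) {
  stopifnot(noise_fraction >= 0, noise_fraction <= 1)
  set.seed(seed)
  chrA <- paste0("A", seq_len(n_chrom_A))
  chrB <- paste0("B", seq_len(n_chrom_B))
  if (is.null(correspondence_map)) {
    k <- min(n_chrom_A, n_chrom_B)
    correspondence_map <- setNames(chrB[seq_len(k)], chrA[seq_len(k)])
  }
  gA <- paste0("ga", seq_len(n_pairs))
  gB <- paste0("gb", seq_len(n_pairs))
  mapped <- runif(n_pairs) >= noise_fraction
  ca <- character(n_pairs); cb <- character(n_pairs)
  ca[mapped] <- sample(names(correspondence_map), sum(mapped), replace = TRUE)
  cb[mapped] <- unname(correspondence_map[ca[mapped]])
  ca[!mapped] <- sample(chrA, sum(!mapped), replace = TRUE)
  cb[!mapped] <- sample(chrB, sum(!mapped), replace = TRUE)
  hits <- data.frame(geneA = gA, geneB = gB,
                     score = round(runif(n_pairs, 200, 400), 1),
                     stringsAsFactors = FALSE)
  list(hits = hits,
       chromA = setNames(ca, gA), chromB = setNames(cb, gB),
       truth = data.frame(chromA = names(correspondence_map),
                          chromB = unname(correspondence_map),
                          stringsAsFactors = FALSE))
}
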
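#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on ingestion; the id is the header token before
#' the first whitespace. Only A/C/G/T/N are accepted.
#'
#' @param path Path to a FASTA file (arbitrary line wrapping).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("non-ACGTN character in sequence '", ids[i], "' at position ",
         bad[i])
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' Coordinates are kept 0-based half-open, exactly as stored in BED.
#' Columns beyond the third are ignored; output is sorted by
#' (contig, start).
#'
#' @param path Path to a tab-separated BED file.
#' @return data.frame with columns contig, start, end.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(parts, length, 1L)
  if (any(n < 3)) stop("BED line ", which(n < 3)[1], " has fewer than 3 columns")
  contig <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinate at BED line ",
         which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop("start >= end at BED line ", bad[1])
  df <- data.frame(contig = contig, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read motif matrices in JASPAR PFM text format
#'
#' Accepts the JASPAR flat format: a header line \code{">ID name"} followed
#' by four rows \code{"A [ 1 2 3 ]"} etc. Rows may appear in any order; the
#' returned matrices always have rows A, C, G, T.
#'
#' @param path Path to a JASPAR-format text file.
#' @return Named list of 4 x W numeric count matrices (rownames A,C,G,T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) stop("JASPAR file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("JASPAR file is empty: ", path)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) stop("no '>' header lines in JASPAR file: ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) != 4)
      stop("motif '", id, "': expected 4 base rows, found ", length(body))
    base <- toupper(substr(body, 1, 1))
    if (!setequal(base, DNA_BASES))
      stop("motif '", id, "': missing base row(s): ",
           paste(setdiff(DNA_BASES, base), collapse = ", "))
    rows <- lapply(body, function(l) {
      nums <- gsub("^[ACGTacgt]\\s*\\[|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    w <- vapply(rows, length, 1L)
    if (length(unique(w)) != 1)
      stop("motif '", id, "': rows of unequal width (", paste(w, collapse = ","), ")")
    m <- do.call(rbind, rows)
    rownames(m) <- base
    m <- m[DNA_BASES, , drop = FALSE]
    if (any(m < 0)) stop("motif '", id, "': negative counts")
    if (any(colSums(m) <= 0)) stop("motif '", id, "': column with zero total")
    out[[id]] <- m
  }
  out
}

#' Read a TSV expression matrix (genes x conditions)
#'
#' First column holds gene ids; the header row holds condition labels
#' (developmental stages or cell ids).
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and condition colnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  rownames(m) <- genes
  m
}

#' Read a cell-to-cluster label table (cell_id, cluster_id TSV)
#'
#' @param path Path to a two-column TSV.
#' @return Named character vector mapping cell id to cluster id.
#' @export
read_cluster_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), df[[1]])
}

#' Read a motif-to-TF-gene mapping table (motif_id, gene_id TSV)
#'
#' A motif may map to several genes (one row per pair).
#'
#' @param path Path to a two-column TSV.
#' @return Named list: motif id -> character vector of gene ids.
#' @export
read_tf_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Extract the upstream (promoter) region of a gene
#'
#' Returns the \code{length} bases 5' of the start codon, always in
#' promoter orientation: position increases toward the start codon
#' regardless of genomic strand. Truncates at contig boundaries with a
#' warning.
#'
#' @param genome Named character vector of contig sequences.
#' @param gene List with fields gene_id, contig, start_codon_pos (0-based
#'   coordinate of the first base of the start codon) and strand.
#' @param length Number of upstream bases requested (default 5000).
#' @return List with \code{sequence} (promoter orientation) and
#'   \code{interval} (realized genomic interval, 0-based half-open).
#' @export
extract_upstream <- function(genome, gene, length = 5000L) {
  stopifnot(length > 0)
  if (!gene$contig %in% names(genome))
    stop("contig '", gene$contig, "' not found in genome for gene ",
         gene$gene_id)
  contig <- genome[[gene$contig]]
  clen <- nchar(contig)
  if (gene$strand == "+") {
    start <- max(0L, gene$start_codon_pos - length)
    end <- gene$start_codon_pos
    if (end - start < length)
      warning("upstream region of ", gene$gene_id, " truncated to ",
              end - start, " bp at contig start")
    if (end - start <= 0) stop("realized upstream length 0 for ", gene$gene_id)
    seq <- substr(contig, start + 1L, end)
  } else {
    start <- gene$start_codon_pos + 1L
    end <- min(clen, start + length)
    if (end - start < length)
      warning("upstream region of ", gene$gene_id, " truncated to ",
              end - start, " bp at contig end")
    if (end - start <= 0) stop("realized upstream length 0 for ", gene$gene_id)
    seq <- revcomp(substr(contig, start + 1L, end))
  }
  list(sequence = seq,
       interval = interval(gene$contig, start, end, gene$strand))
}
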
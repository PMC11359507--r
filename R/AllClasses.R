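#' @useDynLib phamkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## PhageGenome
## ---------------------------------------------------------------------------

#' Empty gene table
#'
#' Canonical zero-row gene table used by [PhageGenome()]. Coordinates are
#' 0-based half-open on the forward strand throughout the package; conversion
#' to the 1-based inclusive convention of GenBank/GFF3 happens only at I/O
#' boundaries.
#'
#' @return data.frame with the gene-table columns and zero rows.
#' @export
emptyGeneTable <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), translation = character(0),
             pham_id = character(0), product = character(0),
             stringsAsFactors = FALSE)
}

.GENE_COLS <- c("gene_id", "start", "end", "strand", "translation",
                "pham_id", "product")

#' PhageGenome: an annotated phage genome
#'
#' S4 container for one phage genome: its nucleotide sequence (uppercase
#' A/C/G/T only -- sequences with ambiguity characters are rejected at
#' construction, mirroring the dataset filter applied upstream of all
#' similarity metrics), a circularity flag, an ordered table of
#' protein-coding genes, and free-form metadata (host, accession, ...).
#'
#' Gene coordinates are 0-based half-open intervals on the forward strand
#' (`0 <= start < end <= length(sequence)`), rows sorted by `start`.
#' Minus-strand genes store the translation of the reverse complement.
#'
#' @slot genomeId character scalar, unique within a dataset.
#' @slot sequence character scalar over A/C/G/T.
#' @slot circular logical scalar.
#' @slot genes data.frame with columns gene_id, start, end, strand
#'   (`"+"`/`"-"`), translation, pham_id (NA until phams are built), product.
#' @slot metadata named list of scalar annotations.
#' @export
setClass("PhageGenome",
  representation(genomeId = "character", sequence = "character",
                 circular = "logical", genes = "data.frame",
                 metadata = "list"),
  prototype(genomeId = NA_character_, sequence = "", circular = FALSE,
            genes = emptyGeneTable(), metadata = list()))

setValidity("PhageGenome", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1 || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a non-empty string")
  if (length(object@sequence) != 1)
    msg <- c(msg, "sequence must be a single string")
  else if (grepl("[^ACGT]", object@sequence))
    msg <- c(msg, "sequence contains non-TCGA characters")
  if (length(object@circular) != 1 || is.na(object@circular))
    msg <- c(msg, "circular must be TRUE or FALSE")
  g <- object@genes
  if (!all(.GENE_COLS %in% names(g))) {
    msg <- c(msg, paste("genes must have columns:",
                        paste(.GENE_COLS, collapse = ", ")))
  } else if (nrow(g) > 0) {
    L <- nchar(object@sequence)
    if (any(g$start < 0 | g$end <= g$start | g$end > L))
      msg <- c(msg, "gene intervals must satisfy 0 <= start < end <= length")
    if (is.unsorted(g$start))
      msg <- c(msg, "genes must be sorted by start")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(is.na(g$translation) | !nzchar(g$translation)))
      msg <- c(msg, "every gene needs a non-empty translation")
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "gene_id values must be unique within a genome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhageGenome
#'
#' @param genomeId genome identifier, unique within a dataset.
#' @param sequence nucleotide sequence (will be uppercased). Characters
#'   outside A/C/G/T raise an error.
#' @param circular is the assembly circular?
#' @param genes gene table (see [emptyGeneTable()] for the schema);
#'   rows are re-sorted by start.
#' @param metadata named list of annotations.
#' @return a validated [PhageGenome-class] object.
#' @export
#' @examples
#' PhageGenome("toy", "ATGAAATAA")
PhageGenome <- function(genomeId, sequence, circular = FALSE,
                        genes = emptyGeneTable(), metadata = list()) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
    stop("genome '", genomeId, "' rejected: sequence contains non-TCGA ",
         "characters (", paste(bad, collapse = ", "), ")")
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in setdiff(.GENE_COLS, names(genes))) genes[[col]] <- NA_character_
  genes <- genes[.GENE_COLS]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes) > 0) {
    genes <- genes[order(genes$start, genes$end, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  new("PhageGenome", genomeId = genomeId, sequence = sequence,
      circular = isTRUE(circular), genes = genes,
      metadata = as.list(metadata))
}

## ---------------------------------------------------------------------------
## PhamSet
## ---------------------------------------------------------------------------

#' PhamSet: a partition of genes into phamilies
#'
#' Holds the assignment of every gene in a dataset to exactly one pham
#' (gene phamily: a single-linkage homology class over thresholded pairwise
#' protein similarity). A pham with one member is an "orpham".
#'
#' @slot assignments data.frame with columns pham_id, genome_id, gene_id,
#'   aa_length; one row per gene.
#' @slot representatives data.frame with columns pham_id, genome_id, gene_id,
#'   translation; the longest member of each pham (ties broken by the
#'   lexicographically smallest `genome_id:gene_id` key).
#' @slot parameters named list echoing the thresholds used to build the set.
#' @export
setClass("PhamSet",
  representation(assignments = "data.frame", representatives = "data.frame",
                 parameters = "list"))

setValidity("PhamSet", function(object) {
  a <- object@assignments
  msg <- character(0)
  need <- c("pham_id", "genome_id", "gene_id", "aa_length")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("assignments needs columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(paste(a$genome_id, a$gene_id, sep = ":")))
      msg <- c(msg, "each gene must belong to exactly one pham")
    if (any(is.na(a$pham_id) | !nzchar(a$pham_id)))
      msg <- c(msg, "pham_id must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' SimilarityMatrix: symmetric pairwise genome similarity
#'
#' Dense symmetric matrix of one similarity metric on the 0-100 scale, with
#' 100 on the diagonal (self-comparison). Row/column names are genome ids.
#'
#' @slot metric one of "peq", "gcs", "aai", "gni".
#' @slot values numeric matrix with dimnames.
#' @export
setClass("SimilarityMatrix",
  representation(metric = "character", values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (is.null(dimnames(v)) || is.null(rownames(v)) ||
      !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must have identical row and column genome ids")
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (anyNA(v) || any(v < -1e-9) || any(v > 100 + 1e-9))
    msg <- c(msg, "values must lie in [0, 100]")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (nrow(v) > 0 && max(abs(diag(v) - 100)) > 1e-8)
    msg <- c(msg, "diagonal must equal 100")
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square numeric matrix with genome ids as dimnames.
#' @param metric metric name ("peq", "gcs", "aai", or "gni").
#' @return a validated [SimilarityMatrix-class].
#' @export
SimilarityMatrix <- function(values, metric) {
  new("SimilarityMatrix", metric = metric, values = values)
}
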
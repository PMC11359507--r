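## Pham assembly: k-mer prefilter + alignment verification + single-linkage
## closure. Candidate pairs are pairs of proteins whose k-mer-set Jaccard
## similarity reaches min_kmer_jaccard; candidates are verified by global
## alignment (proteinIdentity) against identity and coverage thresholds,
## and phams are the connected components of the verified-edge graph.

#' Assort proteins into phamilies (phams)
#'
#' @param x a list of [PhageGenome-class] objects, or a data.frame with
#'   columns genome_id, gene_id, translation.
#' @param minIdentity minimum pairwise identity for a verified edge
#'   (fraction, default 0.35).
#' @param minCoverage minimum coverage of the shorter sequence (fraction,
#'   default 0.80).
#' @param kmerSize k-mer length for the prefilter (default 5).
#' @param minKmerJaccard minimum k-mer-set Jaccard for a candidate pair
#'   (default 0.05). Set to 0 to disable the prefilter and align all
#'   pairs.
#' @return a [PhamSet-class]. Pham ids are assigned deterministically:
#'   connected components are ordered by their lexicographically smallest
#'   `genome_id:gene_id` member key and numbered from 1 (`pham_1`, ...),
#'   so shuffling the input order changes no assignment.
#' @details Single-linkage (connected-component) closure is used rather
#'   than centroid clustering: pham membership is a transitive
#'   "related-to" notion, so two proteins joined through an intermediate
#'   belong together even when their direct identity is below threshold.
#' @export
#' @examples
#' gs <- simulateDataset(simulationSpec(nClusters = 2, genomesPerCluster = 2,
#'                                      phamsPerGenome = 5))$genomes
#' buildPhams(gs)
buildPhams <- function(x, minIdentity = 0.35, minCoverage = 0.80,
                       kmerSize = 5L, minKmerJaccard = 0.05) {
  if (minIdentity <= 0 || minIdentity > 1 || minCoverage <= 0 ||
      minCoverage > 1)
    stop("minIdentity and minCoverage must lie in (0, 1]")
  tab <- .geneTableFrom(x)
  if (nrow(tab) == 0) stop("no genes to assort into phams")
  key <- paste(tab$genome_id, tab$gene_id, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate (genome_id, gene_id) pairs in input")
  n <- nrow(tab)

  cand <- .candidatePairs(tab$translation, kmerSize, minKmerJaccard)
  edges <- .verifyPairs(cand, tab$translation, minIdentity, minCoverage)

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  comp <- igraph::components(g)$membership

  # deterministic numbering: order components by smallest member key
  min_key <- tapply(key, comp, min)
  ord <- order(min_key)
  renum <- integer(length(min_key))
  renum[as.integer(names(min_key))[ord]] <- seq_along(ord)
  pham_id <- sprintf("pham_%d", renum[comp])

  assignments <- data.frame(pham_id = pham_id, genome_id = tab$genome_id,
                            gene_id = tab$gene_id,
                            aa_length = nchar(tab$translation),
                            stringsAsFactors = FALSE)
  reps <- .pickRepresentatives(assignments, tab$translation, key)
  new("PhamSet", assignments = assignments, representatives = reps,
      parameters = list(minIdentity = minIdentity, minCoverage = minCoverage,
                        kmerSize = kmerSize,
                        minKmerJaccard = minKmerJaccard))
}

.geneTableFrom <- function(x) {
  if (is.data.frame(x)) {
    need <- c("genome_id", "gene_id", "translation")
    if (!all(need %in% names(x)))
      stop("gene table needs columns: ", paste(need, collapse = ", "))
    return(x[need])
  }
  if (is(x, "PhageGenome")) x <- list(x)
  tabs <- lapply(x, function(g) {
    gn <- genes(g)
    data.frame(genome_id = rep(genomeId(g), nrow(gn)),
               gene_id = gn$gene_id, translation = gn$translation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

## Candidate pairs by k-mer-set Jaccard, via a sparse kmer-by-gene
## incidence matrix: crossprod gives shared-kmer counts for all pairs at
## once. Returns a data.frame(i, j) with i < j (row indices into the gene
## table).
.candidatePairs <- function(translations, kmerSize, minKmerJaccard) {
  n <- length(translations)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  if (minKmerJaccard <= 0) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(data.frame(i = idx[, 1], j = idx[, 2]))
  }
  kms <- lapply(translations, function(s) {
    L <- nchar(s)
    if (L < kmerSize) return(character(0))
    unique(substring(s, 1:(L - kmerSize + 1L), kmerSize:L))
  })
  sizes <- lengths(kms)
  all_k <- unique(unlist(kms, use.names = FALSE))
  if (length(all_k) == 0) return(data.frame(i = integer(0), j = integer(0)))
  M <- Matrix::sparseMatrix(
    i = match(unlist(kms, use.names = FALSE), all_k),
    j = rep.int(seq_len(n), sizes), x = 1,
    dims = c(length(all_k), n))
  S <- Matrix::crossprod(M)            # shared k-mer counts, gene x gene
  tri <- Matrix::summary(S)
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  if (nrow(tri) == 0) return(data.frame(i = integer(0), j = integer(0)))
  jac <- tri$x / (sizes[tri$i] + sizes[tri$j] - tri$x)
  keep <- jac >= minKmerJaccard
  data.frame(i = tri$i[keep], j = tri$j[keep])
}

## Verify candidate pairs by alignment, in one elementwise batch.
.verifyPairs <- function(cand, translations, minIdentity, minCoverage) {
  if (nrow(cand) == 0) return(data.frame(i = integer(0), j = integer(0)))
  res <- .proteinIdentityPairs(translations[cand$i], translations[cand$j])
  ok <- res[, "identity"] >= minIdentity & res[, "coverage"] >= minCoverage
  cand[ok, , drop = FALSE]
}

.pickRepresentatives <- function(assignments, translations, key) {
  len <- nchar(translations)
  reps <- lapply(split(seq_len(nrow(assignments)), assignments$pham_id),
                 function(idx) {
    best <- idx[order(-len[idx], key[idx])][1]
    data.frame(pham_id = assignments$pham_id[best],
               genome_id = assignments$genome_id[best],
               gene_id = assignments$gene_id[best],
               translation = translations[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out[order(out$pham_id), , drop = FALSE]
}

#' Attach pham assignments to genomes
#'
#' Fills the `pham_id` column of each genome's gene table from a
#' [PhamSet-class].
#'
#' @param genomes list of [PhageGenome-class].
#' @param phams a [PhamSet-class].
#' @return the list of genomes with pham ids set.
#' @export
assignPhams <- function(genomes, phams) {
  stopifnot(is(phams, "PhamSet"))
  a <- phamTable(phams)
  lookup <- setNames(a$pham_id, paste(a$genome_id, a$gene_id, sep = ":"))
  lapply(genomes, function(g) {
    gn <- genes(g)
    gn$pham_id <- unname(lookup[paste(genomeId(g), gn$gene_id, sep = ":")])
    genes(g) <- gn
    g
  })
}

#' Write pham outputs
#'
#' Writes the pham table as TSV (pham_id, genome_id, gene_id) and the
#' representative sequences as protein FASTA.
#'
#' @param phams a [PhamSet-class].
#' @param tablePath output TSV path.
#' @param fastaPath optional output FASTA path for representatives.
#' @return `tablePath`, invisibly.
#' @export
writePhamTable <- function(phams, tablePath, fastaPath = NULL) {
  a <- phamTable(phams)
  write.table(a[c("pham_id", "genome_id", "gene_id")], tablePath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fastaPath)) {
    r <- representatives(phams)
    ss <- Biostrings::AAStringSet(setNames(r$translation, r$pham_id))
    Biostrings::writeXStringSet(ss, fastaPath, width = 70L)
  }
  invisible(tablePath)
}
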
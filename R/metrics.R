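## Pairwise genome similarity metrics, all on a 0-100 scale:
##   gcs  - gene content similarity: mean over both genomes of the fraction
##          of genes whose pham occurs in the partner;
##   aai  - length-weighted amino-acid identity of shared homologues;
##   peq  - proteomic equivalence quotient: length-weighted shared identity
##          normalized over ALL genes of both genomes, so every unshared
##          gene contributes identity 0;
##   gni  - genome-wide nucleotide identity from seed-and-extend HSPs,
##          identities summed over both genomes' resolved coverage and
##          normalized by the two genome lengths.

.phamLookup <- function(phams) {
  a <- phamTable(phams)
  setNames(a$pham_id, paste(a$genome_id, a$gene_id, sep = ":"))
}

.genePhams <- function(genome, lookup) {
  gn <- genes(genome)
  if (nrow(gn) == 0)
    stop("genome '", genomeId(genome), "' has no genes")
  ph <- unname(lookup[paste(genomeId(genome), gn$gene_id, sep = ":")])
  if (all(is.na(ph)))
    stop("genome '", genomeId(genome),
         "' has no pham-assigned genes; run buildPhams() first")
  list(pham = ph, gene_id = gn$gene_id, translation = gn$translation,
       aa_len = nchar(gn$translation))
}

#' Gene content similarity (GCS)
#'
#' The fraction of each genome's genes whose pham also occurs in the
#' partner genome, averaged over both directions and expressed as a
#' percentage. Averaging makes the measure symmetric even when the two
#' genomes have different gene counts.
#'
#' @param a,b [PhageGenome-class] objects with pham-assigned genes.
#' @param phams the [PhamSet-class] covering both genomes.
#' @return percentage in \[0, 100\].
#' @export
gcs <- function(a, b, phams) {
  lookup <- .phamLookup(phams)
  ga <- .genePhams(a, lookup); gb <- .genePhams(b, lookup)
  sA <- sum(ga$pham %in% gb$pham, na.rm = TRUE)
  sB <- sum(gb$pham %in% ga$pham, na.rm = TRUE)
  100 * (sA / length(ga$pham) + sB / length(gb$pham)) / 2
}

## Pair homologues within each shared pham: greedy best-identity bipartite
## matching (paralogs beyond the smaller copy number stay unpaired), ties
## broken by gene_id lexicographic order. Returns data.frame(weight =
## summed aa length of the pair, identity).
.pairedHomologues <- function(ga, gb) {
  shared <- intersect(ga$pham[!is.na(ga$pham)], gb$pham[!is.na(gb$pham)])
  if (length(shared) == 0)
    return(data.frame(weight = numeric(0), identity = numeric(0)))
  # batch all cross-genome within-pham alignments into one call
  ia_list <- lapply(shared, function(p) which(ga$pham == p))
  ib_list <- lapply(shared, function(p) which(gb$pham == p))
  grid <- do.call(rbind, lapply(seq_along(shared), function(k)
    cbind(k, expand.grid(i = ia_list[[k]], j = ib_list[[k]]))))
  ids <- .proteinIdentityPairs(ga$translation[grid$i],
                               gb$translation[grid$j])[, "identity"]
  out <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    ia <- ia_list[[k]]
    ib <- ib_list[[k]]
    rows <- which(grid$k == k)
    idm <- matrix(NA_real_, length(ia), length(ib))
    idm[cbind(match(grid$i[rows], ia), match(grid$j[rows], ib))] <-
      ids[rows]
    pairs <- list()
    availA <- rep(TRUE, length(ia)); availB <- rep(TRUE, length(ib))
    for (step in seq_len(min(length(ia), length(ib)))) {
      sub <- idm
      sub[!availA, ] <- -Inf; sub[, !availB] <- -Inf
      best <- max(sub)
      cand <- which(sub == best, arr.ind = TRUE)
      # tie-break: smallest a-side gene_id, then b-side gene_id
      ordc <- order(ga$gene_id[ia[cand[, 1]]], gb$gene_id[ib[cand[, 2]]])
      ri <- cand[ordc[1], 1]; ci <- cand[ordc[1], 2]
      pairs[[step]] <- c(
        weight = ga$aa_len[ia[ri]] + gb$aa_len[ib[ci]],
        identity = idm[ri, ci])
      availA[ri] <- FALSE; availB[ci] <- FALSE
    }
    out[[k]] <- do.call(rbind, pairs)
  }
  as.data.frame(do.call(rbind, out))
}

#' Amino-acid identity of shared homologues (AAI)
#'
#' For each pham present in both genomes, member genes are paired by
#' greedy best-identity bipartite matching (leftover paralog copies stay
#' unpaired); AAI is the length-weighted mean identity of the paired
#' homologues, as a percentage, with weights equal to the summed
#' amino-acid length of each pair.
#'
#' @inheritParams gcs
#' @return list with elements `aai` (percent) and `sharedWeight` (summed
#'   amino-acid length of all paired homologues); `(0, 0)` when the
#'   genomes share no pham.
#' @export
aaiShared <- function(a, b, phams) {
  lookup <- .phamLookup(phams)
  ga <- .genePhams(a, lookup); gb <- .genePhams(b, lookup)
  pr <- .pairedHomologues(ga, gb)
  if (nrow(pr) == 0) return(list(aai = 0, sharedWeight = 0))
  list(aai = 100 * sum(pr$weight * pr$identity) / sum(pr$weight),
       sharedWeight = sum(pr$weight))
}

#' Proteomic equivalence quotient (PEQ)
#'
#' A single 0-100 value combining shared-gene proportion with the
#' amino-acid identity of shared homologues:
#' \deqn{PEQ = 100 \frac{\sum_{pairs} (l_a + l_b)\, id}{\sum_{all\ genes} l}}
#' where the sum in the numerator runs over paired homologues (as in
#' [aaiShared()]) and the denominator over every gene of both genomes.
#' Every unshared gene therefore contributes identity 0: PEQ is 100
#' exactly when the proteomes are identical under the pairing and 0
#' exactly when no pham is shared.
#'
#' @inheritParams gcs
#' @return percentage in \[0, 100\].
#' @export
peq <- function(a, b, phams) {
  lookup <- .phamLookup(phams)
  ga <- .genePhams(a, lookup); gb <- .genePhams(b, lookup)
  pr <- .pairedHomologues(ga, gb)
  total <- sum(ga$aa_len) + sum(gb$aa_len)
  if (nrow(pr) == 0) return(0)
  100 * sum(pr$weight * pr$identity) / total
}

#' Genome-wide nucleotide identity (gNI)
#'
#' Runs [findHsps()] with each genome as query and as subject, projects
#' all passing HSPs onto each genome, resolves overlapping projections by
#' keeping higher-identity fragments, sums the identical bases per genome,
#' and normalizes by the two genome lengths:
#' `gNI = 100 * (id_a + id_b) / (len_a + len_b)`. Symmetric by
#' construction; exactly 0 when no HSP passes the E-value filter ("no
#' detectable nucleotide similarity").
#'
#' @param a,b [PhageGenome-class] objects with non-empty sequences.
#' @param evalueMax HSP E-value cutoff (default 1e-4).
#' @param wordSize seed length passed to [findHsps()].
#' @return percentage in \[0, 100\].
#' @export
gni <- function(a, b, evalueMax = 1e-4, wordSize = 11L) {
  sa <- genomeSeq(a); sb <- genomeSeq(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("genome sequences must be non-empty")
  h_ab <- findHsps(sa, sb, wordSize = wordSize, evalueMax = evalueMax)
  h_ba <- findHsps(sb, sa, wordSize = wordSize, evalueMax = evalueMax)
  segsA <- rbind(
    data.frame(start = h_ab$q_start, end = h_ab$q_end,
               identities = h_ab$identities),
    data.frame(start = h_ba$s_start, end = h_ba$s_end,
               identities = h_ba$identities))
  segsB <- rbind(
    data.frame(start = h_ba$q_start, end = h_ba$q_end,
               identities = h_ba$identities),
    data.frame(start = h_ab$s_start, end = h_ab$s_end,
               identities = h_ab$identities))
  idA <- .resolvedIdentities(segsA)
  idB <- .resolvedIdentities(segsB)
  100 * (idA + idB) / (nchar(sa) + nchar(sb))
}

## Overlap resolution: visit segments by identity fraction (desc); each
## segment contributes its identities prorated to the part of it not yet
## covered by a better segment.
.resolvedIdentities <- function(segs) {
  if (nrow(segs) == 0) return(0)
  len <- segs$end - segs$start
  frac <- segs$identities / len
  ord <- order(-frac, segs$start)
  covered <- IRanges::IRanges()
  total <- 0
  for (k in ord) {
    ir <- IRanges::IRanges(start = segs$start[k] + 1L, end = segs$end[k])
    uncov <- IRanges::setdiff(ir, covered)
    w <- sum(IRanges::width(uncov))
    if (w > 0) {
      total <- total + segs$identities[k] * w / len[k]
      covered <- IRanges::union(covered, ir)
    }
  }
  total
}

#' Pairwise similarity matrix for a genome dataset
#'
#' Computes the upper triangle of the chosen metric for every genome pair,
#' mirrors it, and sets the diagonal to 100.
#'
#' @param genomes list of [PhageGenome-class] with unique ids (>= 2).
#' @param metric one of `"peq"`, `"gcs"`, `"aai"`, `"gni"`.
#' @param phams a [PhamSet-class]; required for peq/gcs/aai.
#' @param evalueMax,wordSize passed to [gni()].
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseMatrix <- function(genomes, metric = c("peq", "gcs", "aai", "gni"),
                           phams = NULL, evalueMax = 1e-4, wordSize = 11L) {
  metric <- match.arg(metric)
  ids <- vapply(genomes, genomeId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(genomes) < 2) stop("need at least 2 genomes")
  if (metric != "gni" && is.null(phams))
    stop("metric '", metric, "' requires a PhamSet")
  n <- length(genomes)
  v <- matrix(100, n, n, dimnames = list(ids, ids))
  pairFun <- switch(metric,
    peq = function(a, b) peq(a, b, phams),
    gcs = function(a, b) gcs(a, b, phams),
    aai = function(a, b) aaiShared(a, b, phams)$aai,
    gni = function(a, b) gni(a, b, evalueMax = evalueMax,
                             wordSize = wordSize))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      val <- pairFun(genomes[[i]], genomes[[j]])
      v[i, j] <- val
      v[j, i] <- val
    }
  }
  SimilarityMatrix(v, metric)
}

#' Write a similarity matrix as TSV
#'
#' Emits a long-form table (genome_a, genome_b, value; upper triangle
#' only) and a square matrix with genome ids as header row/column, both
#' with 2 decimals.
#'
#' @param mat a [SimilarityMatrix-class].
#' @param longPath path for the long-form TSV (or NULL to skip).
#' @param matrixPath path for the square TSV (or NULL to skip).
#' @return invisibly, the long-form data.frame.
#' @export
writeSimilarity <- function(mat, longPath = NULL, matrixPath = NULL) {
  v <- simValues(mat)
  ids <- rownames(v)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  long <- data.frame(genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
                     value = sprintf("%.2f", v[idx]),
                     stringsAsFactors = FALSE)
  if (!is.null(longPath))
    write.table(long, longPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(matrixPath)) {
    sq <- matrix(sprintf("%.2f", v), nrow(v), dimnames = dimnames(v))
    write.table(sq, matrixPath, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(long)
}

#' Read a square similarity matrix TSV back
#'
#' @param path TSV written by [writeSimilarity()].
#' @param metric metric label for the resulting object.
#' @return a [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, metric) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  v <- as.matrix(tab)
  # symmetrize away rounding asymmetry from the 2-decimal serialization
  v <- (v + t(v)) / 2
  diag(v) <- 100
  SimilarityMatrix(v, metric)
}
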
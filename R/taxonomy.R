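## Hierarchical (ICTV-style) taxonomy handling: gap-filling of missing
## higher ranks and concordance between a similarity matrix and the
## taxonomic grouping at each rank.
##
## Ranks, lowest to highest: species, genus, subfamily, family. The
## hierarchy means co-membership at a lower rank implies co-membership at
## every higher rank, even when the higher taxon has not been named; gap
## filling makes that implication explicit with deterministic placeholder
## names so pair enumeration at each rank is well defined.

TAX_RANKS <- c("species", "genus", "subfamily", "family")

#' Read a taxonomy table
#'
#' @param path TSV with header genome_id, species, genus, subfamily,
#'   family; empty fields mean unknown.
#' @return data.frame with NA for unknown ranks.
#' @export
readTaxonomy <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("genome_id", TAX_RANKS)
  if (!all(need %in% names(tab)))
    stop("taxonomy table needs columns: ", paste(need, collapse = ", "))
  for (r in TAX_RANKS) tab[[r]][!nzchar(trimws(tab[[r]]))] <- NA_character_
  tab[need]
}

.placeholderName <- function(rank, child) {
  base <- sub("^unnamed_[a-z]+_", "", child)
  paste0("unnamed_", rank, "_", base)
}

#' Gap-fill missing higher taxonomic ranks
#'
#' For every named taxon at rank r whose parent at rank r+1 is unnamed, a
#' deterministic placeholder parent (`unnamed_<rank>_<taxon>`) is created,
#' so that two genomes sharing a taxon at any rank also share (possibly
#' placeholder) taxa at all higher ranks. Parents already named elsewhere
#' in the table are reused; given names are never overwritten. The
#' operation is idempotent.
#'
#' @param tax data.frame with columns genome_id, species, genus,
#'   subfamily, family (NA = unknown), e.g. from [readTaxonomy()].
#' @return the gap-filled data.frame, with added `<rank>_src` columns
#'   recording per-rank provenance: `"given"`, `"gap_filled"`, or
#'   `"none"`.
#' @export
#' @examples
#' tax <- data.frame(genome_id = c("p1", "p2"),
#'                   species = NA, genus = c("Fromanvirus", "Fromanvirus"),
#'                   subfamily = NA, family = NA)
#' gapfillRanks(tax)[, c("genus", "subfamily", "family")]
gapfillRanks <- function(tax) {
  for (r in TAX_RANKS)
    if (!r %in% names(tax)) stop("taxonomy table lacks rank column: ", r)
  src <- lapply(TAX_RANKS, function(r)
    ifelse(is.na(tax[[r]]), "none", "given"))
  names(src) <- TAX_RANKS
  for (k in seq_len(length(TAX_RANKS) - 1)) {
    child_rank <- TAX_RANKS[k]; parent_rank <- TAX_RANKS[k + 1]
    child <- tax[[child_rank]]; parent <- tax[[parent_rank]]
    # map each named child taxon to its unique named parent, if any
    known <- !is.na(child) & !is.na(parent)
    map <- list()
    for (i in which(known)) {
      prev <- map[[child[i]]]
      if (!is.null(prev) && prev != parent[i])
        stop("taxonomy inconsistency: ", child_rank, " '", child[i],
             "' is assigned to two different ", parent_rank, " taxa ('",
             prev, "' and '", parent[i], "')")
      map[[child[i]]] <- parent[i]
    }
    fill <- which(!is.na(child) & is.na(parent))
    for (i in fill) {
      mapped <- map[[child[i]]]
      tax[[parent_rank]][i] <- if (!is.null(mapped)) mapped
        else .placeholderName(parent_rank, child[i])
      src[[parent_rank]][i] <- "gap_filled"
    }
  }
  for (r in TAX_RANKS) tax[[paste0(r, "_src")]] <- src[[r]]
  tax
}

.pairIndex <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Similarity values for intra-rank genome pairs
#'
#' Returns the matrix values for exactly the unordered pairs of genomes
#' co-assigned (named or placeholder) at the given rank; self-pairs are
#' excluded, and genomes with no assignment at the rank pair with no one.
#'
#' @param mat a [SimilarityMatrix-class].
#' @param tax gap-filled taxonomy (see [gapfillRanks()]) covering every
#'   genome in `mat`.
#' @param rank one of `"species"`, `"genus"`, `"subfamily"`, `"family"`.
#' @return numeric vector of similarity values, named `"a|b"` by the pair
#'   of genome ids. Length equals the sum over taxa of `choose(n_t, 2)`.
#' @export
intraRankValues <- function(mat, tax, rank = TAX_RANKS) {
  rank <- match.arg(rank)
  v <- simValues(mat)
  ids <- rownames(v)
  missing <- setdiff(ids, tax$genome_id)
  if (length(missing))
    stop("genomes missing from taxonomy: ", paste(missing, collapse = ", "))
  taxon <- tax[[rank]][match(ids, tax$genome_id)]
  if (length(ids) < 2) return(setNames(numeric(0), character(0)))
  idx <- .pairIndex(length(ids))
  same <- !is.na(taxon[idx[, 1]]) & !is.na(taxon[idx[, 2]]) &
    taxon[idx[, 1]] == taxon[idx[, 2]]
  idx <- idx[same, , drop = FALSE]
  setNames(v[idx], paste(ids[idx[, 1]], ids[idx[, 2]], sep = "|"))
}

#' Concordance between similarity and taxonomic ranks
#'
#' For each rank, collects the similarity values of intra-rank genome
#' pairs and summarizes them: pair count, fraction of pairs at or above
#' 50 (the informal genus-level nucleotide-identity threshold), fraction
#' exactly 0 (no detectable similarity), and a histogram with bin edges
#' \[0,5), \[5,10), ..., \[95,100\]. When a second matrix is supplied, a
#' least-squares fit of `peqMat` against `mat` over all genome pairs is
#' added (slope, intercept, Pearson R squared), the comparison behind the
#' PEQ-versus-gNI landscape.
#'
#' @param mat a [SimilarityMatrix-class] (conventionally gNI).
#' @param tax gap-filled taxonomy covering every genome in `mat`.
#' @param peqMat optional second [SimilarityMatrix-class] (conventionally
#'   PEQ) on the same genomes.
#' @return list with elements `summary` (data.frame: rank, n_pairs,
#'   frac_ge_50, frac_zero), `histograms` (data.frame: rank, bin_lo,
#'   bin_hi, count), and -- when `peqMat` is given -- `scatter`
#'   (data.frame: genome_a, genome_b, x, y) and `fit` (list: slope,
#'   intercept, r_squared, n).
#' @export
concordanceSummary <- function(mat, tax, peqMat = NULL) {
  summaries <- list(); hists <- list()
  for (r in TAX_RANKS) {
    vals <- intraRankValues(mat, tax, r)
    n <- length(vals)
    summaries[[r]] <- data.frame(
      rank = r, n_pairs = n,
      frac_ge_50 = if (n) mean(vals >= 50) else NA_real_,
      frac_zero = if (n) mean(vals == 0) else NA_real_,
      stringsAsFactors = FALSE)
    bin <- pmin(floor(vals / 5) + 1L, 20L)   # values of 100 fold into [95,100]
    counts <- tabulate(bin, nbins = 20L)
    hists[[r]] <- data.frame(rank = r, bin_lo = seq(0, 95, 5),
                             bin_hi = seq(5, 100, 5), count = counts,
                             stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, c(summaries,
                                         list(make.row.names = FALSE))),
              histograms = do.call(rbind, c(hists,
                                            list(make.row.names = FALSE))))
  if (!is.null(peqMat)) {
    vx <- simValues(mat); vy <- simValues(peqMat)
    if (!identical(rownames(vx), rownames(vy)))
      stop("the two matrices must cover the same genomes in the same order")
    ids <- rownames(vx)
    idx <- .pairIndex(length(ids))
    x <- vx[idx]; y <- vy[idx]
    fit <- lm(y ~ x)
    out$scatter <- data.frame(genome_a = ids[idx[, 1]],
                              genome_b = ids[idx[, 2]], x = x, y = y,
                              stringsAsFactors = FALSE)
    out$fit <- list(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    r_squared = cor(x, y)^2, n = length(x))
  }
  out
}
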
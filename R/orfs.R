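#' Call open reading frames de novo
#'
#' A deliberately transparent six-frame ORF caller: it scans all six reading
#' frames for maximal ORFs (start codon in ATG/GTG/TTG, stop in
#' TAA/TAG/TGA, translation table 11), keeps ORFs of at least `minAa`
#' amino acids, and resolves nested ORFs by keeping the longest ORF per
#' stop codon (i.e., the leftmost usable start upstream of each stop).
#' There is no ribosome-binding-site scoring and no model training; output
#' is deterministic for a fixed input. ORFs do not wrap the origin of
#' circular genomes.
#'
#' The gene interval includes the stop codon, so the translation has
#' `(end - start)/3 - 1` residues. Start codons translate to M.
#'
#' @param genome a [PhageGenome-class]; existing genes are discarded.
#' @param minAa minimum translation length in amino acids (>= 10).
#' @return a copy of `genome` with `genes` replaced by the called ORFs
#'   (ids `orf_1`, `orf_2`, ... in genome order). Zero ORFs is a valid
#'   outcome.
#' @export
#' @examples
#' g <- PhageGenome("toy", paste0("ATG", strrep("GCT", 40), "TAA"))
#' nrow(genes(callOrfs(g, minAa = 30)))
callOrfs <- function(genome, minAa = 30L) {
  stopifnot(is(genome, "PhageGenome"))
  if (minAa < 10) stop("minAa must be >= 10")
  seq <- genomeSeq(genome)
  L <- nchar(seq)
  if (L == 0) stop("genome sequence is empty")

  rows <- rbind(.scanFrames(seq, L, reverse = FALSE, minAa = minAa),
                .scanFrames(revComp(seq), L, reverse = TRUE, minAa = minAa))
  if (is.null(rows) || nrow(rows) == 0) {
    out <- genome
    out@genes <- emptyGeneTable()
    return(out)
  }
  rows <- rows[order(rows$start, rows$end), , drop = FALSE]
  rows$gene_id <- sprintf("orf_%d", seq_len(nrow(rows)))
  rows$pham_id <- NA_character_
  rows$product <- NA_character_
  rownames(rows) <- NULL
  out <- genome
  out@genes <- rows[.GENE_COLS]
  validObject(out)
  out
}

## Scan the three forward frames of `s`. When reverse = TRUE, `s` is the
## reverse complement and intervals are mapped back to forward coordinates.
.scanFrames <- function(s, L, reverse, minAa) {
  gc <- geneticCode11()
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < minAa + 1L) next
    at <- seq.int(f + 1L, by = 3L, length.out = n_cod)
    codons <- substring(s, at, at + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% START_CODONS
    stop_idx <- which(is_stop)
    start_idx <- which(is_start)
    if (length(stop_idx) == 0 || length(start_idx) == 0) next
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    for (k in seq_along(stop_idx)) {
      # leftmost start strictly after the previous stop -> longest ORF
      cand <- start_idx[start_idx > prev_stop[k] & start_idx < stop_idx[k]]
      if (length(cand) == 0) next
      s_i <- cand[1]
      aa_len <- stop_idx[k] - s_i
      if (aa_len < minAa) next
      aa <- unname(gc[codons[s_i:(stop_idx[k] - 1L)]])
      aa[1] <- "M"
      a <- f + 3L * (s_i - 1L)          # 0-based start incl. start codon
      b <- f + 3L * stop_idx[k]         # 0-based end incl. stop codon
      if (reverse) {
        tmp <- a; a <- L - b; b <- L - tmp
      }
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, strand = if (reverse) "-" else "+",
        translation = paste(aa, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Rotate a circular genome to a new origin
#'
#' Re-establishes coordinate 0 at the start of an anchor gene (by
#' convention the terminase gene, or a closely linked upstream gene after a
#' non-coding gap). The sequence content is preserved as a rotation and
#' all gene coordinates are remapped modulo the genome length.
#'
#' Reorientation to a minus-strand anchor is undefined and raises an
#' error, as does a gene that would span the new origin after rotation
#' (wrapped gene intervals cannot be represented).
#'
#' @param genome a circular [PhageGenome-class].
#' @param anchorGeneId gene_id of the plus-strand anchor gene.
#' @return the rotated [PhageGenome-class]; the anchor gene starts at 0.
#' @export
reorientCircular <- function(genome, anchorGeneId) {
  stopifnot(is(genome, "PhageGenome"))
  if (!isCircular(genome))
    stop("genome '", genomeId(genome), "' is not circular; ",
         "reorientation is only defined for circular assemblies")
  gn <- genes(genome)
  k <- match(anchorGeneId, gn$gene_id)
  if (is.na(k)) stop("anchor gene '", anchorGeneId, "' not found in genome '",
                     genomeId(genome), "'")
  if (gn$strand[k] != "+")
    stop("anchor gene '", anchorGeneId, "' is on the minus strand; ",
         "reorientation to a reverse gene start is undefined")
  off <- gn$start[k]
  L <- seqLength(genome)
  if (off == 0L) return(genome)
  seq <- genomeSeq(genome)
  new_seq <- paste0(substr(seq, off + 1L, L), substr(seq, 1L, off))
  width <- gn$end - gn$start
  new_start <- (gn$start - off) %% L
  new_end <- new_start + width
  if (any(new_end > L))
    stop("gene(s) ", paste(gn$gene_id[new_end > L], collapse = ", "),
         " would span the new origin; choose a different anchor")
  gn$start <- as.integer(new_start)
  gn$end <- as.integer(new_end)
  out <- genome
  out@sequence <- new_seq
  gn <- gn[order(gn$start, gn$end, gn$gene_id), , drop = FALSE]
  rownames(gn) <- NULL
  out@genes <- gn
  validObject(out)
  out
}
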
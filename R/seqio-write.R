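## Writers: FASTA (70-column wrap), GFF3, GenBank flat file, and a TSV gene
## table. Coordinates are converted back to 1-based inclusive for
## GenBank/GFF3; the TSV gene table keeps the internal 0-based half-open
## convention (documented in its header comment line).

#' Write a genome as FASTA
#'
#' @param genome a [PhageGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(setNames(genomeSeq(genome),
                                          genomeId(genome)))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write gene translations as protein FASTA
#'
#' Record names are `genomeId|geneId`.
#'
#' @param genomes list of [PhageGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(genomes, path) {
  if (is(genomes, "PhageGenome")) genomes <- list(genomes)
  seqs <- unlist(lapply(genomes, function(g) {
    gn <- genes(g)
    if (nrow(gn) == 0) return(character(0))
    setNames(gn$translation, paste(genomeId(g), gn$gene_id, sep = "|"))
  }))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Write the annotation as GFF3
#'
#' @param genome a [PhageGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genome, path) {
  gn <- genes(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = genomeId(genome),
    ranges = IRanges::IRanges(start = gn$start + 1L, end = gn$end),
    strand = gn$strand)
  gr$source <- "phamkit"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- gn$gene_id
  if (any(!is.na(gn$product))) gr$product <- gn$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a genome as a GenBank flat file
#'
#' Minimal LOCUS/FEATURES/ORIGIN layout with CDS features carrying
#' `/locus_tag`, `/product` and `/translation` qualifiers; readable back
#' with [readGenome()] (round-trip preserves coordinates, strands, and
#' translations exactly).
#'
#' @param genome a [PhageGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  seq <- genomeSeq(genome)
  L <- nchar(seq)
  top <- if (isCircular(genome)) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   PHG",
                   genomeId(genome), L, top),
           sprintf("DEFINITION  %s.", genomeId(genome)),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  gn <- genes(genome)
  wrapQ <- function(text) {
    # wrap qualifier text to the GenBank 80-column layout (58 payload chars)
    starts <- seq.int(1L, max(nchar(text), 1L), by = 58L)
    paste0(strrep(" ", 21), substring(text, starts,
                                      pmin(starts + 57L, nchar(text))))
  }
  for (i in seq_len(nrow(gn))) {
    loc <- sprintf("%d..%d", gn$start[i] + 1L, gn$end[i])
    if (gn$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     CDS             %s", loc),
             wrapQ(sprintf('/locus_tag="%s"', gn$gene_id[i])))
    if (!is.na(gn$product[i]))
      out <- c(out, wrapQ(sprintf('/product="%s"', gn$product[i])))
    out <- c(out, wrapQ(sprintf('/translation="%s"', gn$translation[i])))
  }
  out <- c(out, "ORIGIN")
  for (off in seq.int(0L, L - 1L, by = 60L)) {
    chunk <- substr(seq, off + 1L, min(off + 60L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off + 1L,
                          tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write a TSV gene table
#'
#' Columns: genome_id, gene_id, start, end, strand, pham_id. Coordinates
#' are 0-based half-open.
#'
#' @param genomes list of [PhageGenome-class] (or a single genome).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genomes, path) {
  if (is(genomes, "PhageGenome")) genomes <- list(genomes)
  tabs <- lapply(genomes, function(g) {
    gn <- genes(g)
    data.frame(genome_id = rep(genomeId(g), nrow(gn)),
               gene_id = gn$gene_id, start = gn$start, end = gn$end,
               strand = gn$strand, pham_id = gn$pham_id,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
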
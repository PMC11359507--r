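## Reading genomes and annotations.
##
## Supported inputs:
##   * GenBank flat file (LOCUS ... //) with CDS features, parsed here
##     directly (no installed R package reads GenBank flat files);
##   * FASTA + GFF3 (GFF3 via rtracklayer);
##   * bare FASTA, in which case ORFs are called de novo (callOrfs).
##
## All coordinates are converted from the 1-based inclusive convention of
## GenBank/GFF3 to the internal 0-based half-open convention at this
## boundary. Sequences containing characters outside A/C/G/T are rejected
## outright rather than masked.

#' Read a phage genome with its annotation
#'
#' @param path path to the GenBank or FASTA file.
#' @param fmt input format: `"genbank"`, `"fasta+gff"`, or `"fasta"` (ORFs
#'   are then called de novo with [callOrfs()]).
#' @param gffPath for `fmt = "fasta+gff"`, path to the GFF3 annotation.
#' @param minAa for `fmt = "fasta"`, minimum ORF length in amino acids.
#' @param genomeId optional id override; defaults to the LOCUS name /
#'   FASTA header word.
#' @return a [PhageGenome-class].
#' @details GenBank CDS features use their `/translation` qualifier when
#'   present; otherwise the translation is derived from the sequence with
#'   translation table 11 (minus-strand features from the reverse
#'   complement). tRNA/tmRNA features are retained in the genome metadata
#'   but never enter similarity metrics, which are defined on
#'   protein-coding genes only.
#' @export
#' @examples
#' g <- simulateDataset(simulationSpec(nClusters = 1, genomesPerCluster = 1,
#'                                     phamsPerGenome = 3))$genomes[[1]]
#' tf <- tempfile(fileext = ".gbk")
#' writeGenBank(g, tf)
#' g2 <- readGenome(tf, "genbank")
#' identical(genes(g)$start, genes(g2)$start)
readGenome <- function(path, fmt = c("genbank", "fasta+gff", "fasta"),
                       gffPath = NULL, minAa = 30L, genomeId = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(fmt,
    genbank = .readGenBank(path, genomeId),
    `fasta+gff` = {
      if (is.null(gffPath)) stop("fmt='fasta+gff' requires gffPath")
      .readFastaGff(path, gffPath, genomeId)
    },
    fasta = {
      g <- .readBareFasta(path, genomeId)
      callOrfs(g, minAa = minAa)
    })
}

.checkSequence <- function(seq, what) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(what, " rejected: contains non-TCGA characters (",
         paste(bad, collapse = ", "), ")")
  }
  seq
}

.readBareFasta <- function(path, genomeId = NULL) {
  ss <- Biostrings::readBStringSet(path)  # BString: validate characters ourselves
  if (length(ss) == 0) stop("FASTA parse failure in ", path, ": no records")
  if (length(ss) > 1)
    warning("multiple FASTA records in ", path, "; using the first")
  id <- genomeId %||% strsplit(names(ss)[1], "\\s+")[[1]][1]
  seq <- .checkSequence(as.character(ss[[1]]), paste0("genome '", id, "'"))
  PhageGenome(id, seq)
}

## --- GenBank flat file ----------------------------------------------------

.readGenBank <- function(path, genomeId = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0)
    stop("GenBank parse failure in ", path, ": no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- genomeId %||% locus[2]
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0)
    stop("GenBank parse failure in ", path, ": no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[seq.int(origin_i[1] + 1L, end_i - 1L)]
  seq <- toupper(gsub("[ 0-9]", "", paste(seq_lines, collapse = "")))
  seq <- .checkSequence(seq, paste0("genome '", id, "'"))

  feats <- .parseGenBankFeatures(lines, origin_i[1], path)
  gene_rows <- list()
  extra_feats <- list()
  cds_n <- 0L
  for (f in feats) {
    if (f$key == "CDS") {
      cds_n <- cds_n + 1L
      loc <- .parseGbLocation(f$location, path, cds_n)
      gid <- f$qualifiers[["locus_tag"]] %||% f$qualifiers[["gene"]] %||%
        sprintf("CDS_%d", cds_n)
      tr <- f$qualifiers[["translation"]]
      if (is.null(tr)) {
        nt <- substr(seq, loc$start1, loc$end1)
        if (loc$strand == "-") nt <- revComp(nt)
        tr <- tryCatch(translateCds(nt),
          error = function(e) stop("feature error in ", path, ", CDS #",
            cds_n, " (", gid, "): translation not derivable (",
            conditionMessage(e), ")"))
      } else {
        tr <- gsub("\\s", "", tr)
      }
      if (!nzchar(tr))
        stop("feature error in ", path, ", CDS #", cds_n, " (", gid,
             "): empty translation")
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, start = loc$start1 - 1L, end = loc$end1,
        strand = loc$strand, translation = tr, pham_id = NA_character_,
        product = f$qualifiers[["product"]] %||% NA_character_,
        stringsAsFactors = FALSE)
    } else if (f$key %in% c("tRNA", "tmRNA")) {
      extra_feats[[length(extra_feats) + 1L]] <-
        list(key = f$key, location = f$location,
             product = f$qualifiers[["product"]] %||% NA_character_)
    }
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows)
           else emptyGeneTable()
  meta <- list(source = path)
  if (length(extra_feats)) meta$rna_features <- extra_feats
  PhageGenome(id, seq, circular = circular, genes = genes, metadata = meta)
}

## Split the FEATURES block into (key, location, qualifiers) records.
## Feature keys start at column 6, qualifiers ("/name=value") at column 22;
## continuation lines are appended to the open qualifier/location.
.parseGenBankFeatures <- function(lines, origin_i, path) {
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i) == 0) return(list())
  block <- lines[seq.int(feat_i[1] + 1L, origin_i - 1L)]
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {            # new feature
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  qualifiers = list())
      cur_qual <- NULL
    } else if (grepl("^ {21}/", ln)) {       # new qualifier
      q <- sub("^ +/", "", ln)
      eq <- regexpr("=", q, fixed = TRUE)
      if (eq > 0) {
        nm <- substr(q, 1, eq - 1)
        val <- substr(q, eq + 1, nchar(q))
        val <- gsub('^"|"$', "", val)
        cur$qualifiers[[nm]] <- val
        cur_qual <- nm
      } else {
        cur$qualifiers[[q]] <- TRUE
        cur_qual <- NULL
      }
    } else if (grepl("^ {21}\\S", ln) && !is.null(cur)) {  # continuation
      txt <- trimws(ln)
      if (!is.null(cur_qual)) {
        cur$qualifiers[[cur_qual]] <-
          paste0(cur$qualifiers[[cur_qual]], gsub('"$', "", txt))
      } else {
        cur$location <- paste0(cur$location, txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

## "123..456" or "complement(123..456)"; joins are not supported.
.parseGbLocation <- function(loc, path, n) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order", loc))
    stop("format error in ", path, ", feature #", n,
         ": joined locations are not supported (", loc, ")")
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3)
    stop("format error in ", path, ", feature #", n,
         ": cannot parse location '", loc, "'")
  list(start1 = as.integer(m[2]), end1 = as.integer(m[3]), strand = strand)
}

## --- FASTA + GFF3 ---------------------------------------------------------

.readFastaGff <- function(fastaPath, gffPath, genomeId = NULL) {
  g <- .readBareFasta(fastaPath, genomeId)
  if (!file.exists(gffPath)) stop("file not found: ", gffPath)
  gr <- tryCatch(rtracklayer::import(gffPath, format = "gff3"),
    error = function(e) stop("GFF3 parse failure in ", gffPath, ": ",
                             conditionMessage(e)))
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0) {
    genes(g) <- emptyGeneTable()
    return(g)
  }
  seq <- genomeSeq(g)
  rows <- lapply(seq_along(gr), function(i) {
    s1 <- BiocGenerics::start(gr)[i]
    e1 <- BiocGenerics::end(gr)[i]
    strand <- as.character(BiocGenerics::strand(gr))[i]
    if (!strand %in% c("+", "-"))
      stop("feature error in ", gffPath, ", CDS #", i,
           ": strand must be + or -")
    if (e1 > nchar(seq))
      stop("feature error in ", gffPath, ", CDS #", i,
           ": coordinates exceed sequence length")
    gid <- gr$ID[i] %||% sprintf("CDS_%d", i)
    if (is.na(gid)) gid <- sprintf("CDS_%d", i)
    nt <- substr(seq, s1, e1)
    if (strand == "-") nt <- revComp(nt)
    tr <- tryCatch(translateCds(nt),
      error = function(e) stop("feature error in ", gffPath, ", CDS #", i,
        " (", gid, "): translation not derivable (",
        conditionMessage(e), ")"))
    prod <- NA_character_
    if ("product" %in% names(S4Vectors::mcols(gr))) {
      prod <- gr$product[i]
      if (is.null(prod) || length(prod) == 0) prod <- NA_character_
    }
    data.frame(gene_id = gid, start = s1 - 1L, end = e1, strand = strand,
               translation = tr, pham_id = NA_character_, product = prod,
               stringsAsFactors = FALSE)
  })
  genes(g) <- do.call(rbind, rows)
  g
}
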
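# Shared fixtures, built once per test run. The default dataset is the
# package's study condition: 4 planted clusters x 5 genomes, core fraction
# 0.8, amino-acid divergence 0.05, HGT rate 1 (simulationSpec() defaults,
# seed 1).

.fixtures <- new.env()

defaultDataset <- function() {
  if (is.null(.fixtures$default)) {
    sim <- simulateDataset(simulationSpec(seed = 1))
    phams <- buildPhams(sim$genomes)
    genomes <- assignPhams(sim$genomes, phams)
    .fixtures$default <- list(
      sim = sim, phams = phams, genomes = genomes,
      peq = pairwiseMatrix(genomes, "peq", phams = phams),
      gcs = pairwiseMatrix(genomes, "gcs", phams = phams),
      gni = pairwiseMatrix(genomes, "gni"))
  }
  .fixtures$default
}

# Two-level study condition: 2 clusters x 2 subclusters x 3 genomes,
# subcluster ancestors diverged at 0.2 from the cluster ancestor.
nestedDataset <- function() {
  if (is.null(.fixtures$nested)) {
    sim <- simulateDataset(simulationSpec(
      seed = 2, nClusters = 2, genomesPerCluster = 3,
      subclustersPerCluster = 2, phamsPerGenome = 20))
    phams <- buildPhams(sim$genomes)
    genomes <- assignPhams(sim$genomes, phams)
    .fixtures$nested <- list(
      sim = sim, phams = phams, genomes = genomes,
      peq = pairwiseMatrix(genomes, "peq", phams = phams))
  }
  .fixtures$nested
}

# Build a PhamSet directly from a gene table with known pham labels
# (for hand-constructed metric examples).
makePhamSet <- function(df) {
  df$aa_length <- nchar(df$translation)
  key <- paste(df$genome_id, df$gene_id, sep = ":")
  reps <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$pham_id),
    function(idx) {
      best <- idx[order(-df$aa_length[idx], key[idx])][1]
      data.frame(pham_id = df$pham_id[best], genome_id = df$genome_id[best],
                 gene_id = df$gene_id[best],
                 translation = df$translation[best],
                 stringsAsFactors = FALSE)
    }))
  new("PhamSet",
      assignments = df[c("pham_id", "genome_id", "gene_id", "aa_length")],
      representatives = reps, parameters = list())
}

# A toy genome whose genes carry given translations laid head-to-tail;
# nucleotide content is a consistent back-translation (no noise).
toyGenome <- function(id, translations, phams = NULL, gap = 30L,
                      strands = NULL) {
  n <- length(translations)
  if (is.null(strands)) strands <- rep("+", n)
  rows <- list(); parts <- character(0); pos <- 0L
  parts <- c(parts, randomDnaStr(gap)); pos <- pos + gap
  for (k in seq_len(n)) {
    aa <- strsplit(translations[k], "")[[1]]
    by_aa <- phamkit:::codonsForAa()
    codons <- vapply(aa, function(x) by_aa[[x]][1], character(1))
    codons[1] <- if (aa[1] == "M") "ATG" else codons[1]
    nt <- paste(c(codons, "TAA"), collapse = "")
    rows[[k]] <- data.frame(
      gene_id = sprintf("g%d", k), start = pos, end = pos + nchar(nt),
      strand = strands[k], translation = translations[k],
      pham_id = if (is.null(phams)) NA_character_ else phams[k],
      product = NA_character_, stringsAsFactors = FALSE)
    parts <- c(parts, if (strands[k] == "+") nt else
      phamkit:::revComp(nt), randomDnaStr(gap))
    pos <- pos + nchar(nt) + gap
  }
  PhageGenome(id, paste(parts, collapse = ""), genes = do.call(rbind, rows))
}
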
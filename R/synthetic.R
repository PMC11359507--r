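## Mosaic phage genome simulator with planted pham / cluster / subcluster
## / taxonomy structure. The generator emulates the dominant features of
## dsDNA phage comparative genomics -- shared gene phamilies with tunable
## amino-acid divergence, horizontal-transfer insertions from a global
## pool, intergenic spacers, alternating transcription strands -- while
## deliberately omitting indels, recombination breakpoints, and selection.
## All randomness flows from one seed through R's Mersenne-Twister RNG;
## identical spec + seed gives a byte-identical dataset.

#' Specification for a synthetic mosaic genome dataset
#'
#' Defaults describe a compact 20-genome study: 4 well-separated clusters
#' of 5 genomes, 30 phams per genome of which 80% are cluster-core, 5%
#' per-site amino-acid divergence within a (sub)cluster, 2% additional
#' nucleotide noise, and on average one horizontally transferred foreign
#' gene per genome.
#'
#' @param seed integer RNG seed.
#' @param nClusters number of planted clusters.
#' @param genomesPerCluster genomes per cluster.
#' @param subclustersPerCluster subclusters per cluster (1 = no planted
#'   substructure).
#' @param phamsPerGenome genes per genome (before HGT insertions).
#' @param coreFraction fraction of each genome's phams drawn from the
#'   cluster core (shared by all cluster members); the rest are drawn
#'   per genome from a cluster accessory pool.
#' @param aaDivergence per-site amino-acid substitution probability from
#'   the (sub)cluster ancestor to each genome.
#' @param subclusterDivergence per-site amino-acid substitution
#'   probability from the cluster ancestor to each subcluster ancestor
#'   (used only when `subclustersPerCluster > 1`). The default of 0.15
#'   plants cross-subcluster protein identities around 0.65 -- deep
#'   enough to split subclusters at the 60% PEQ threshold, shallow
#'   enough that pham assembly still bridges the subclusters, keeping
#'   them in one cluster at 25% (cross-subcluster PEQ roughly 45-55).
#'   When subclusters are planted, each subcluster also draws its
#'   accessory genes from a private pool, mirroring how accessory gene
#'   content tracks subclusters in real phage populations.
#' @param ntDivergence additional iid per-site nucleotide substitution
#'   probability applied to each gene after inheritance.
#' @param hgtRate expected number of foreign-pool gene insertions per
#'   genome (Poisson).
#' @param hgtPoolSize size of the global foreign pham pool shared by all
#'   genomes.
#' @param geneLengthMeanlog,geneLengthSdlog lognormal parameters for
#'   ancestral protein length in amino acids (median `exp(meanlog)`).
#' @param minGeneAa minimum ancestral protein length.
#' @param intergenicGap fixed spacer length between genes, bp.
#' @return a validated `SimulationSpec` (S3 list).
#' @export
simulationSpec <- function(seed = 1L, nClusters = 4L, genomesPerCluster = 5L,
                           subclustersPerCluster = 1L, phamsPerGenome = 30L,
                           coreFraction = 0.8, aaDivergence = 0.05,
                           subclusterDivergence = 0.15, ntDivergence = 0.02,
                           hgtRate = 1, hgtPoolSize = 40L,
                           geneLengthMeanlog = log(180),
                           geneLengthSdlog = 0.35, minGeneAa = 50L,
                           intergenicGap = 50L) {
  spec <- list(seed = as.integer(seed), nClusters = as.integer(nClusters),
               genomesPerCluster = as.integer(genomesPerCluster),
               subclustersPerCluster = as.integer(subclustersPerCluster),
               phamsPerGenome = as.integer(phamsPerGenome),
               coreFraction = coreFraction, aaDivergence = aaDivergence,
               subclusterDivergence = subclusterDivergence,
               ntDivergence = ntDivergence, hgtRate = hgtRate,
               hgtPoolSize = as.integer(hgtPoolSize),
               geneLengthMeanlog = geneLengthMeanlog,
               geneLengthSdlog = geneLengthSdlog,
               minGeneAa = as.integer(minGeneAa),
               intergenicGap = as.integer(intergenicGap))
  class(spec) <- "SimulationSpec"
  validateSimulationSpec(spec)
  spec
}

#' Validate a SimulationSpec
#'
#' @param spec a `SimulationSpec`.
#' @return `spec`, invisibly; errors list every violated field.
#' @export
validateSimulationSpec <- function(spec) {
  bad <- character(0)
  probs <- c("coreFraction", "aaDivergence", "subclusterDivergence",
             "ntDivergence")
  for (p in probs)
    if (!is.numeric(spec[[p]]) || is.na(spec[[p]]) ||
        spec[[p]] < 0 || spec[[p]] > 1) bad <- c(bad, p)
  counts <- c("nClusters", "genomesPerCluster", "subclustersPerCluster",
              "phamsPerGenome", "hgtPoolSize", "minGeneAa", "intergenicGap")
  for (p in counts)
    if (!is.numeric(spec[[p]]) || is.na(spec[[p]]) || spec[[p]] < 1)
      bad <- c(bad, p)
  if (!is.numeric(spec$hgtRate) || is.na(spec$hgtRate) || spec$hgtRate < 0)
    bad <- c(bad, "hgtRate")
  if (!is.numeric(spec$seed) || is.na(spec$seed)) bad <- c(bad, "seed")
  if (length(bad))
    stop("invalid SimulationSpec field(s): ", paste(bad, collapse = ", "))
  invisible(spec)
}

#' Substitute symbols of a sequence at a fixed per-site rate
#'
#' Each position is replaced, independently with probability `rate`, by a
#' uniformly chosen *different* symbol from `alphabet`. Length is
#' preserved. With `rate = 1` no position retains its original symbol.
#'
#' @param seq character string.
#' @param rate substitution probability per site, in \[0, 1\].
#' @param alphabet character vector of symbols (default DNA).
#' @param seed optional seed for reproducibility in isolation; when NULL
#'   the current RNG stream is used.
#' @return the mutated string.
#' @export
#' @examples
#' mutateSequence("AAAA", 1, seed = 1)
mutateSequence <- function(seq, rate, alphabet = c("A", "C", "G", "T"),
                           seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  run <- function() {
    ch <- strsplit(seq, "")[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      others <- lapply(ch[hit], function(x) setdiff(alphabet, x))
      ch[hit] <- vapply(others, function(o)
        o[sample.int(length(o), 1L)], character(1))
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

## Back-translate a protein once: start codon ATG, uniform synonymous
## codon per residue, TAA stop. Returns the codon vector (length n+1
## counting the stop; the initiator ATG replaces the codon of residue 1).
.backTranslate <- function(protein) {
  by_aa <- codonsForAa()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(x) {
    opts <- by_aa[[x]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  codons[1] <- "ATG"
  c(codons, "TAA")
}

## Mutate a protein (position 1 fixed at M so the gene keeps a canonical
## start) and update its codons: substituted residues get a uniform codon
## of the new amino acid. Returns list(protein, codons).
.diverge <- function(protein, codons, rate) {
  if (rate <= 0) return(list(protein = protein, codons = codons))
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < 2) return(list(protein = protein, codons = codons))
  hit <- which(runif(n) < rate)
  hit <- hit[hit > 1L]                      # keep the initiator M
  if (length(hit)) {
    by_aa <- codonsForAa()
    for (i in hit) {
      new_aa <- sample(setdiff(AA_ALPHABET, aa[i]), 1L)
      aa[i] <- new_aa
      opts <- by_aa[[new_aa]]
      codons[i] <- opts[sample.int(length(opts), 1L)]
    }
  }
  list(protein = paste(aa, collapse = ""), codons = codons)
}

#' Simulate a mosaic phage genome dataset with planted truth
#'
#' Draws one ancestral protein per source pham (random sequence,
#' lognormal length) and back-translates it once with uniform synonymous
#' codons; cluster members inherit the cluster's core phams plus a random
#' accessory subset, diverge each inherited protein by iid amino-acid
#' substitutions (substituted codons re-drawn for the new residue), apply
#' extra iid nucleotide noise, and receive Poisson-distributed horizontal
#' insertions from a global foreign pool. Genes are laid head-to-tail
#' with fixed-length intergenic spacers; each gene slot's transcription
#' strand is set by a seeded coin at the ancestor and inherited, and the
#' downstream spacer is likewise inherited (and subject to the nucleotide
#' noise), so a zero-divergence dataset is byte-identical across cluster
#' members. When `subclustersPerCluster > 1`, each subcluster first diverges from
#' the cluster ancestor at `subclusterDivergence`, planting a two-level
#' hierarchy.
#'
#' Stored translations are the diverged proteins (authoritative for pham
#' assembly); the nucleotide noise models faster nucleotide-level
#' divergence and is not re-translated.
#'
#' @param spec a [simulationSpec()].
#' @return list with elements:
#'   \describe{
#'     \item{genomes}{list of [PhageGenome-class].}
#'     \item{truth}{list: `genomes` (data.frame genome_id, cluster,
#'       subcluster), `genes` (data.frame genome_id, gene_id,
#'       source_pham), `taxonomy` (data.frame in [readTaxonomy()] layout:
#'       genus = planted subcluster, subfamily = planted cluster, family
#'       shared, species unnamed), and `spec` (the spec echo).}
#'   }
#' @export
simulateDataset <- function(spec = simulationSpec()) {
  validateSimulationSpec(spec)
  withSeed(spec$seed, .simulate(spec))
}

.simulate <- function(spec) {
  nCore <- round(spec$coreFraction * spec$phamsPerGenome)
  nAcc <- spec$phamsPerGenome - nCore
  accPool <- max(3L * nAcc, nAcc)

  drawAncestor <- function(pham_id) {
    len <- max(spec$minGeneAa,
               round(rlnorm(1, spec$geneLengthMeanlog,
                            spec$geneLengthSdlog)))
    protein <- randomProtein(len)
    # the downstream intergenic spacer is inherited with the gene, so
    # zero-divergence datasets reproduce byte-identical genomes
    list(pham = pham_id, protein = protein,
         codons = .backTranslate(protein),
         spacer = randomDna(spec$intergenicGap),
         strand = if (runif(1) < 0.5) "+" else "-")
  }

  hgtPool <- lapply(seq_len(spec$hgtPoolSize), function(i)
    drawAncestor(sprintf("hgt_%d", i)))

  genomes <- list(); truth_genomes <- list(); truth_genes <- list()
  g_idx <- 0L
  for (c_i in seq_len(spec$nClusters)) {
    core <- lapply(seq_len(nCore), function(i)
      drawAncestor(sprintf("c%d_core_%d", c_i, i)))
    acc <- lapply(seq_len(accPool), function(i)
      drawAncestor(sprintf("c%d_acc_%d", c_i, i)))
    for (s_i in seq_len(spec$subclustersPerCluster)) {
      sub_div <- if (spec$subclustersPerCluster > 1)
        spec$subclusterDivergence else 0
      subDiverge <- function(a) {
        d <- .diverge(a$protein, a$codons, sub_div)
        list(pham = a$pham, protein = d$protein, codons = d$codons,
             spacer = a$spacer, strand = a$strand)
      }
      sub_core <- lapply(core, subDiverge)
      # accessory genes track subclusters: private pool per subcluster
      sub_acc <- if (spec$subclustersPerCluster > 1)
        lapply(seq_len(accPool), function(i)
          drawAncestor(sprintf("c%d_s%d_acc_%d", c_i, s_i, i)))
      else lapply(acc, subDiverge)
      for (g_i in seq_len(spec$genomesPerCluster)) {
        g_idx <- g_idx + 1L
        gid <- sprintf("synphage_%03d", g_idx)
        repertoire <- c(sub_core,
                        if (nAcc > 0) sub_acc[sample.int(accPool, nAcc)])
        n_hgt <- min(rpois(1, spec$hgtRate), spec$hgtPoolSize)
        if (n_hgt > 0) {
          foreign <- hgtPool[sample.int(spec$hgtPoolSize, n_hgt)]
          pos <- sample.int(length(repertoire) + n_hgt, n_hgt)
          merged <- vector("list", length(repertoire) + n_hgt)
          merged[pos] <- foreign
          merged[-pos] <- repertoire
          repertoire <- merged
        }
        res <- .layoutGenome(gid, repertoire, spec)
        genomes[[g_idx]] <- res$genome
        truth_genes[[g_idx]] <- res$truth
        truth_genomes[[g_idx]] <- data.frame(
          genome_id = gid, cluster = sprintf("C%d", c_i),
          subcluster = sprintf("C%d.S%d", c_i, s_i),
          stringsAsFactors = FALSE)
      }
    }
  }
  tg <- do.call(rbind, truth_genomes)
  taxonomy <- data.frame(
    genome_id = tg$genome_id, species = NA_character_,
    genus = tg$subcluster, subfamily = tg$cluster,
    family = "Synthviridae", stringsAsFactors = FALSE)
  list(genomes = genomes,
       truth = list(genomes = tg,
                    genes = do.call(rbind, truth_genes),
                    taxonomy = taxonomy, spec = spec))
}

## Diverge each repertoire entry for one genome, add nucleotide noise,
## assign strands, and concatenate with spacers into a PhageGenome.
.layoutGenome <- function(gid, repertoire, spec) {
  parts <- character(0)
  rows <- list(); truth <- list()
  pos <- 0L
  for (k in seq_along(repertoire)) {
    anc <- repertoire[[k]]
    d <- .diverge(anc$protein, anc$codons, spec$aaDivergence)
    nt <- paste(d$codons, collapse = "")
    spc <- anc$spacer
    if (spec$ntDivergence > 0) {
      nt <- mutateSequence(nt, spec$ntDivergence)
      spc <- mutateSequence(spc, spec$ntDivergence)
    }
    strand <- anc$strand
    gene_id <- sprintf("gene_%d", k)
    rows[[k]] <- data.frame(
      gene_id = gene_id, start = pos, end = pos + nchar(nt),
      strand = strand, translation = d$protein, pham_id = NA_character_,
      product = NA_character_, stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(genome_id = gid, gene_id = gene_id,
                             source_pham = anc$pham,
                             stringsAsFactors = FALSE)
    parts <- c(parts, if (strand == "+") nt else revComp(nt), spc)
    pos <- pos + nchar(nt) + spec$intergenicGap
  }
  genome <- PhageGenome(gid, paste(parts, collapse = ""),
                        genes = do.call(rbind, rows),
                        metadata = list(source = "synthetic"))
  list(genome = genome, truth = do.call(rbind, truth))
}
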
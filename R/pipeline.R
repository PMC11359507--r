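## Flat-file project pipeline: simulate/ingest -> phams -> compare ->
## cluster -> concord -> map over a project directory of documented
## TSV/FASTA/SVG artifacts. Stages are idempotent and re-runnable; a
## manifest records the tool version, a hash of the effective
## configuration, and checksums of every artifact (no timestamps, so
## reruns are byte-identical). A relational store is deliberately
## avoided: the flat artifacts keep the project portable and diffable.

.defaultConfig <- function() {
  list(
    seed = 1L,
    ingest = list(paths = NULL, fmt = "genbank", min_aa = 30L),
    simulate = list(),                 # simulationSpec() overrides
    phams = list(min_identity = 0.35, min_coverage = 0.80, kmer = 5L,
                 min_kmer_jaccard = 0.05),
    compare = list(metrics = c("peq", "gcs", "gni"), evalue = 1e-4),
    cluster = list(metric = "peq", cluster_threshold = 25,
                   subcluster_threshold = 60),
    concord = list(metric = "gni", taxonomy = "taxonomy.tsv"),
    map = list(order = NULL, window = NULL, evalue = 1e-4)
  )
}

.mergeConfig <- function(config) {
  def <- .defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      sub_unknown <- if (nm == "simulate") character(0)
        else setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(sub_unknown))
        stop("unknown config key(s) under '", nm, "': ",
             paste(sub_unknown, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  def
}

.artifact <- function(projectDir, ...) file.path(projectDir, ...)

.needArtifact <- function(projectDir, file, producer) {
  p <- .artifact(projectDir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run the '", producer,
         "' stage first")
  p
}

## Read the genome store (genomes.fasta + genes.tsv + proteins.faa) back
## into PhageGenome objects.
loadProjectGenomes <- function(projectDir) {
  fa <- .needArtifact(projectDir, "genomes.fasta", "simulate/ingest")
  gt <- .needArtifact(projectDir, "genes.tsv", "simulate/ingest")
  pf <- .needArtifact(projectDir, "proteins.faa", "simulate/ingest")
  seqs <- Biostrings::readDNAStringSet(fa)
  tab <- read.delim(gt, colClasses = c(start = "integer",
                                       end = "integer"))
  need <- c("genome_id", "gene_id", "start", "end", "strand", "pham_id")
  if (!all(need %in% names(tab)))
    stop("genes.tsv: expected columns ", paste(need, collapse = ", "),
         "; found ", paste(names(tab), collapse = ", "))
  prot <- Biostrings::readAAStringSet(pf)
  trans <- setNames(as.character(prot), names(prot))
  lapply(names(seqs), function(id) {
    gn <- tab[tab$genome_id == id, , drop = FALSE]
    key <- paste(id, gn$gene_id, sep = "|")
    genes <- data.frame(gene_id = gn$gene_id, start = gn$start,
                        end = gn$end, strand = gn$strand,
                        translation = unname(trans[key]),
                        pham_id = ifelse(nzchar(gn$pham_id) &
                                           !is.na(gn$pham_id),
                                         gn$pham_id, NA_character_),
                        product = NA_character_, stringsAsFactors = FALSE)
    PhageGenome(id, as.character(seqs[[id]]), genes = genes)
  })
}

.writeGenomeStore <- function(genomes, projectDir) {
  ss <- Biostrings::DNAStringSet(setNames(
    vapply(genomes, genomeSeq, character(1)),
    vapply(genomes, genomeId, character(1))))
  Biostrings::writeXStringSet(ss, .artifact(projectDir, "genomes.fasta"),
                              width = 70L)
  writeGeneTable(genomes, .artifact(projectDir, "genes.tsv"))
  writeProteinFasta(genomes, .artifact(projectDir, "proteins.faa"))
}

#' Run the analysis pipeline over a project directory
#'
#' Wires the stages simulate/ingest, phams, compare, cluster, concord,
#' and map over a flat on-disk project store. Each stage reads and
#' writes only documented artifacts (TSV/FASTA/SVG) inside `projectDir`;
#' a missing prerequisite names the stage to run first. All randomness
#' flows from `config$seed`. After the last stage a `manifest.json` is
#' written with the tool version, config hash, and artifact checksums;
#' rerunning an unchanged project reproduces every artifact byte for
#' byte.
#'
#' @param projectDir existing directory for the project store.
#' @param config named list of overrides of the documented defaults (see
#'   the package vignette); unknown keys raise an error. May also be a
#'   path to a YAML file.
#' @param stages character vector of stages to run, in order. Default
#'   runs everything starting from simulation; use `"ingest"` with
#'   `config$ingest$paths` for real input files.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(projectDir,
                        config = list(),
                        stages = c("simulate", "phams", "compare",
                                   "cluster", "concord", "map")) {
  if (!dir.exists(projectDir)) stop("project directory does not exist: ",
                                    projectDir)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  known <- c("simulate", "ingest", "phams", "compare", "cluster",
             "concord", "map")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in stages) {
    switch(st,
      simulate = .stageSimulate(projectDir, cfg),
      ingest = .stageIngest(projectDir, cfg),
      phams = .stagePhams(projectDir, cfg),
      compare = .stageCompare(projectDir, cfg),
      cluster = .stageCluster(projectDir, cfg),
      concord = .stageConcord(projectDir, cfg),
      map = .stageMap(projectDir, cfg))
  }
  manifest <- .writeManifest(projectDir, cfg)
  invisible(manifest)
}

.stageSimulate <- function(projectDir, cfg) {
  args <- cfg$simulate
  args$seed <- args$seed %||% cfg$seed
  spec <- do.call(simulationSpec, args)
  sim <- simulateDataset(spec)
  .writeGenomeStore(sim$genomes, projectDir)
  write.table(sim$truth$genomes,
              .artifact(projectDir, "truth_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, .artifact(projectDir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- sim$truth$taxonomy
  tax[is.na(tax)] <- ""
  write.table(tax, .artifact(projectDir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.stageIngest <- function(projectDir, cfg) {
  paths <- cfg$ingest$paths
  if (is.null(paths) || length(paths) == 0)
    stop("ingest stage needs config$ingest$paths")
  genomes <- lapply(paths, function(p) {
    if (is.list(p))
      readGenome(p$path, fmt = p$fmt %||% cfg$ingest$fmt,
                 gffPath = p$gff, minAa = cfg$ingest$min_aa)
    else readGenome(p, fmt = cfg$ingest$fmt, minAa = cfg$ingest$min_aa)
  })
  .writeGenomeStore(genomes, projectDir)
  invisible(NULL)
}

.stagePhams <- function(projectDir, cfg) {
  genomes <- loadProjectGenomes(projectDir)
  p <- cfg$phams
  phams <- buildPhams(genomes, minIdentity = p$min_identity,
                      minCoverage = p$min_coverage, kmerSize = p$kmer,
                      minKmerJaccard = p$min_kmer_jaccard)
  writePhamTable(phams, .artifact(projectDir, "phams.tsv"),
                 .artifact(projectDir, "representatives.faa"))
  genomes <- assignPhams(genomes, phams)
  writeGeneTable(genomes, .artifact(projectDir, "genes.tsv"))
  invisible(NULL)
}

.readPhamSet <- function(projectDir) {
  p <- .needArtifact(projectDir, "phams.tsv", "phams")
  tab <- read.delim(p, colClasses = "character")
  need <- c("pham_id", "genome_id", "gene_id")
  if (!all(need %in% names(tab)) || anyNA(tab[need]) ||
      any(!nzchar(as.matrix(tab[need]))))
    stop("phams.tsv: malformed pham table; expected non-empty columns ",
         paste(need, collapse = ", "))
  genomes <- loadProjectGenomes(projectDir)
  trans <- unlist(lapply(genomes, function(g)
    setNames(genes(g)$translation,
             paste(genomeId(g), genes(g)$gene_id, sep = ":"))))
  tab$aa_length <- nchar(trans[paste(tab$genome_id, tab$gene_id,
                                     sep = ":")])
  if (anyNA(tab$aa_length))
    stop("phams.tsv: malformed pham table; rows refer to unknown genes")
  reps <- .pickRepresentatives(tab,
    unname(trans[paste(tab$genome_id, tab$gene_id, sep = ":")]),
    paste(tab$genome_id, tab$gene_id, sep = ":"))
  list(phams = new("PhamSet", assignments = tab[c("pham_id", "genome_id",
                                                  "gene_id", "aa_length")],
                   representatives = reps, parameters = list()),
       genomes = genomes)
}

.stageCompare <- function(projectDir, cfg) {
  st <- .readPhamSet(projectDir)
  genomes <- assignPhams(st$genomes, st$phams)
  for (metric in cfg$compare$metrics) {
    mat <- pairwiseMatrix(genomes, metric = metric, phams = st$phams,
                          evalueMax = cfg$compare$evalue)
    writeSimilarity(mat,
                    .artifact(projectDir, paste0(metric, ".tsv")),
                    .artifact(projectDir,
                              paste0("matrix_", metric, ".tsv")))
  }
  invisible(NULL)
}

.stageCluster <- function(projectDir, cfg) {
  metric <- cfg$cluster$metric
  mp <- .needArtifact(projectDir, paste0("matrix_", metric, ".tsv"),
                      "compare")
  mat <- readSimilarityMatrix(mp, metric)
  cl <- thresholdClusters(mat, cfg$cluster$cluster_threshold)
  cl <- assignSubclusters(mat, cl, cfg$cluster$subcluster_threshold)
  writeClusters(cl, .artifact(projectDir, "clusters.tsv"))
  curve <- clusterCountCurve(mat, seq(5, 95, by = 5))
  write.table(curve, .artifact(projectDir, "curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.stageConcord <- function(projectDir, cfg) {
  metric <- cfg$concord$metric
  mp <- .needArtifact(projectDir, paste0("matrix_", metric, ".tsv"),
                      "compare")
  taxp <- .needArtifact(projectDir, cfg$concord$taxonomy,
                        "simulate (or provide a taxonomy TSV)")
  mat <- readSimilarityMatrix(mp, metric)
  tax <- gapfillRanks(readTaxonomy(taxp))
  peqPath <- .artifact(projectDir, "matrix_peq.tsv")
  peqMat <- if (file.exists(peqPath) && metric != "peq")
    readSimilarityMatrix(peqPath, "peq") else NULL
  cs <- concordanceSummary(mat, tax, peqMat = peqMat)
  for (r in TAX_RANKS) {
    write.table(cs$summary[cs$summary$rank == r, , drop = FALSE],
                .artifact(projectDir, paste0("concordance_", r, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cs$histograms[cs$histograms$rank == r, , drop = FALSE],
                .artifact(projectDir, paste0("histogram_", r, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cs$scatter)) {
    sc <- cs$scatter
    names(sc) <- c("genome_a", "genome_b", metric, "peq")
    write.table(sc, .artifact(projectDir, "peq_vs_gni.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

.stageMap <- function(projectDir, cfg) {
  st <- .readPhamSet(projectDir)
  genomes <- assignPhams(st$genomes, st$phams)
  ids <- vapply(genomes, genomeId, character(1))
  order_ids <- cfg$map$order %||% head(ids, 2)
  sel <- genomes[match(order_ids, ids)]
  if (anyNA(match(order_ids, ids)))
    stop("map order refers to unknown genome(s): ",
         paste(setdiff(order_ids, ids), collapse = ", "))
  renderComparisonMap(sel, st$phams,
                      file = .artifact(projectDir, "map.svg"),
                      evalueMax = cfg$map$evalue,
                      window = cfg$map$window)
  invisible(NULL)
}

.writeManifest <- function(projectDir, cfg) {
  files <- sort(setdiff(list.files(projectDir), "manifest.json"))
  sums <- as.list(tools::md5sum(file.path(projectDir, files)))
  names(sums) <- files
  manifest <- list(
    tool = "phamkit",
    version = as.character(packageVersion("phamkit")),
    schema = 1L,
    config_hash = unname(tools::md5sum(
      .writeTemp(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null")))),
    artifacts = sums)
  jsonlite::write_json(manifest, file.path(projectDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

.writeTemp <- function(text) {
  tf <- tempfile()
  writeLines(as.character(text), tf)
  tf
}
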
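# Genome I/O: coordinate conventions, ambiguity rejection, round trips.

test_that("GenBank CDS coordinates shift to 0-based half-open on read", {
  # two plus-strand CDS: 4..12 and 16..27 (1-based inclusive)
  seq <- paste0("AAA", "ATGAAATAA", "CCC", "ATGGGTCCCTAA", "TT")
  genes <- data.frame(gene_id = c("gp1", "gp2"), start = c(3L, 15L),
                      end = c(12L, 27L), strand = "+",
                      translation = c("MK", "MGP"), pham_id = NA,
                      product = c("terminase", NA))
  g <- PhageGenome("two_cds", seq, genes = genes)
  tf <- withr::local_tempfile(fileext = ".gbk")
  writeGenBank(g, tf)
  # the flat file itself must carry 1-based inclusive locations
  txt <- readLines(tf)
  expect_true(any(grepl("CDS             4..12", txt, fixed = TRUE)))
  expect_true(any(grepl("CDS             16..27", txt, fixed = TRUE)))
  g2 <- readGenome(tf, "genbank")
  expect_equal(genes(g2)$start, c(3L, 15L))
  expect_equal(genes(g2)$end, c(12L, 27L))
  expect_equal(genes(g2)$translation, c("MK", "MGP"))
  expect_equal(genes(g2)$product[1], "terminase")
})

test_that("sequences with non-TCGA characters are rejected", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">amb", "ACGTN"), tf)
  expect_error(readGenome(tf, "fasta"), "non-TCGA")
  expect_error(PhageGenome("x", "ACGTRY"), "non-TCGA")
})

test_that("minus-strand CDS from GFF3 yields revcomp translation", {
  # CDS 4..12 (1-based) on '-': forward subsequence is revcomp("ATGAAATAA")
  seq <- paste0("ACG", "TTATTTCAT", "GG")
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">minus_toy", seq), fa)
  writeLines(c("##gff-version 3",
               "minus_toy\ttest\tCDS\t4\t12\t.\t-\t0\tID=gene1"), gff)
  g <- readGenome(fa, "fasta+gff", gffPath = gff)
  expect_equal(genes(g)$start, 3L)
  expect_equal(genes(g)$end, 12L)
  expect_equal(genes(g)$strand, "-")
  expect_equal(genes(g)$translation, "MK")  # ATG AAA TAA -> MK
})

test_that("GenBank and fasta+gff round trips preserve annotation exactly", {
  sim <- simulateDataset(simulationSpec(
    seed = 11, nClusters = 1, genomesPerCluster = 2, phamsPerGenome = 10,
    ntDivergence = 0))
  for (g in sim$genomes) {
    gb <- withr::local_tempfile(fileext = ".gbk")
    writeGenBank(g, gb)
    g2 <- readGenome(gb, "genbank")
    expect_identical(genomeSeq(g2), genomeSeq(g))
    expect_identical(genes(g2)[c("start", "end", "strand", "translation")],
                     genes(g)[c("start", "end", "strand", "translation")])
    fa <- withr::local_tempfile(fileext = ".fa")
    gf <- withr::local_tempfile(fileext = ".gff3")
    writeGenomeFasta(g, fa)
    writeGff3(g, gf)
    g3 <- readGenome(fa, "fasta+gff", gffPath = gf)
    expect_identical(genes(g3)[c("start", "end", "strand", "translation")],
                     genes(g)[c("start", "end", "strand", "translation")])
  }
})

test_that("GenBank parse failures name the offending part", {
  tf <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       x 9 bp DNA linear PHG",
               "FEATURES             Location/Qualifiers",
               "     CDS             join(1..3,7..9)",
               "ORIGIN", "        1 atgaaataa", "//"), tf)
  expect_error(readGenome(tf, "genbank"), "feature #1")
  writeLines(c(">notgenbank", "ACGT"), tf)
  expect_error(readGenome(tf, "genbank"), "LOCUS")
})

# ---------------------------------------------------------------------------
# ORF calling

test_that("a single constructed ORF is called exactly", {
  set.seed(42)
  sense <- paste(replicate(32, sample(c("GCT", "GAA", "TGC", "AAA"), 1)),
                 collapse = "")
  g <- PhageGenome("one_orf", paste0("CCCC", "ATG", sense, "TAA", "CC"))
  out <- callOrfs(g, minAa = 30)
  expect_equal(nrow(genes(out)), 1L)
  expect_equal(genes(out)$start, 4L)
  expect_equal(genes(out)$end, 4L + 3L + 96L + 3L)
  # interval includes start and stop codons; translation includes the
  # initiator M, so (end - start)/3 - 1 = 33 residues
  expect_equal(nchar(genes(out)$translation), 33L)
  expect_match(genes(out)$translation, "^M")
})

test_that("a stop-free sequence yields zero ORFs", {
  g <- PhageGenome("polyA", strrep("A", 300))
  expect_equal(nrow(genes(callOrfs(g, minAa = 30))), 0L)
})

test_that("callOrfs matches the brute-force six-frame oracle", {
  for (seed in c(5, 17)) {
    set.seed(seed)
    g <- PhageGenome(paste0("rand", seed), randomDnaStr(10000))
    got <- genes(callOrfs(g, minAa = 30))
    want <- oracleOrfs(genomeSeq(g), 30)
    expect_equal(got[c("start", "end", "strand", "translation")], want,
                 ignore_attr = TRUE)
    # translation length invariant for ORF-called genes
    expect_true(all((got$end - got$start) %% 3 == 0))
    expect_equal(nchar(got$translation), (got$end - got$start) / 3 - 1)
  }
})

# ---------------------------------------------------------------------------
# Circular reorientation

test_that("rotation to an anchor gene is a sequence rotation", {
  set.seed(8)
  seq <- randomDnaStr(100)
  genes <- data.frame(gene_id = c("a", "b"), start = c(10L, 40L),
                      end = c(22L, 70L), strand = "+",
                      translation = c("MAA", "MAAAAAAAAA"), pham_id = NA,
                      product = NA)
  g <- PhageGenome("circ", seq, circular = TRUE, genes = genes)
  r <- reorientCircular(g, "b")
  expect_equal(genes(r)$start[genes(r)$gene_id == "b"], 0L)
  expect_identical(genomeSeq(r),
                   paste0(substr(seq, 41, 100), substr(seq, 1, 40)))
  # anchor already at 0 is the identity
  r0 <- reorientCircular(r, "b")
  expect_identical(genomeSeq(r0), genomeSeq(r))
  # rotations compose: anchoring at 'a' gives the same result whether or
  # not the genome was first re-anchored at 'b'
  expect_identical(genomeSeq(reorientCircular(r, "a")),
                   genomeSeq(reorientCircular(g, "a")))
})

test_that("pairwise inter-gene distances are preserved mod length", {
  set.seed(9)
  seq <- randomDnaStr(200)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      start = c(5L, 80L, 150L), end = c(20L, 110L, 180L),
                      strand = "+", translation = "MAA", pham_id = NA,
                      product = NA)
  g <- PhageGenome("circ3", seq, circular = TRUE, genes = genes)
  dist_mod <- function(x) outer(genes(x)$start, genes(x)$start, "-") %% 200
  before <- dist_mod(g)
  r <- reorientCircular(g, "g2")
  after <- dist_mod(r)
  ids_b <- genes(g)$gene_id; ids_a <- genes(r)$gene_id
  expect_equal(after[match(ids_b, ids_a), match(ids_b, ids_a)], before,
               ignore_attr = TRUE)
})

test_that("reorientation errors are raised for undefined cases", {
  genes <- data.frame(gene_id = c("f", "r"), start = c(10L, 40L),
                      end = c(22L, 70L), strand = c("+", "-"),
                      translation = "MAA", pham_id = NA, product = NA)
  g <- PhageGenome("circ", strrep("ACGT", 25), circular = TRUE,
                   genes = genes)
  expect_error(reorientCircular(g, "r"), "minus strand")
  expect_error(reorientCircular(g, "missing"), "not found")
  lin <- PhageGenome("lin", strrep("ACGT", 25), circular = FALSE,
                     genes = genes)
  expect_error(reorientCircular(lin, "f"), "not circular")
})
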
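# Genome similarity metrics: GCS, AAI, PEQ, HSPs, gNI.

# two toy genomes sharing 3 of 5 phams each; the shared homologues are
# identical copies, the rest genome-private
.toyPair <- function() {
  set.seed(101)
  shared <- replicate(3, randomAaStr(100))
  privA <- replicate(2, randomAaStr(100))
  privB <- replicate(2, randomAaStr(100))
  ga <- toyGenome("A", c(shared, privA),
                  phams = c("p1", "p2", "p3", "pa1", "pa2"))
  gb <- toyGenome("B", c(shared, privB),
                  phams = c("p1", "p2", "p3", "pb1", "pb2"))
  df <- rbind(
    data.frame(genome_id = "A", gene_id = genes(ga)$gene_id,
               pham_id = genes(ga)$pham_id,
               translation = genes(ga)$translation),
    data.frame(genome_id = "B", gene_id = genes(gb)$gene_id,
               pham_id = genes(gb)$pham_id,
               translation = genes(gb)$translation))
  list(a = ga, b = gb, phams = makePhamSet(df))
}

test_that("GCS is the mean directed shared-gene fraction", {
  tp <- .toyPair()
  # 3 of 5 genes shared in each direction -> 60%, the classic two-phage
  # shared-gene-content figure
  expect_equal(gcs(tp$a, tp$b, tp$phams), 60)
  expect_equal(gcs(tp$a, tp$a, tp$phams), 100)
})

test_that("GCS is 0 for disjoint pham sets and errors without phams", {
  tp <- .toyPair()
  ga <- tp$a
  gn <- genes(ga); gn$pham_id <- c("q1", "q2", "q3", "q4", "q5")
  genes(ga) <- gn
  df <- rbind(
    data.frame(genome_id = "A2", gene_id = gn$gene_id, pham_id = gn$pham_id,
               translation = gn$translation),
    data.frame(genome_id = "B", gene_id = genes(tp$b)$gene_id,
               pham_id = genes(tp$b)$pham_id,
               translation = genes(tp$b)$translation))
  ga@genomeId <- "A2"
  expect_equal(gcs(ga, tp$b, makePhamSet(df)), 0)
  empty <- PhageGenome("empty", strrep("ACGT", 30))
  expect_error(gcs(empty, tp$b, tp$phams), "no genes")
})

test_that("AAI reflects the identity of shared homologues", {
  tp <- .toyPair()
  res <- aaiShared(tp$a, tp$b, tp$phams)
  expect_equal(res$aai, 100)            # shared copies are identical
  expect_equal(res$sharedWeight, 3 * 200)
  # one shared pham at 80% identity between 100-aa proteins
  set.seed(7)
  p <- randomAaStr(100)
  q <- substituteAt(p, sample(100, 20))
  df <- data.frame(genome_id = c("X", "Y"), gene_id = "g1",
                   pham_id = "p1", translation = c(p, q))
  gx <- toyGenome("X", p, phams = "p1")
  gy <- toyGenome("Y", q, phams = "p1")
  res2 <- aaiShared(gx, gy, makePhamSet(df))
  expect_equal(res2$aai, 80)
  # no shared pham -> (0, 0)
  df3 <- data.frame(genome_id = c("X", "Y"), gene_id = "g1",
                    pham_id = c("p1", "p2"), translation = c(p, q))
  res3 <- aaiShared(gx, gy, makePhamSet(df3))
  expect_equal(res3$aai, 0)
  expect_equal(res3$sharedWeight, 0)
})

test_that("PEQ matches the hand-computed length-weighted quotient", {
  # each genome: one shared 100-aa homologue at 90% identity plus one
  # unshared 100-aa gene -> 100 * (200 * 0.9) / 400 = 45
  set.seed(3)
  p <- randomAaStr(100)
  q <- substituteAt(p, sample(100, 10))
  ga <- toyGenome("A", c(p, randomAaStr(100)), phams = c("s", "ua"))
  gb <- toyGenome("B", c(q, randomAaStr(100)), phams = c("s", "ub"))
  df <- rbind(data.frame(genome_id = "A", gene_id = genes(ga)$gene_id,
                         pham_id = genes(ga)$pham_id,
                         translation = genes(ga)$translation),
              data.frame(genome_id = "B", gene_id = genes(gb)$gene_id,
                         pham_id = genes(gb)$pham_id,
                         translation = genes(gb)$translation))
  expect_equal(peq(ga, gb, makePhamSet(df)), 45)
  expect_equal(peq(ga, ga, makePhamSet(df)), 100)
})

test_that("PEQ is bounded by the shared length fraction", {
  fx <- defaultDataset()
  gs <- fx$genomes
  lookup <- phamkit:::.phamLookup(fx$phams)
  set.seed(12)
  for (k in 1:10) {
    ij <- sample(length(gs), 2)
    a <- gs[[ij[1]]]; b <- gs[[ij[2]]]
    val <- fx$peq[genomeId(a), genomeId(b)]
    ga <- phamkit:::.genePhams(a, lookup)
    gb <- phamkit:::.genePhams(b, lookup)
    shared_len <- sum(ga$aa_len[ga$pham %in% gb$pham]) +
      sum(gb$aa_len[gb$pham %in% ga$pham])
    expect_lte(val, 100 * shared_len / (sum(ga$aa_len) + sum(gb$aa_len)) +
                 1e-9)
  }
})

# ---------------------------------------------------------------------------
# HSPs

test_that("self-comparison yields one full-length perfect HSP", {
  set.seed(30)
  s <- randomDnaStr(10000)
  h <- findHsps(s, s)
  expect_equal(h$q_start[1], 0)
  expect_equal(h$q_end[1], 10000)
  expect_equal(h$identities[1], 10000)
  expect_equal(h$strand[1], "+")
})

test_that("a reverse-complement subject is found on the minus strand", {
  set.seed(31)
  s <- randomDnaStr(8000)
  h <- findHsps(s, phamkit:::revComp(s))
  expect_equal(h$strand[1], "-")
  expect_equal(h$q_start[1], 0)
  expect_equal(h$q_end[1], 8000)
  expect_equal(h$s_start[1], 0)   # forward-strand subject coordinates
  expect_equal(h$s_end[1], 8000)
  expect_equal(h$identities[1], 8000)
})

test_that("an embedded shared segment is recovered within word-size slack", {
  set.seed(32)
  for (k in 1:3) {
    seg <- randomDnaStr(500)
    qpos <- sample(1000:8000, 1); spos <- sample(1000:8000, 1)
    q <- paste0(randomDnaStr(qpos), seg, randomDnaStr(10000 - qpos - 500))
    s <- paste0(randomDnaStr(spos), seg, randomDnaStr(10000 - spos - 500))
    h <- findHsps(q, s)
    expect_gte(nrow(h), 1)
    expect_lte(abs(h$q_start[1] - qpos), 11)
    expect_lte(abs(h$q_end[1] - (qpos + 500)), 11)
    expect_lte(abs(h$s_start[1] - spos), 11)
    expect_gte(h$identities[1], 500 - 11)
  }
})

test_that("findHsps validates its inputs", {
  expect_error(findHsps("ACGTACG", "ACGTACGTACGT"), "wordSize")
  expect_error(findHsps(strrep("ACGT", 5), strrep("ACGT", 5),
                        wordSize = 5), "wordSize")
})

# ---------------------------------------------------------------------------
# gNI

test_that("gNI is 100 for self and exactly 0 for unrelated sequences", {
  set.seed(40)
  a <- PhageGenome("a", randomDnaStr(20000))
  b <- PhageGenome("b", randomDnaStr(20000))
  expect_equal(gni(a, a), 100)
  expect_identical(gni(a, b), 0)
  # oracle: the best ungapped segment between unrelated 20-kbp sequences
  # stays far below the score an E-value of 1e-4 requires (~22)
  top <- oracleTopSegment(substr(genomeSeq(a), 1, 2000),
                          substr(genomeSeq(b), 1, 2000))
  expect_lt(top$score, 22)
})

test_that("gNI is symmetric and degrades with shared fraction", {
  set.seed(41)
  core <- randomDnaStr(6000)
  a <- PhageGenome("a", paste0(core, randomDnaStr(4000)))
  b <- PhageGenome("b", paste0(randomDnaStr(2000), core))
  v1 <- gni(a, b); v2 <- gni(b, a)
  expect_equal(v1, v2)
  # shared 6000 of (10000 + 8000) bp -> about 2*6000/18000
  expect_gt(v1, 60); expect_lt(v1, 72)
})

test_that("pairwise matrices are symmetric with a 100 diagonal", {
  set.seed(50)
  base <- randomDnaStr(5000)
  gs <- lapply(1:3, function(i) PhageGenome(sprintf("g%d", i), base))
  m <- pairwiseMatrix(gs, "gni")
  expect_true(all(simValues(m) == 100))
  dup <- c(gs, list(PhageGenome("g1", base)))
  expect_error(pairwiseMatrix(dup, "gni"), "duplicate")
})

test_that("matrix entries equal pair-by-pair recomputation", {
  fx <- defaultDataset()
  v <- simValues(fx$peq)
  expect_identical(v, t(v))
  set.seed(51)
  for (k in 1:5) {
    ij <- sample(nrow(v), 2)
    a <- fx$genomes[[ij[1]]]; b <- fx$genomes[[ij[2]]]
    expect_equal(v[ij[1], ij[2]], peq(a, b, fx$phams))
  }
  w <- simValues(fx$gni)
  ij <- sample(nrow(w), 2)
  expect_equal(w[ij[1], ij[2]],
               gni(fx$genomes[[ij[1]]], fx$genomes[[ij[2]]]))
})
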
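# Taxonomy gap-filling and similarity/taxonomy concordance.

.toyTaxonomy <- function() {
  # 10 genomes, ranks partially named; nested structure by construction
  data.frame(
    genome_id = sprintf("p%02d", 1:10),
    species = c("s1", "s1", "s2", NA, NA, "s3", NA, NA, NA, NA),
    genus = c("gA", "gA", "gA", "gA", "gB", "gB", "gB", NA, "gC", NA),
    subfamily = c("sfX", NA, NA, NA, NA, NA, "sfX", "sfY", NA, NA),
    family = c("famQ", NA, NA, NA, NA, NA, NA, NA, NA, "famR"),
    stringsAsFactors = FALSE)
}

.toyMatrix <- function(ids) {
  n <- length(ids)
  set.seed(70)
  v <- matrix(runif(n * n, 0, 100), n, n)
  v[] <- (v + t(v)) / 2
  diag(v) <- 100
  dimnames(v) <- list(ids, ids)
  SimilarityMatrix(v, "gni")
}

test_that("gap filling creates shared placeholder parents", {
  tax <- data.frame(genome_id = c("p1", "p2"), species = NA_character_,
                    genus = "Fromanvirus", subfamily = NA_character_,
                    family = NA_character_)
  out <- gapfillRanks(tax)
  expect_equal(out$subfamily, rep("unnamed_subfamily_Fromanvirus", 2))
  expect_equal(out$family, rep("unnamed_family_Fromanvirus", 2))
  expect_equal(out$subfamily_src, rep("gap_filled", 2))
  expect_equal(out$species_src, rep("none", 2))
})

test_that("fully named lineages pass through unchanged", {
  tax <- data.frame(genome_id = "p1", species = "s", genus = "g",
                    subfamily = "sf", family = "f")
  out <- gapfillRanks(tax)
  expect_identical(out[names(tax)], tax)
  expect_true(all(unlist(out[paste0(phamkit:::TAX_RANKS, "_src")])
                  == "given"))
})

test_that("a named parent elsewhere in the table is reused", {
  tax <- data.frame(genome_id = c("p1", "p2"), species = c("s1", "s1"),
                    genus = c("gA", NA), subfamily = NA_character_,
                    family = NA_character_)
  out <- gapfillRanks(tax)
  expect_equal(out$genus, c("gA", "gA"))
  expect_equal(out$genus_src, c("given", "gap_filled"))
})

test_that("conflicting parents raise a consistency error", {
  # one genus under two families (via its placeholder subfamily)
  expect_error(gapfillRanks(
    data.frame(genome_id = c("p1", "p2"), species = NA_character_,
               genus = c("gA", "gA"), subfamily = NA_character_,
               family = c("famQ", "famR"))), "two different")
  # one species under two genera
  expect_error(gapfillRanks(
    data.frame(genome_id = c("p1", "p2"), species = c("s1", "s1"),
               genus = c("gA", "gB"), subfamily = NA_character_,
               family = NA_character_)), "two different")
})

test_that("gap filling is idempotent and yields nested pair sets", {
  tax <- gapfillRanks(.toyTaxonomy())
  again <- gapfillRanks(tax[c("genome_id", phamkit:::TAX_RANKS)])
  expect_identical(again[c("genome_id", phamkit:::TAX_RANKS)],
                   tax[c("genome_id", phamkit:::TAX_RANKS)])
  m <- .toyMatrix(tax$genome_id)
  pair_sets <- lapply(phamkit:::TAX_RANKS, function(r)
    names(intraRankValues(m, tax, r)))
  for (k in 1:3) {
    expect_true(all(pair_sets[[k]] %in% pair_sets[[k + 1]]))
  }
})

test_that("intra-rank pair enumeration is exact", {
  tax <- data.frame(genome_id = c("p1", "p2", "p3", "p4"),
                    species = c("s1", "s1", "s1", NA),
                    genus = c("g1", "g1", "g1", "g1"),
                    subfamily = NA_character_, family = NA_character_)
  tax <- gapfillRanks(tax)
  m <- .toyMatrix(tax$genome_id)
  sp <- intraRankValues(m, tax, "species")
  expect_length(sp, choose(3, 2))
  ge <- intraRankValues(m, tax, "genus")
  expect_length(ge, choose(4, 2))
  v <- simValues(m)
  expect_equal(unname(sp), c(v["p1", "p2"], v["p1", "p3"], v["p2", "p3"]))
  # all genomes in distinct families -> no pairs
  lone <- data.frame(genome_id = c("p1", "p2"), species = NA_character_,
                     genus = NA_character_, subfamily = NA_character_,
                     family = c("f1", "f2"))
  expect_length(intraRankValues(.toyMatrix(c("p1", "p2")),
                                gapfillRanks(lone), "family"), 0)
  expect_error(intraRankValues(m, tax[-1, ], "genus"), "p1")
})

test_that("concordance summaries match direct enumeration", {
  tax <- gapfillRanks(.toyTaxonomy())
  m <- .toyMatrix(tax$genome_id)
  cs <- concordanceSummary(m, tax)
  for (r in phamkit:::TAX_RANKS) {
    vals <- intraRankValues(m, tax, r)
    row <- cs$summary[cs$summary$rank == r, ]
    expect_equal(row$n_pairs, length(vals))
    if (length(vals)) {
      expect_equal(row$frac_ge_50, mean(vals >= 50))
      expect_equal(row$frac_zero, mean(vals == 0))
    }
    h <- cs$histograms[cs$histograms$rank == r, ]
    expect_equal(sum(h$count), length(vals))   # histogram conservation
    # bit-exact bin edges: recount one bin by hand
    expect_equal(h$count[h$bin_lo == 45],
                 sum(vals >= 45 & vals < 50))
  }
})

test_that("identical matrices fit on the Y = X line", {
  tax <- gapfillRanks(.toyTaxonomy())
  m <- .toyMatrix(tax$genome_id)
  cs <- concordanceSummary(m, tax, peqMat = m)
  expect_equal(cs$fit$slope, 1)
  expect_equal(cs$fit$intercept, 0)
  expect_equal(cs$fit$r_squared, 1)
  expect_equal(cs$fit$n, choose(10, 2))
})

test_that("an all-similar genus scores full concordance", {
  ids <- c("q1", "q2", "q3")
  v <- matrix(100, 3, 3, dimnames = list(ids, ids))
  m <- SimilarityMatrix(v, "gni")
  tax <- gapfillRanks(data.frame(genome_id = ids, species = NA_character_,
                                 genus = "gOne", subfamily = NA_character_,
                                 family = NA_character_))
  cs <- concordanceSummary(m, tax)
  row <- cs$summary[cs$summary$rank == "genus", ]
  expect_equal(row$frac_ge_50, 1)
  expect_equal(row$frac_zero, 0)
})
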
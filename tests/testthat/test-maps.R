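# SVG comparison maps: display-rule contracts asserted on the XML.

library(xml2)

.svgNodes <- function(doc, xpath) {
  xml_find_all(read_xml(doc), xpath, ns = c(svg = "http://www.w3.org/2000/svg"))
}

test_that("genes draw above the ruler on + and below on -", {
  set.seed(80)
  g <- toyGenome("two_strand", c(randomAaStr(60), randomAaStr(60)),
                 phams = c("p1", "p2"), strands = c("+", "-"))
  df <- data.frame(genome_id = "two_strand", gene_id = genes(g)$gene_id,
                   pham_id = genes(g)$pham_id,
                   translation = genes(g)$translation)
  doc <- renderComparisonMap(list(g), makePhamSet(df))
  rects <- .svgNodes(doc, "//svg:rect[@class='gene']")
  expect_length(rects, 2)
  y <- as.numeric(xml_attr(rects, "y"))
  ruler <- as.numeric(xml_attr(.svgNodes(doc, "//svg:line[not(@class)]")[[1]],
                               "y1"))
  strands <- xml_attr(rects, "data-strand")
  expect_true(y[strands == "+"] < ruler)
  expect_true(y[strands == "-"] > ruler)
  # ruler furniture: one tick per 100 bp (including position 0)
  expect_length(.svgNodes(doc, "//svg:line[@class='tick']"),
                floor(seqLength(g) / 100) + 1)
})

test_that("identical genomes shade violet across their full length", {
  set.seed(81)
  g1 <- toyGenome("copy1", c(randomAaStr(150), randomAaStr(150)),
                  phams = c("p1", "p2"))
  g2 <- PhageGenome("copy2", genomeSeq(g1), genes = genes(g1))
  df <- rbind(
    data.frame(genome_id = "copy1", gene_id = genes(g1)$gene_id,
               pham_id = genes(g1)$pham_id,
               translation = genes(g1)$translation),
    data.frame(genome_id = "copy2", gene_id = genes(g2)$gene_id,
               pham_id = genes(g2)$pham_id,
               translation = genes(g2)$translation))
  doc <- renderComparisonMap(list(g1, g2), makePhamSet(df))
  polys <- .svgNodes(doc, "//svg:polygon[@class='hsp']")
  expect_gte(length(polys), 1)
  ident <- as.numeric(xml_attr(polys, "data-identity"))
  expect_true(any(ident == 1))
  # identity 1 maps to the violet end of the spectrum (hue 270)
  expect_match(xml_attr(polys[which.max(ident)], "fill"), "hsl\\(270")
})

test_that("shared phams share a fill and orphams are white", {
  set.seed(82)
  shared <- replicate(3, randomAaStr(100))
  ga <- toyGenome("ga", c(shared, randomAaStr(100)),
                  phams = c("p1", "p2", "p3", "orA"))
  gb <- toyGenome("gb", c(shared[1:2], randomAaStr(100), shared[3]),
                  phams = c("p1", "p2", "orB", "p3"))
  df <- rbind(
    data.frame(genome_id = "ga", gene_id = genes(ga)$gene_id,
               pham_id = genes(ga)$pham_id,
               translation = genes(ga)$translation),
    data.frame(genome_id = "gb", gene_id = genes(gb)$gene_id,
               pham_id = genes(gb)$pham_id,
               translation = genes(gb)$translation))
  doc <- renderComparisonMap(list(ga, gb), makePhamSet(df))
  rects <- .svgNodes(doc, "//svg:rect[@class='gene']")
  pham <- xml_attr(rects, "data-pham")
  fill <- xml_attr(rects, "fill")
  for (p in c("p1", "p2", "p3"))
    expect_length(unique(fill[pham == p]), 1)
  expect_true(all(fill[pham %in% c("orA", "orB")] == "#FFFFFF"))
  expect_true(all(fill[pham %in% c("p1", "p2", "p3")] != "#FFFFFF"))
  # pham labels carry the member count in parentheses
  labels <- xml_text(.svgNodes(doc, "//svg:text[@class='pham-label']"))
  expect_true(any(grepl("\\(2\\)$", labels)))
})

test_that("no shading is drawn for HSPs above the E-value cutoff", {
  set.seed(83)
  ga <- toyGenome("wa", randomAaStr(200), phams = "p1")
  gb <- toyGenome("wb", randomAaStr(200), phams = "p1")
  # hand the renderer an HSP list whose only entry fails the filter
  fake <- data.frame(q_start = 0L, q_end = 50L, s_start = 0L, s_end = 50L,
                     identities = 40L, score = 10, strand = "+",
                     evalue = 1e-2)
  df <- rbind(data.frame(genome_id = "wa", gene_id = genes(ga)$gene_id,
                         pham_id = "p1", translation = genes(ga)$translation),
              data.frame(genome_id = "wb", gene_id = genes(gb)$gene_id,
                         pham_id = "p1", translation = genes(gb)$translation))
  doc <- renderComparisonMap(list(ga, gb), makePhamSet(df),
                             hsps = list("wa|wb" = fake), evalueMax = 1e-4)
  expect_length(.svgNodes(doc, "//svg:polygon[@class='hsp']"), 0)
  expect_error(
    renderComparisonMap(list(ga, gb), makePhamSet(df),
                        hsps = list("wa|nope" = fake)), "unknown genome")
})

test_that("unassigned genes and coordinate windows are handled", {
  set.seed(84)
  g <- toyGenome("nogaps", c(randomAaStr(80), randomAaStr(80)),
                 phams = c("p1", NA))
  df <- data.frame(genome_id = "nogaps", gene_id = genes(g)$gene_id[1],
                   pham_id = "p1", translation = genes(g)$translation[1])
  expect_error(renderComparisonMap(list(g), makePhamSet(df)),
               "without pham")
  gn <- genes(g); gn$pham_id <- c("p1", "p2"); genes(g) <- gn
  df2 <- data.frame(genome_id = "nogaps", gene_id = gn$gene_id,
                    pham_id = gn$pham_id, translation = gn$translation)
  # a window covering only the first gene drops the second box
  doc <- renderComparisonMap(list(g), makePhamSet(df2),
                             window = c(0, genes(g)$end[1] + 5))
  rects <- .svgNodes(doc, "//svg:rect[@class='gene']")
  expect_length(rects, 1)
  expect_equal(xml_attr(rects, "data-pham"), "p1")
})
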
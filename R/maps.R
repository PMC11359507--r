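## Phamerator-style pairwise genome comparison maps as SVG.
##
## Display rules: each genome is a ruler with 1-kbp labels and ticks every
## 100 bp; genes are boxes above the ruler when transcribed rightwards
## (+) and below when leftwards (-); the box is filled by a deterministic
## pham colour (orphams white), the gene name sits inside the box and the
## pham number with its member count in parentheses above it; putative
## function strings are rendered when present. Between consecutive
## rulers, each HSP passing the E-value filter is drawn as a shaded
## quadrilateral, spectrum-coloured by identity fraction from violet
## (most similar) to red (least similar among the displayed HSPs).
## SVG is used so every display rule is text-assertable.

.PALETTE <- c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231",
              "#911eb4", "#46f0f0", "#f032e6", "#bcf60c", "#fabebe",
              "#008080", "#e6beff", "#9a6324", "#fffac8", "#800000",
              "#aaffc3", "#808000", "#ffd8b1", "#000075", "#808080")

#' Deterministic pham colour
#'
#' Hashes the pham id into a fixed palette; orphams are white. Equal pham
#' ids always map to equal colours, across genomes and across sessions.
#'
#' @param phamId pham id string(s).
#' @param orpham logical vector: is the pham an orpham?
#' @return hex/named colour strings.
#' @export
phamColor <- function(phamId, orpham = FALSE) {
  col <- vapply(phamId, function(p) {
    h <- sum(utf8ToInt(p) * seq_len(nchar(p))) %% length(.PALETTE)
    .PALETTE[h + 1L]
  }, character(1), USE.NAMES = FALSE)
  col[orpham] <- "#FFFFFF"
  col
}

.hspHue <- function(idFrac, idMin) {
  if (idMin >= 1) return(rep(270, length(idFrac)))
  270 * (idFrac - idMin) / (1 - idMin)
}

#' Render a Phamerator-style comparison map
#'
#' @param genomes ordered list of [PhageGenome-class] with pham-assigned
#'   genes (a gene without a pham raises an error).
#' @param phams the [PhamSet-class] (provides member counts and orpham
#'   status).
#' @param file optional path; when given the SVG is written there.
#' @param hsps optional named list of precomputed HSP tables for each
#'   consecutive pair, named `"<idA>|<idB>"` (as from [findHsps()]);
#'   computed on the fly when NULL. A name referring to an unknown genome
#'   raises an error.
#' @param evalueMax only HSPs with E-value at or below this are shaded
#'   (default 1e-4).
#' @param window optional `c(from, to)` coordinate window (0-based
#'   half-open) for zoomed views; applied to every genome row.
#' @param width figure width in pixels.
#' @return the SVG document as a single string, invisibly when `file` is
#'   given.
#' @export
renderComparisonMap <- function(genomes, phams, file = NULL, hsps = NULL,
                                evalueMax = 1e-4, window = NULL,
                                width = 1200) {
  if (is(genomes, "PhageGenome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1, is(phams, "PhamSet"))
  ids <- vapply(genomes, genomeId, character(1))
  for (g in genomes) {
    gn <- genes(g)
    if (nrow(gn) > 0 && anyNA(gn$pham_id))
      stop("genome '", genomeId(g), "' has genes without pham assignment: ",
           paste(head(gn$gene_id[is.na(gn$pham_id)], 3), collapse = ", "))
  }
  if (!is.null(hsps)) {
    for (nm in names(hsps)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
      if (!all(pair %in% ids))
        stop("hsp list refers to unknown genome(s): ",
             paste(setdiff(pair, ids), collapse = ", "))
    }
  } else if (length(genomes) > 1) {
    hsps <- list()
    for (i in seq_len(length(genomes) - 1)) {
      nm <- paste(ids[i], ids[i + 1], sep = "|")
      hsps[[nm]] <- findHsps(genomeSeq(genomes[[i]]),
                             genomeSeq(genomes[[i + 1]]),
                             evalueMax = evalueMax)
    }
  }

  sizes <- phamSizes(phams)
  margin <- 60; rowH <- 150; boxH <- 22; rulerGap <- 4
  from <- if (is.null(window)) 0 else window[1]
  to <- if (is.null(window)) max(vapply(genomes, seqLength, numeric(1)))
        else window[2]
  scale <- (width - 2 * margin) / (to - from)
  x_of <- function(bp) margin + (bp - from) * scale
  height <- margin + rowH * length(genomes)

  svg <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d">'), width, height))
  ruler_y <- function(i) margin + (i - 1) * rowH + rowH / 2

  # inter-genome shading first so gene boxes draw on top
  for (i in seq_len(max(length(genomes) - 1, 0))) {
    nm <- paste(ids[i], ids[i + 1], sep = "|")
    h <- hsps[[nm]]
    if (is.null(h) || nrow(h) == 0) next
    h <- h[h$evalue <= evalueMax, , drop = FALSE]
    if (nrow(h) == 0) next
    idFrac <- h$identities / (h$q_end - h$q_start)
    idMin <- min(idFrac)
    hue <- .hspHue(idFrac, idMin)
    y_top <- ruler_y(i) + rulerGap
    y_bot <- ruler_y(i + 1) - rulerGap
    for (k in seq_len(nrow(h))) {
      qx1 <- x_of(h$q_start[k]); qx2 <- x_of(h$q_end[k])
      sx1 <- x_of(h$s_start[k]); sx2 <- x_of(h$s_end[k])
      if (h$strand[k] == "-") { tmp <- sx1; sx1 <- sx2; sx2 <- tmp }
      svg <- c(svg, sprintf(paste0(
        '<polygon class="hsp" points="%.1f,%.1f %.1f,%.1f %.1f,%.1f ',
        '%.1f,%.1f" fill="hsl(%.1f, 85%%, 60%%)" fill-opacity="0.6" ',
        'data-evalue="%.3g" data-identity="%.4f"/>'),
        qx1, y_top, qx2, y_top, sx2, y_bot, sx1, y_bot,
        hue[k], h$evalue[k], idFrac[k]))
    }
  }

  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    ry <- ruler_y(i)
    L <- seqLength(g)
    w_from <- max(from, 0); w_to <- min(to, L)
    svg <- c(svg, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
      x_of(w_from), ry, x_of(w_to), ry))
    svg <- c(svg, sprintf(
      '<text x="%.1f" y="%.1f" font-size="12" text-anchor="start">%s</text>',
      margin, ry - rowH / 2 + 12, xmlEscape(genomeId(g))))
    # ticks every 100 bp, taller + labelled each kbp
    for (bp in seq(ceiling(w_from / 100) * 100, w_to, by = 100)) {
      kbp <- bp %% 1000 == 0
      svg <- c(svg, sprintf(paste0(
        '<line class="tick" x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" ',
        'stroke="black" stroke-width="0.5"/>'),
        x_of(bp), ry, x_of(bp), ry + (if (kbp) 6 else 3)))
      if (kbp) svg <- c(svg, sprintf(paste0(
        '<text x="%.1f" y="%.1f" font-size="8" text-anchor="middle">',
        '%d</text>'), x_of(bp), ry + 16, bp %/% 1000))
    }
    gn <- genes(g)
    if (nrow(gn) == 0) next
    vis <- gn$end > w_from & gn$start < w_to
    for (k in which(vis)) {
      x1 <- x_of(max(gn$start[k], w_from))
      x2 <- x_of(min(gn$end[k], w_to))
      above <- gn$strand[k] == "+"
      y <- if (above) ry - rulerGap - boxH else ry + rulerGap
      sz <- sizes[[gn$pham_id[k]]]
      fill <- phamColor(gn$pham_id[k], orpham = sz == 1L)
      svg <- c(svg, sprintf(paste0(
        '<rect class="gene" x="%.1f" y="%.1f" width="%.1f" height="%d" ',
        'fill="%s" stroke="black" stroke-width="0.6" data-pham="%s" ',
        'data-genome="%s" data-gene="%s" data-strand="%s"/>'),
        x1, y, max(x2 - x1, 0.5), boxH, fill, xmlEscape(gn$pham_id[k]),
        xmlEscape(genomeId(g)), xmlEscape(gn$gene_id[k]), gn$strand[k]))
      svg <- c(svg, sprintf(paste0(
        '<text class="gene-name" x="%.1f" y="%.1f" font-size="7" ',
        'text-anchor="middle">%s</text>'),
        (x1 + x2) / 2, y + boxH / 2 + 2.5, xmlEscape(gn$gene_id[k])))
      # pham number with member count, above the box
      pham_label <- sprintf("%s (%d)", sub("^pham_", "", gn$pham_id[k]), sz)
      label_y <- if (above) y - 3 else y + boxH + 9
      svg <- c(svg, sprintf(paste0(
        '<text class="pham-label" x="%.1f" y="%.1f" font-size="7" ',
        'text-anchor="middle">%s</text>'),
        (x1 + x2) / 2, label_y, xmlEscape(pham_label)))
      if (!is.na(gn$product[k])) {
        func_y <- if (above) y - 12 else y + boxH + 19
        svg <- c(svg, sprintf(paste0(
          '<text class="function" x="%.1f" y="%.1f" font-size="7" ',
          'text-anchor="middle">%s</text>'),
          (x1 + x2) / 2, func_y, xmlEscape(gn$product[k])))
      }
    }
  }
  svg <- c(svg, "</svg>")
  doc <- paste(svg, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
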
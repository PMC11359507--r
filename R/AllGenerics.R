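#' @name accessors
#' @title Accessors for phamkit S4 classes
#' @param x a phamkit object.
#' @param value replacement value.
#' @description Slot accessors: prefer these over direct `@` access.
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("genes<-", function(x, value) standardGeneric("genes<-"))
#' @rdname accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname accessors
#' @export
setGeneric("genomeMeta", function(x) standardGeneric("genomeMeta"))
#' @rdname accessors
#' @export
setGeneric("phamTable", function(x) standardGeneric("phamTable"))
#' @rdname accessors
#' @export
setGeneric("phamSizes", function(x) standardGeneric("phamSizes"))
#' @rdname accessors
#' @export
setGeneric("orphams", function(x) standardGeneric("orphams"))
#' @rdname accessors
#' @export
setGeneric("nPhams", function(x) standardGeneric("nPhams"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setGeneric("simMetric", function(x) standardGeneric("simMetric"))
#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))
#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname accessors
#' @export
setMethod("genomeId", "PhageGenome", function(x) x@genomeId)
#' @rdname accessors
#' @export
setMethod("genomeSeq", "PhageGenome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("isCircular", "PhageGenome", function(x) x@circular)
#' @rdname accessors
#' @export
setMethod("genes", "PhageGenome", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("genes<-", "PhageGenome", function(x, value) {
  value <- as.data.frame(value, stringsAsFactors = FALSE)
  if (nrow(value) > 0) {
    value <- value[order(value$start, value$end, value$gene_id), ,
                   drop = FALSE]
    rownames(value) <- NULL
  }
  x@genes <- value
  validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("seqLength", "PhageGenome", function(x) nchar(x@sequence))
#' @rdname accessors
#' @export
setMethod("genomeMeta", "PhageGenome", function(x) x@metadata)

setMethod("show", "PhageGenome", function(object) {
  cat("PhageGenome '", object@genomeId, "': ",
      format(nchar(object@sequence), big.mark = ","), " bp, ",
      nrow(object@genes), " genes, ",
      if (object@circular) "circular" else "linear", "\n", sep = "")
  if (nrow(object@genes) > 0) {
    n_ph <- sum(!is.na(object@genes$pham_id))
    cat("  genes with pham assignment: ", n_ph, "/", nrow(object@genes),
        "\n", sep = "")
  }
})

#' @rdname accessors
#' @export
setMethod("phamTable", "PhamSet", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("phamSizes", "PhamSet", function(x) {
  tab <- table(x@assignments$pham_id)
  setNames(as.integer(tab), names(tab))
})
#' @rdname accessors
#' @export
setMethod("orphams", "PhamSet", function(x) {
  sz <- phamSizes(x)
  names(sz)[sz == 1L]
})
#' @rdname accessors
#' @export
setMethod("nPhams", "PhamSet",
          function(x) length(unique(x@assignments$pham_id)))
#' @rdname accessors
#' @export
setMethod("representatives", "PhamSet", function(x) x@representatives)

setMethod("show", "PhamSet", function(object) {
  sz <- phamSizes(object)
  cat("PhamSet: ", nrow(object@assignments), " genes in ", length(sz),
      " phams (", sum(sz == 1L), " orphams)\n", sep = "")
  if (length(sz)) cat("  largest pham: ", max(sz), " members\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("simMetric", "SimilarityMatrix", function(x) x@metric)
#' @rdname accessors
#' @export
setMethod("simValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("genomeIds", "SimilarityMatrix", function(x) rownames(x@values))

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat("SimilarityMatrix [", object@metric, "]: ", nrow(v), " genomes\n",
      sep = "")
  if (length(off))
    cat(sprintf("  off-diagonal range: %.2f - %.2f (median %.2f)\n",
                min(off), max(off), median(off)))
})

#' @rdname accessors
#' @param i,j,drop standard matrix subsetting arguments.
#' @export
setMethod("[", "SimilarityMatrix", function(x, i, j, drop = FALSE) {
  x@values[i, j, drop = drop]
})
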
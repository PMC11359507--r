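#' @importFrom methods new validObject is slot
#' @importFrom stats rpois rlnorm runif setNames median cor lm coef
#' @importFrom utils head read.delim write.table packageVersion combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## cache for lazily loaded substitution matrices etc.
.pkg_cache <- new.env(parent = emptyenv())

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`
#' (Mersenne-Twister, R's default), restoring the caller's RNG state
#' afterwards so library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Spreadsheet-style letter labels
#'
#' Maps 1, 2, ... to A, B, ..., Z, AA, AB, ... as used for cluster names.
#'
#' @param i positive integer vector.
#' @return character vector of labels.
#' @keywords internal
letterLabels <- function(i) {
  vapply(i, function(n) {
    stopifnot(n >= 1)
    out <- character(0)
    while (n > 0) {
      r <- (n - 1L) %% 26L
      out <- c(LETTERS[r + 1L], out)
      n <- (n - 1L) %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Adjusted Rand index between two labelings
#'
#' Standard Hubert-Arabie adjusted Rand index; used to score recovery of
#' planted cluster structure. Labels are compared as partitions, so the
#' actual label values are irrelevant.
#'
#' @param a,b vectors of equal length giving two labelings of the same items.
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## Genetic code, translation table 11 (bacterial/archaeal/plant plastid).
## Codon -> amino-acid map; initiator codons handled by callers.
geneticCode11 <- function() {
  if (is.null(.pkg_cache$gc11)) {
    .pkg_cache$gc11 <- Biostrings::getGeneticCode("11")
  }
  .pkg_cache$gc11
}

## Reverse complement of a plain character DNA string.
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Translate a DNA string (length divisible by 3) with table 11.
## Start codons (ATG/GTG/TTG) at position 1 translate to M when
## `initiator = TRUE`, matching CDS convention. The terminal stop (if any)
## is dropped.
translateCds <- function(nt, initiator = TRUE) {
  n <- nchar(nt)
  if (n %% 3 != 0) stop("CDS length not divisible by 3: ", n)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  gc <- geneticCode11()
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("untranslatable codon in CDS")
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS")
  if (initiator && length(aa) &&
      codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

randomDna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = "")

randomProtein <- function(n, startM = TRUE) {
  aa <- sample(AA_ALPHABET, n, replace = TRUE)
  if (startM) aa[1] <- "M"
  paste(aa, collapse = "")
}

## Synonymous codon table: amino acid -> codons (table 11), stops excluded.
codonsForAa <- function() {
  if (is.null(.pkg_cache$codons_by_aa)) {
    gc <- geneticCode11()
    gc <- gc[gc != "*"]
    .pkg_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons_by_aa
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
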
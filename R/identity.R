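## Pairwise protein identity/coverage, the primitive behind pham assembly
## and the amino-acid identity metrics. Alignment itself is delegated to
## Biostrings::pairwiseAlignment (ends-free global alignment, BLOSUM62,
## affine gaps); identity and coverage are derived from the alignment's
## C-level summaries (nmatch, alignment length, aligned ranges), with a
## string-level fallback for sequences containing X.

.blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

.AA_RE <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Global protein identity and coverage
#'
#' Aligns two amino-acid sequences with an ends-free global alignment
#' (BLOSUM62, gap open 10, gap extend 0.5) and reports:
#' \describe{
#'   \item{identity}{identical aligned residues divided by alignment
#'     columns, terminal gaps excluded. `X` is permitted in the input but
#'     never counts as a match, even against another `X`.}
#'   \item{coverage}{aligned residues of the shorter sequence divided by
#'     its length.}
#' }
#' The function is symmetric: `proteinIdentity(a, b)` equals
#' `proteinIdentity(b, a)` (arguments are ordered canonically before
#' aligning so tie-broken alignments cannot differ).
#'
#' @param a,b non-empty amino-acid strings (20-letter alphabet plus X).
#' @return named numeric vector `c(identity = , coverage = )`, both in
#'   \[0, 1\].
#' @export
#' @examples
#' proteinIdentity("MKLV", "MKLV")
proteinIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("protein sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  if (!grepl(.AA_RE, a) || !grepl(.AA_RE, b))
    stop("protein sequences must use the 20-letter amino-acid alphabet ",
         "(X permitted)")
  res <- .proteinIdentityPairs(a, b)
  c(identity = unname(res[1, "identity"]),
    coverage = unname(res[1, "coverage"]))
}

## Elementwise batched identity/coverage for paired vectors of amino-acid
## strings. Pairs are ordered canonically (lexicographically smaller
## string as pattern) so results are exactly symmetric.
.proteinIdentityPairs <- function(avec, bvec, chunk = 5000L) {
  stopifnot(length(avec) == length(bvec))
  n <- length(avec)
  res <- matrix(NA_real_, nrow = n, ncol = 2,
                dimnames = list(NULL, c("identity", "coverage")))
  if (n == 0) return(res)
  swap <- avec > bvec
  pat <- ifelse(swap, bvec, avec)
  sub <- ifelse(swap, avec, bvec)
  has_x <- grepl("X", pat, fixed = TRUE) | grepl("X", sub, fixed = TRUE)
  same <- pat == sub & !has_x
  res[same, ] <- rep(c(1, 1), each = sum(same))
  todo <- which(!same & !has_x)
  lo_starts <- if (length(todo)) seq.int(1L, length(todo), by = chunk)
               else integer(0)
  for (lo in lo_starts) {
    idx <- todo[lo:min(lo + chunk - 1L, length(todo))]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(pat[idx]), Biostrings::AAStringSet(sub[idx]),
      type = "overlap", substitutionMatrix = .blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    cols <- Biostrings::nchar(aln)
    matches <- Biostrings::nmatch(aln)
    resA <- BiocGenerics::end(Biostrings::pattern(aln)) -
      BiocGenerics::start(Biostrings::pattern(aln)) + 1L
    resB <- BiocGenerics::end(Biostrings::subject(aln)) -
      BiocGenerics::start(Biostrings::subject(aln)) + 1L
    nA <- nchar(pat[idx]); nB <- nchar(sub[idx])
    shorter_res <- ifelse(nA <= nB, resA, resB)
    id <- ifelse(cols == 0, 0, matches / cols)
    cov <- ifelse(cols == 0, 0, shorter_res / pmin(nA, nB))
    res[idx, "identity"] <- id
    res[idx, "coverage"] <- cov
  }
  for (i in which(has_x)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pat[i]), Biostrings::AAString(sub[i]),
      type = "overlap", substitutionMatrix = .blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    res[i, ] <- .identityFromAlignmentStrings(aln, nchar(pat[i]),
                                              nchar(sub[i]))
  }
  res
}

## String-level computation, used only for X-containing sequences where
## "X never matches" departs from nmatch()'s definition.
.identityFromAlignmentStrings <- function(aln, nA, nB) {
  pa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pa)
  if (cols == 0) return(c(identity = 0, coverage = 0))
  pc <- strsplit(pa, "")[[1]]
  sc <- strsplit(sb, "")[[1]]
  matches <- sum(pc == sc & pc != "X" & pc != "-")
  resA <- sum(pc != "-")
  resB <- sum(sc != "-")
  shorter_res <- if (nA <= nB) resA else resB
  c(identity = matches / cols, coverage = shorter_res / min(nA, nB))
}

## Identity/coverage of each string in `queries` against one `subject`.
.proteinIdentityMany <- function(queries, subject) {
  .proteinIdentityPairs(queries, rep(subject, length(queries)))
}
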
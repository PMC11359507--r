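## Genome-vs-genome local alignment: exact-word seeding on both strands,
## ungapped X-drop extension (match +1 / mismatch -2), greedy merge of
## overlapping extensions, and a Karlin-Altschul E-value filter. This is a
## transparent stand-in for a BLASTN-style search, tuned for desk-scale
## phage genomes; E-values use the classic ungapped +1/-2 parameters
## (lambda = 1.28, K = 0.46) and serve purely as a significance filter.

KA_LAMBDA <- 1.28
KA_K <- 0.46

#' Find high-scoring segment pairs between two nucleotide sequences
#'
#' @param query,subject nucleotide strings (A/C/G/T), each at least
#'   `wordSize` long.
#' @param wordSize exact-match seed length (>= 7; default 11).
#' @param evalueMax maximum E-value for a reported HSP (default 1e-4, the
#'   conventional display threshold for genome-map shading).
#' @param xDrop ungapped X-drop termination parameter (default 20).
#' @return data.frame with columns q_start, q_end, s_start, s_end (0-based
#'   half-open; subject coordinates always on the forward subject strand),
#'   strand (`"+"` or `"-"`: strand of the subject relative to the query),
#'   identities, score, evalue; sorted by score descending. Zero rows when
#'   nothing passes the filter.
#' @details E = K * m * n * exp(-lambda * S) with the fixed ungapped
#'   +1/-2 parameters above; deterministic for fixed inputs.
#' @export
#' @examples
#' seq <- paste(sample(c("A","C","G","T"), 2000, replace = TRUE),
#'              collapse = "")
#' findHsps(seq, seq)[1, c("q_start", "q_end", "identities")]
findHsps <- function(query, subject, wordSize = 11L, evalueMax = 1e-4,
                     xDrop = 20) {
  if (wordSize < 7) stop("wordSize must be >= 7")
  query <- toupper(query); subject <- toupper(subject)
  if (nchar(query) < wordSize || nchar(subject) < wordSize)
    stop("sequences must be at least wordSize (", wordSize, ") long")
  if (grepl("[^ACGT]", query) || grepl("[^ACGT]", subject))
    stop("sequences must contain only A/C/G/T")
  m <- nchar(query); n <- nchar(subject)

  fwd <- .hsp_scan_cpp(query, subject, as.integer(wordSize), xDrop)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- .hsp_scan_cpp(query, revComp(subject), as.integer(wordSize), xDrop)
  if (nrow(rev) > 0) {
    # map subject coordinates back to the forward strand
    ss <- n - rev$s_end
    se <- n - rev$s_start
    rev$s_start <- ss
    rev$s_end <- se
    rev$strand <- "-"
  } else rev$strand <- character(0)
  out <- rbind(fwd, rev)
  if (nrow(out) == 0) {
    out$evalue <- numeric(0)
    return(out)
  }
  out$evalue <- KA_K * m * n * exp(-KA_LAMBDA * out$score)
  out <- out[out$evalue <= evalueMax, , drop = FALSE]
  out <- out[order(-out$score, out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
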
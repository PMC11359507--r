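# Independent oracles used to cross-check the package implementation.
# These deliberately use different algorithms from the package code paths.

# Brute-force six-frame ORF enumeration: for every start codon, scan
# forward codon-by-codon to the first in-frame stop; keep ORFs >= minAa;
# per stop keep the longest ORF (smallest start).
oracleOrfs <- function(seq, minAa) {
  gc11 <- Biostrings::getGeneticCode("11")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    L <- nchar(s)
    codon_at <- function(p) substr(s, p + 1, p + 3)   # p is 0-based
    starts <- which(vapply(0:(L - 3), function(p)
      codon_at(p) %in% c("ATG", "GTG", "TTG"), logical(1))) - 1L
    best <- list()  # stop position -> smallest start
    for (p in starts) {
      k <- p
      repeat {
        k <- k + 3L
        if (k + 3L > L) { k <- NA_integer_; break }
        if (codon_at(k) %in% c("TAA", "TAG", "TGA")) break
      }
      if (is.na(k)) next
      if ((k - p) / 3 < minAa) next
      key <- as.character(k)
      if (is.null(best[[key]]) || p < best[[key]]) best[[key]] <- p
    }
    for (key in names(best)) {
      p <- best[[key]]; k <- as.integer(key)
      aa <- unname(gc11[vapply(seq(p, k - 3L, 3L), codon_at, character(1))])
      aa[1] <- "M"
      a <- p; b <- k + 3L
      if (strand == "-") { tmp <- a; a <- L - b; b <- L - tmp }
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, strand = strand,
        translation = paste(aa, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      translation = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Quadratic-time ungapped local alignment (match +1 / mismatch -2):
# per-diagonal maximum-sum segment via prefix sums, both strands.
# Returns the best-scoring segment with 0-based half-open coordinates
# (subject coordinates on the forward strand).
oracleTopSegment <- function(q, s) {
  qc <- strsplit(q, "")[[1]]; m <- length(qc)
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    sv <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    sc <- strsplit(sv, "")[[1]]; n <- length(sc)
    for (d in (-(n - 1)):(m - 1)) {
      q0 <- max(0L, d); q1 <- min(m - 1L, n - 1L + d)
      if (q1 < q0) next
      qi <- q0:q1; si <- qi - d
      x <- ifelse(qc[qi + 1L] == sc[si + 1L], 1, -2)
      p <- cumsum(x)
      prefix0 <- c(0, p)
      pm <- cummin(prefix0[-length(prefix0)])
      gain <- p - pm
      k <- which.max(gain)
      if (gain[k] > best$score) {
        i0 <- max(which(prefix0[seq_len(k)] == pm[k]))  # index into prefix0
        len <- k - (i0 - 1L)
        matches <- (gain[k] + 2 * len) / 3
        qs <- qi[i0]; qe <- qi[k] + 1L
        ss <- si[i0]; se <- si[k] + 1L
        if (strand == "-") { tmp <- ss; ss <- n - se; se <- n - tmp }
        best <- list(score = gain[k], q_start = qs, q_end = qe,
                     s_start = ss, s_end = se, identities = matches,
                     strand = strand)
      }
    }
  }
  best
}

# Union-find with path compression; edges is a 2-column matrix of indices.
unionFind <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Connected components of a thresholded similarity matrix, via union-find.
oracleComponents <- function(v, threshold) {
  n <- nrow(v)
  idx <- which(upper.tri(v) & v >= threshold, arr.ind = TRUE)
  unionFind(n, idx)
}

randomDnaStr <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

randomAaStr <- function(n) paste(sample(phamkit:::AA_ALPHABET, n,
                                        replace = TRUE), collapse = "")

# Substitute exactly the given 1-based positions with different symbols.
substituteAt <- function(seq, positions,
                         alphabet = phamkit:::AA_ALPHABET) {
  ch <- strsplit(seq, "")[[1]]
  for (i in positions) ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  paste(ch, collapse = "")
}
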
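# Independent oracles used to validate the implementation paths.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Exhaustive all-positions Hamming scanner over every reference and both
# strands; deliberately independent of the package's seed-and-extend path.
# Returns hits in the same sorted convention as align_tag().
oracle_scanner <- function(ref, max_mm = 2L, classes = SOURCE_CLASSES) {
  keep <- ref$meta$source_class %in% classes
  ids <- ref$meta$id[keep]
  seqs <- lapply(ref$sequences[keep], utf8ToInt)
  function(tag) {
    L <- nchar(tag)
    tf <- utf8ToInt(tag)
    tr <- utf8ToInt(oracle_revcomp(tag))
    out <- list()
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      n <- length(s)
      if (n < L) next
      W <- matrix(s[outer(seq_len(L), 0:(n - L), "+")], nrow = L)
      for (strand in c("+", "-")) {
        t <- if (strand == "+") tf else tr
        mm <- colSums(W != t)
        hit <- which(mm <= max_mm)
        if (length(hit))
          out[[length(out) + 1L]] <- data.frame(
            ref_id = ids[i], position = hit - 1L, strand = strand,
            mismatches = as.integer(mm[hit]), stringsAsFactors = FALSE)
      }
    }
    if (!length(out))
      return(data.frame(ref_id = character(), position = integer(),
                        strand = character(), mismatches = integer()))
    out <- do.call(rbind, out)
    out <- out[order(out$mismatches, out$ref_id, out$position, out$strand,
                     method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

# closed-form expected per-site difference between two sequences that each
# diverged from a common ancestor by i.i.d. substitution at rate p (each
# substitution uniform over the 3 other bases)
oracle_cross_divergence <- function(p) 1 - (1 - p)^2 - p^2 / 3

# textbook Pearson correlation, written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# draw a tag from a reference with exactly k mismatches at random positions
mutated_substring <- function(seq, L, k) {
  n <- nchar(seq)
  start <- sample.int(n - L + 1L, 1L)
  v <- strsplit(substr(seq, start, start + L - 1L), "", fixed = TRUE)[[1L]]
  if (k > 0L) {
    pos <- sample.int(L, k)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}
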
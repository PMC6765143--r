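# Independent oracles used across the suite.  These deliberately use
# different algorithmic routes than the package implementation.

# brute-force smallest period: test every p against every position explicitly
period_oracle <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  for (p in seq_len(n)) {
    if (p == n) return(n)
    if (all(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])) return(p)
  }
}

# naive per-record substring scanner (single-line grep equivalent)
naive_scan <- function(seqs, perms) {
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (p in perms) {
      pos <- c()
      from <- 1L
      repeat {
        hit <- regexpr(p, substr(s, from, nchar(s)), fixed = TRUE)
        if (hit == -1L) break
        pos <- c(pos, from + hit - 2L)      # 0-based
        from <- from + hit                  # allow overlapping matches
      }
      if (length(pos) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, permutation = p, position = pos,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(), permutation = character(),
                      position = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$transcript_id, df$permutation, df$position), , drop = FALSE]
}

# local alignment score by explicit enumeration of inter-column gap lengths
# (O(n^2 m^2) quadratic-gap DP; independent of the Gotoh affine-state route).
# A k-base gap costs go + k * ge; alignments start and end on aligned pairs.
sw_oracle <- function(a, b, match = 2, mismatch = -3, go = 5, ge = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) return(0)
  M <- matrix(-Inf, n, m)
  gapcost <- function(da, db) {
    (if (da > 0) go + da * ge else 0) + (if (db > 0) go + db * ge else 0)
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    prev <- 0
    if (i > 1L && j > 1L) {
      for (ii in seq_len(i - 1L)) for (jj in seq_len(j - 1L)) {
        cand <- M[ii, jj] - gapcost(i - ii - 1L, j - jj - 1L)
        if (cand > prev) prev <- cand
      }
    }
    M[i, j] <- s + prev
    if (M[i, j] > best) best <- M[i, j]
  }
  best
}

# rescore a gapped alignment pair from scratch (gap runs scored per strand)
rescore_alignment <- function(qa, sa, match = 2, mismatch = -3,
                              go = 5, ge = 2) {
  q <- strsplit(qa, "", fixed = TRUE)[[1]]
  s <- strsplit(sa, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(s))
  sc <- 0; k <- 1L
  while (k <= length(q)) {
    if (q[k] != "-" && s[k] != "-") {
      sc <- sc + if (q[k] == s[k]) match else mismatch
      k <- k + 1L
    } else {
      gap_in <- if (q[k] == "-") "q" else "s"
      g <- 0L
      while (k <= length(q) &&
             ((gap_in == "q" && q[k] == "-") ||
              (gap_in == "s" && s[k] == "-"))) {
        g <- g + 1L; k <- k + 1L
      }
      sc <- sc - (go + g * ge)
    }
  }
  as.integer(sc)
}

# seeded random sequences and motifs
rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# a random telomere-like unit from the class for which template windows are
# unambiguous (every (L+1)-window of the circular repeat has full period)
rand_unambiguous_motif <- function(len) {
  repeat {
    u <- rand_seq(len)
    if (teloseeker:::.is_circularly_primitive(u)) return(u)
  }
}

rotate <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

# all strings over an alphabet up to a length
all_strings <- function(max_len, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(max_len), function(L)
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")))
}
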
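# independent brute-force dynamic-programming oracle for global affine
# alignment scores: a gap of length k costs open + k * ext
affine_align_score <- function(a, b, match = 1, mismatch = -2,
                               open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # ends with subject gap
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends with pattern gap
  M[1, 1] <- 0
  if (n >= 1L) for (i in 2:(n + 1L)) X[i, 1] <- -(open + (i - 1L) * ext)
  if (m >= 1L) for (j in 2:(m + 1L)) Y[1, j] <- -(open + (j - 1L) * ext)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext,
                     Y[i - 1L, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, X[i, j - 1L] - open - ext,
                     Y[i, j - 1L] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# read-like mutated copy of a reference: substitutions plus occasional
# short indels, keeping the length within the caller's bounds
mutated_copy <- function(ref, n_sub = 2L, n_indel = 1L) {
  x <- strsplit(ref, "")[[1]]
  L <- length(x)
  for (k in seq_len(n_sub)) {
    p <- sample(L, 1L)
    x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
  }
  for (k in seq_len(n_indel)) {
    if (stats::runif(1) < 0.5 && length(x) > 3L) {
      p <- sample(length(x), 1L)
      x <- x[-p]
    } else {
      p <- sample(length(x), 1L)
      x <- append(x, sample(c("A", "C", "G", "T"), 1L), after = p)
    }
  }
  paste(x, collapse = "")
}
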
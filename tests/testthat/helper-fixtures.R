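## Shared fixtures and independent oracles for the test suite.

## random standard-residue sequence
randomSeq <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                      "H", "I", "L", "K", "M", "F", "P", "T",
                                      "S", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## small labeled feature fixture built from the sequence generator; cached per
## session because feature extraction dominates test time
seqFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generateSequences(generatorSpec(nPerClass = 100L, seed = 42L))
      X <- featureTable(seqRecords(ds))
      cache <<- list(X = X, y = classLabels(ds), ds = ds)
    }
    cache
  }
})

## brute-force global-alignment DP (match +1, mismatch 0, gap -1), tracking
## the number of exact matches along one optimal path; independent of
## Biostrings
nwIdentityOracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0, n + 1, m + 1)  # matches along the best path
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    eq <- as.integer(A[i] == B[j])
    cand <- c(S[i, j] + eq, S[i, j + 1] - 1, S[i + 1, j] - 1)
    mats <- c(M[i, j] + eq, M[i, j + 1], M[i + 1, j])
    k <- which(cand == max(cand))
    ## among co-optimal moves prefer the one with most matches, so the oracle
    ## reports the maximum-identity optimal alignment
    k <- k[which.max(mats[k])]
    S[i + 1, j + 1] <- cand[k]; M[i + 1, j + 1] <- mats[k]
  }
  M[n + 1, m + 1] / min(n, m)
}

## write a small FASTA file and return its path
writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
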
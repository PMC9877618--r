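## Dataset construction: FASTA ingestion, greedy 80%-identity redundancy
## removal, train-only scaling, stratified splitting and k-fold partitioning.

#' Read a protein FASTA file
#'
#' Parses via `Biostrings::readAAStringSet` after a light pre-scan that
#' reports malformed headers, empty records and duplicate ids with their line
#' numbers. Wrapped sequence lines are concatenated; record order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return `Biostrings::AAStringSet` named by header ids.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop(sprintf("%s: empty file", path), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("%s:%d: expected a '>' header line", path, nonblank[1L]),
         call. = FALSE)
  headers <- which(startsWith(trimws(lines), ">"))
  ids <- sub("^>\\s*(\\S*).*$", "\\1", trimws(lines[headers]))
  empty <- !nzchar(ids)
  if (any(empty))
    stop(sprintf("%s:%d: header has no id", path, headers[which(empty)[1L]]),
         call. = FALSE)
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stop(sprintf("%s: duplicate record id '%s' (line %d)",
                 path, d, headers[which(ids == d)[2L]]), call. = FALSE)
  }
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    from <- bounds[k] + 1L
    to <- bounds[k + 1L] - 1L
    if (from > to || !any(nzchar(trimws(lines[from:to]))))
      stop(sprintf("%s:%d: record '%s' has an empty sequence",
                   path, headers[k], ids[k]), call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("^\\s*(\\S*).*$", "\\1", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs `AAStringSet` or named character vector.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Pairwise sequence identity
#'
#' Exact matches in a global (Needleman-Wunsch) alignment with unit match
#' score, zero mismatch score and a simple linear gap penalty, divided by the
#' length of the shorter sequence.
#'
#' @param a,b protein sequences (character scalars).
#' @return identity in [0, 1].
#' @export
pairIdentity <- function(a, b) {
  .pairIdentities(a, b)
}

## vectorised over `b`
.identitySubstMat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c(AA_ORDER, "X", "B", "Z", "J", "U", "O", "*")
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      mat <<- m
    }
    mat
  }
})

.pairIdentities <- function(a, bs) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(a, length(bs))),
    subject = Biostrings::AAStringSet(bs),
    type = "global", substitutionMatrix = .identitySubstMat(),
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / pmin(nchar(a), nchar(bs))
}

#' Greedy redundancy removal at an identity threshold
#'
#' CD-HIT-style greedy clustering: sequences are visited longest-first; each
#' joins the first existing representative with identity at or above the
#' threshold, otherwise it founds a new cluster. All surviving representative
#' pairs therefore have identity below the threshold.
#'
#' @param seqs `AAStringSet` or named character vector.
#' @param threshold identity threshold in (0, 1] (default 0.80).
#' @return list with `representatives` (character vector of ids),
#'   `clusterMap` (named character: member id -> representative id) and
#'   `sequences` (the representative sequences, input order preserved).
#' @export
dedupByIdentity <- function(seqs, threshold = 0.80) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs))
  repIds <- character(0)
  clusterMap <- character(0)
  for (i in ord) {
    id <- names(seqs)[i]
    assigned <- FALSE
    if (length(repIds)) {
      idents <- .pairIdentities(seqs[[i]], unname(seqs[repIds]))
      j <- which(idents >= threshold)
      if (length(j)) {
        clusterMap[id] <- repIds[j[1L]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      repIds <- c(repIds, id)
      clusterMap[id] <- id
    }
  }
  keep <- names(seqs)[names(seqs) %in% repIds]  # restore input order
  list(representatives = keep,
       clusterMap = clusterMap[names(seqs)],
       sequences = seqs[keep])
}

#' Feature scaler
#'
#' Per-feature scaling state fitted on training rows only: `"zscore"`
#' (zero mean, unit variance) or `"minmax"` (training range mapped to [0, 1]).
#' Constant features are flagged and mapped to 0.
#'
#' @slot kind `"zscore"` or `"minmax"`.
#' @slot center,scale per-feature offset and divisor.
#' @slot constant logical flag per feature.
#' @slot fittedOn fingerprint (dimensions + checksum) of the fitting matrix.
#' @export
setClass("Scaler",
         representation(kind = "character", center = "numeric",
                        scale = "numeric", constant = "logical",
                        fittedOn = "character"),
         validity = function(object) {
           if (!object@kind %in% c("zscore", "minmax"))
             return("kind must be 'zscore' or 'minmax'")
           if (length(object@center) != length(object@scale))
             return("center/scale length mismatch")
           if (any(object@scale[!object@constant] <= 0))
             return("scale must be positive for non-constant features")
           TRUE
         })

#' Fit a feature scaler on training data
#'
#' @param X numeric matrix (training rows only).
#' @param kind `"zscore"` (default) or `"minmax"`.
#' @return a [Scaler-class].
#' @export
fitScaler <- function(X, kind = c("zscore", "minmax")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (kind == "zscore") {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
  } else {
    ctr <- apply(X, 2, min)
    scl <- apply(X, 2, max) - ctr
  }
  const <- !is.finite(scl) | scl <= .Machine$double.eps^0.5
  scl[const] <- 1
  fp <- sprintf("%dx%d:%.8g", nrow(X), ncol(X), sum(X))
  new("Scaler", kind = kind, center = ctr, scale = scl,
      constant = const, fittedOn = fp)
}

#' Apply a fitted scaler
#'
#' Transforms with the training parameters (test rows may fall outside [0, 1]
#' for min-max); constant features map to 0.
#'
#' @param X numeric matrix with the same columns as the fitting matrix.
#' @param scaler a fitted [Scaler-class].
#' @export
transformFeatures <- function(X, scaler) {
  if (!methods::is(scaler, "Scaler")) stop("not a fitted Scaler", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) != length(scaler@center))
    stop("column count does not match the fitted scaler", call. = FALSE)
  Z <- sweep(sweep(X, 2, scaler@center, "-"), 2, scaler@scale, "/")
  Z[, scaler@constant] <- 0
  Z
}

#' Invert a scaler transform
#'
#' Round-trips non-constant features exactly (to numerical precision);
#' constant features are restored to their fitted center value.
#'
#' @inheritParams transformFeatures
#' @export
inverseTransformFeatures <- function(X, scaler) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, scaler@scale, "*"), 2, scaler@center, "+")
  Z[, scaler@constant] <- rep(scaler@center[scaler@constant],
                              each = nrow(Z))
  Z
}

#' @describeIn Scaler-class compact display.
#' @param object a `Scaler`.
#' @export
setMethod("show", "Scaler", function(object) {
  cat(sprintf("Scaler(%s): %d features (%d constant), fitted on %s\n",
              object@kind, length(object@center), sum(object@constant),
              object@fittedOn))
})

## per-class test-count rule shared by split and k-fold: round(n * fraction)
.classIndices <- function(labels) split(seq_along(labels), labels)

#' Stratified train/test split with nested validation split
#'
#' Per class, `round(n_class * (1 - trainFraction))` samples go to the test
#' set (remainder to train), so class proportions are preserved within one
#' sample per class. The train set is further split into a training core and
#' an inner validation set with the same rule. Seeded and reproducible.
#'
#' @param labels binary label vector (0/1).
#' @param trainFraction fraction of each class assigned to train (default 0.8).
#' @param validationFraction fraction of the train set held out for per-epoch
#'   validation (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `test`, `trainCore`,
#'   `validation`.
#' @export
stratifiedSplit <- function(labels, trainFraction = 0.8,
                            validationFraction = 0.2, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1 ||
      validationFraction <= 0 || validationFraction >= 1)
    stop("fractions must lie in (0, 1)", call. = FALSE)
  cls <- .classIndices(labels)
  if (length(cls) < 2L || any(lengths(cls) < 2L))
    stop("need both classes with at least 2 members", call. = FALSE)
  set.seed(seed)
  test <- integer(0)
  for (idx in cls) {
    nTest <- round(length(idx) * (1 - trainFraction))
    test <- c(test, sample(idx, nTest))
  }
  train <- setdiff(seq_along(labels), test)
  val <- integer(0)
  for (idx in .classIndices(labels[train])) {
    nVal <- round(length(idx) * validationFraction)
    val <- c(val, train[idx][sample.int(length(idx), nVal)])
  }
  list(train = sort(train), test = sort(test),
       trainCore = sort(setdiff(train, val)), validation = sort(val))
}

#' Stratified k-fold partitioning
#'
#' Shuffles each class under the seed and deals members round-robin across
#' folds, so per-fold class counts differ from proportionality by at most one.
#'
#' @param labels binary label vector.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed.
#' @return list of `nFolds` lists, each with `train` and `test` index vectors.
#' @export
stratifiedKfold <- function(labels, nFolds = 5L, seed = 1L) {
  if (nFolds < 2L) stop("'nFolds' must be >= 2", call. = FALSE)
  cls <- .classIndices(labels)
  if (any(lengths(cls) < nFolds))
    stop("each class needs at least 'nFolds' members", call. = FALSE)
  set.seed(seed)
  foldOf <- integer(length(labels))
  for (idx in cls) {
    sh <- sample(idx)
    foldOf[sh] <- rep_len(seq_len(nFolds), length(sh))
  }
  lapply(seq_len(nFolds), function(k)
    list(train = which(foldOf != k), test = which(foldOf == k)))
}
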
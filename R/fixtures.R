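## Synthetic two-class protein sequence generator. The signal is synthetic by
## design: class 1 is drawn from a shifted residue composition and enriched
## for planted motifs, so the 46-feature encoder separates the classes with a
## controllable margin. A direct feature-space generator with a known Bayes
## rate is also provided.

#' Labeled protein sequence dataset
#'
#' @slot sequences `Biostrings::AAStringSet`, uniquely named.
#' @slot labels integer 0/1 per sequence (1 = stress-responsive positive).
#' @slot stressClass one of cold, drought, heat, salt (or "synthetic").
#' @export
setClass("StressDataset",
         representation(sequences = "AAStringSet", labels = "integer",
                        stressClass = "character"),
         validity = function(object) {
           if (length(object@sequences) != length(object@labels))
             return("sequences and labels differ in length")
           if (!all(object@labels %in% c(0L, 1L)))
             return("labels must be 0/1")
           if (anyDuplicated(names(object@sequences)))
             return("sequence ids must be unique")
           TRUE
         })

#' @describeIn StressDataset-class the sequences.
#' @param x a `StressDataset`.
#' @export
seqRecords <- function(x) x@sequences

#' @describeIn StressDataset-class the 0/1 labels.
#' @export
classLabels <- function(x) x@labels

#' @describeIn StressDataset-class the stress-class tag.
#' @export
stressClass <- function(x) x@stressClass

#' @describeIn StressDataset-class compact display.
#' @param object a `StressDataset`.
#' @export
setMethod("show", "StressDataset", function(object) {
  cat(sprintf("StressDataset (%s): %d sequences (%d positive, %d negative)\n",
              object@stressClass, length(object@sequences),
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

#' Generator specification
#'
#' Defines the synthetic study conditions. Defaults: 200 sequences per class,
#' lengths uniform on 120-220, a uniform 1/20 background composition (chosen
#' for analytic transparency; `background = "natural"` gives approximate
#' natural abundances), an absolute composition shift of +0.10 on K and
#' +0.05 on E (balanced by -0.05 on A, G, P) in class 1, and a SUMO-I motif
#' ("LKHE") planted at a mean rate of 2 per class-1 sequence.
#'
#' @param nPerClass sequences per class.
#' @param lengthRange integer range of sequence lengths.
#' @param background `"uniform"`, `"natural"`, or a 20-vector of frequencies
#'   summing to 1 (in the standard residue order).
#' @param compositionShift named numeric of absolute frequency shifts applied
#'   to class 1; must keep all frequencies nonnegative and sum to 0.
#' @param motifs list of `list(pattern=, rate=, class=)` planted motifs.
#' @param featureEffect effect size d (in SDs) for the direct feature-space
#'   generator.
#' @param shiftedColumns feature columns shifted by `featureEffect`.
#' @param seed integer seed.
#' @export
generatorSpec <- function(nPerClass = 200L, lengthRange = c(120L, 220L),
                          background = "uniform",
                          compositionShift = c(K = 0.10, E = 0.05,
                                               A = -0.05, G = -0.05, P = -0.05),
                          motifs = list(list(pattern = "LKHE", rate = 2,
                                             class = 1L)),
                          featureEffect = 3,
                          shiftedColumns = c("comp_K", "comp_E", "n_positive",
                                             "gravy", "molecular_weight"),
                          seed = 1L) {
  if (is.character(background)) {
    background <- switch(match.arg(background, c("uniform", "natural")),
      uniform = stats::setNames(rep(1 / 20, 20), AA_ORDER),
      natural = stats::setNames(c(0.083, 0.055, 0.041, 0.054, 0.014, 0.039,
                                  0.067, 0.071, 0.023, 0.059, 0.096, 0.058,
                                  0.024, 0.039, 0.047, 0.053, 0.066, 0.011,
                                  0.029, 0.069) /
                                  sum(c(0.083, 0.055, 0.041, 0.054, 0.014,
                                        0.039, 0.067, 0.071, 0.023, 0.059,
                                        0.096, 0.058, 0.024, 0.039, 0.047,
                                        0.053, 0.066, 0.011, 0.029, 0.069)),
                                AA_ORDER))
  }
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-8 ||
      any(background < 0))
    stop("'background' must be 20 nonnegative frequencies summing to 1",
         call. = FALSE)
  names(background) <- AA_ORDER
  shifted <- background
  shifted[names(compositionShift)] <-
    shifted[names(compositionShift)] + compositionShift
  if (abs(sum(shifted) - 1) > 1e-8 || any(shifted < -1e-12))
    stop("compositionShift must keep frequencies nonnegative and sum to 1",
         call. = FALSE)
  if (any(vapply(motifs, function(m) m$rate < 0, logical(1))))
    stop("motif rates must be >= 0", call. = FALSE)
  if (featureEffect < 0) stop("featureEffect must be >= 0", call. = FALSE)
  list(nPerClass = as.integer(nPerClass),
       lengthRange = as.integer(lengthRange),
       background = background, class1Freq = pmax(shifted, 0),
       compositionShift = compositionShift, motifs = motifs,
       featureEffect = featureEffect, shiftedColumns = shiftedColumns,
       seed = as.integer(seed))
}

#' Generate a two-class synthetic sequence dataset
#'
#' Sequences are i.i.d. draws from the class composition; planted motifs
#' overwrite a random non-overlapping position `Poisson(rate)` times per
#' sequence of their class. Byte-identical output under a fixed seed.
#'
#' @param spec from [generatorSpec()].
#' @return a [StressDataset-class].
#' @export
generateSequences <- function(spec) {
  set.seed(spec$seed)
  drawClass <- function(freq, n, cls) {
    lens <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], n, replace = TRUE)
    vapply(lens, function(L) {
      ch <- sample(AA_ORDER, L, replace = TRUE, prob = freq)
      for (m in spec$motifs) {
        if (m$class != cls) next
        k <- stats::rpois(1L, m$rate)
        if (k > 0 && L >= nchar(m$pattern)) {
          starts <- sample.int(L - nchar(m$pattern) + 1L, min(k, 3L))
          for (s in starts)
            ch[s:(s + nchar(m$pattern) - 1L)] <- .seqChars(m$pattern)
        }
      }
      paste(ch, collapse = "")
    }, character(1))
  }
  neg <- drawClass(spec$background, spec$nPerClass, 0L)
  pos <- drawClass(spec$class1Freq, spec$nPerClass, 1L)
  seqs <- Biostrings::AAStringSet(c(neg, pos))
  names(seqs) <- c(sprintf("neg_%04d", seq_along(neg)),
                   sprintf("pos_%04d", seq_along(pos)))
  new("StressDataset", sequences = seqs,
      labels = c(rep(0L, length(neg)), rep(1L, length(pos))),
      stressClass = "synthetic")
}

#' Generate a feature table with a known Bayes rate
#'
#' Draws 46 standard-normal feature columns and shifts `spec$shiftedColumns`
#' by `featureEffect` standard deviations in class 1. With k shifted columns
#' and effect d, the Bayes-optimal accuracy is \eqn{\Phi(d\sqrt{k}/2)},
#' returned alongside the data.
#'
#' @param spec from [generatorSpec()].
#' @return list with `X` (n x 46 matrix), `y` (0/1), `bayesRate`.
#' @export
generateFeatureTable <- function(spec) {
  set.seed(spec$seed)
  n <- 2L * spec$nPerClass
  X <- matrix(stats::rnorm(n * 46L), n, 46L,
              dimnames = list(NULL, .FEATURE_NAMES))
  y <- rep(c(0L, 1L), each = spec$nPerClass)
  cols <- intersect(spec$shiftedColumns, colnames(X))
  X[y == 1L, cols] <- X[y == 1L, cols] + spec$featureEffect
  bayes <- stats::pnorm(spec$featureEffect * sqrt(length(cols)) / 2)
  list(X = X, y = y, bayesRate = bayes)
}

#' Write dataset artifacts
#'
#' Writes the FASTA, a labels CSV and a generator manifest JSON (spec +
#' seed) sufficient to reproduce the dataset exactly.
#'
#' @param dataset a [StressDataset-class].
#' @param dir output directory (created if needed).
#' @param spec the [generatorSpec()] that produced it (stored in the
#'   manifest), or NULL.
#' @return invisibly, the paths written.
#' @export
writeDatasetArtifacts <- function(dataset, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "sequences.fasta")
  writeFasta(seqRecords(dataset), fa)
  lab <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(id = names(seqRecords(dataset)),
                              label = classLabels(dataset)),
                   lab, row.names = FALSE)
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(stressClass = stressClass(dataset),
                            n = length(classLabels(dataset)),
                            generator = spec),
                       man, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fasta = fa, labels = lab, manifest = man))
}
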
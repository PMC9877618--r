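## The 46-feature protein sequence encoder: residue composition (20),
## coiled-coil score, PTM motif counts (12), length/charge/mass/pI,
## elemental counts, instability index, aliphatic index and GRAVY.

.STANDARD_AA <- AA_ORDER

.seqChars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Sanitize a raw protein sequence
#'
#' Uppercases and applies a policy for the non-standard letters
#' (B, J, O, U, X, Z, gaps and whitespace): `"strict"` errors, `"drop"`
#' removes them, `"impute"` maps B to N, Z to Q, U to C and drops X and the
#' rest. Library calls default to strict; the pipeline commands use impute.
#'
#' @param raw non-empty character scalar.
#' @param policy one of `"strict"`, `"drop"`, `"impute"`.
#' @return sanitized uppercase sequence over the 20 standard letters.
#' @export
sanitizeSequence <- function(raw, policy = c("strict", "drop", "impute")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("'raw' must be a non-empty character scalar", call. = FALSE)
  s <- toupper(gsub("[[:space:]*]", "", raw))
  ch <- .seqChars(s)
  std <- ch %in% .STANDARD_AA
  if (policy == "strict") {
    if (!all(std))
      stop(sprintf("non-standard residue '%s' at position %d (policy = strict)",
                   ch[which(!std)[1L]], which(!std)[1L]), call. = FALSE)
  } else if (policy == "impute") {
    map <- c(B = "N", Z = "Q", U = "C")
    ch <- ifelse(ch %in% names(map), map[ch], ch)
    ch <- ch[ch %in% .STANDARD_AA]
  } else {
    ch <- ch[std]
  }
  out <- paste(ch, collapse = "")
  if (!nzchar(out)) stop("sequence empty after sanitization", call. = FALSE)
  out
}

#' Residue composition
#'
#' Fraction of each of the 20 standard residues, in schema order; the
#' fractions sum to 1.
#'
#' @param seq sanitized sequence (standard letters only).
#' @return named numeric vector of length 20.
#' @export
composition <- function(seq) {
  ch <- .seqChars(seq)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  tab <- table(factor(ch, levels = .STANDARD_AA))
  as.numeric(tab) / length(ch) -> fr
  names(fr) <- .STANDARD_AA
  fr
}

#' Charged-residue counts
#'
#' Negatively charged = D + E; positively charged = K + R (histidine is
#' excluded at physiological pH; the sets are configurable via the schema).
#'
#' @inheritParams composition
#' @param schema a [FeatureSchema-class].
#' @return c(n_negative, n_positive).
#' @export
chargeCounts <- function(seq, schema = defaultFeatureSchema()) {
  ch <- .seqChars(seq)
  c(n_negative = sum(ch %in% schema@negativeResidues),
    n_positive = sum(ch %in% schema@positiveResidues))
}

#' Molecular weight (average masses)
#'
#' Sum of Expasy average residue masses plus one water (18.0153 Da), so
#' concatenating two chains loses exactly one water.
#'
#' @inheritParams composition
#' @return mass in Da.
#' @export
molecularWeight <- function(seq) {
  ch <- .seqChars(seq)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  sum(AA_RESIDUE_MASS[ch]) + WATER_MASS
}

#' Elemental composition
#'
#' C/H/N/O/S atom counts: sum of the free-amino-acid formulas minus one water
#' (H2, O1) per peptide bond.
#'
#' @inheritParams composition
#' @return named integer vector c(C, H, N, O, S).
#' @export
atomCounts <- function(seq) {
  ch <- .seqChars(seq)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  tot <- colSums(AA_ATOMS[ch, , drop = FALSE])
  tot["H"] <- tot["H"] - 2L * (length(ch) - 1L)
  tot["O"] <- tot["O"] - (length(ch) - 1L)
  as.integer(tot) -> v
  names(v) <- colnames(AA_ATOMS)
  v
}

## Net charge of the protein at a given pH under the schema's pKa set:
## positive groups (N-terminus, H, K, R) minus negative (C-terminus, D, E, C, Y).
netCharge <- function(seq, pH, pKa = PKA_EMBOSS) {
  ch <- .seqChars(seq)
  posFrac <- function(pk) 1 / (1 + 10^(pH - pk))
  negFrac <- function(pk) 1 / (1 + 10^(pk - pH))
  pos <- posFrac(pKa[["Nterm"]]) +
    sum(vapply(c("H", "K", "R"),
               function(a) sum(ch == a) * posFrac(pKa[[a]]), numeric(1)))
  neg <- negFrac(pKa[["Cterm"]]) +
    sum(vapply(c("D", "E", "C", "Y"),
               function(a) sum(ch == a) * negFrac(pKa[[a]]), numeric(1)))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' The pH in (0, 14) at which the modeled net charge is zero, found by
#' bisection of the monotone net-charge curve to |charge| < 1e-4, under the
#' schema's pKa set (EMBOSS by default).
#'
#' @inheritParams chargeCounts
#' @return pI in pH units.
#' @export
theoreticalPi <- function(seq, schema = defaultFeatureSchema()) {
  pKa <- schema@pKaSet
  lo <- 0; hi <- 14
  if (netCharge(seq, lo, pKa) < 0 || netCharge(seq, hi, pKa) > 0)
    stop("net charge does not bracket zero on (0, 14)", call. = FALSE)
  repeat {
    mid <- (lo + hi) / 2
    q <- netCharge(seq, mid, pKa)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic:
#' \eqn{II = (10/L) \sum_{i=1}^{L-1} \mathrm{DIWV}(s_i, s_{i+1})}.
#'
#' @inheritParams composition
#' @export
instabilityIndex <- function(seq) {
  ch <- .seqChars(seq)
  if (length(ch) < 2L) stop("instability index needs length >= 2", call. = FALSE)
  i <- seq_len(length(ch) - 1L)
  (10 / length(ch)) * sum(AA_DIWV[cbind(ch[i], ch[i + 1L])])
}

#' Aliphatic index
#'
#' \eqn{AI = X_{Ala} + 2.9 X_{Val} + 3.9 (X_{Ile} + X_{Leu})} with X in mole
#' percent.
#'
#' @inheritParams composition
#' @export
aliphaticIndex <- function(seq) {
  fr <- composition(seq) * 100
  fr[["A"]] + 2.9 * fr[["V"]] + 3.9 * (fr[["I"]] + fr[["L"]])
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; bounded by the scale
#' range [-4.5, 4.5].
#'
#' @inheritParams composition
#' @export
gravy <- function(seq) {
  ch <- .seqChars(seq)
  if (!length(ch)) stop("empty sequence", call. = FALSE)
  mean(AA_KYTE_DOOLITTLE[ch])
}

## overlapping regex match count
.countOverlapping <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

## count centers (C or Y) whose +/- window contains a residue from `set`
.countContext <- function(seq, center, set, window) {
  ch <- .seqChars(seq)
  idx <- which(ch == center)
  if (!length(idx)) return(0L)
  n <- length(ch)
  sum(vapply(idx, function(i) {
    ctx <- ch[setdiff(max(1L, i - window):min(n, i + window), i)]
    any(ctx %in% set)
  }, logical(1)))
}

#' Post-translational-modification motif counts
#'
#' Twelve deterministic counts: S-nitrosylation A/B/C and total (cysteines
#' with acidic, basic or hydrophobic context within two flanking residues),
#' nitrotyrosine A/B/C and total (the same contexts around tyrosine), and
#' SUMOylation I/II/III and total (\eqn{\psi}KxE, \eqn{\psi}KxD and the
#' inverted [ED]xK\eqn{\psi} site, counted with overlaps). Each total is the
#' sum of its three subcounts. The patterns are schema-configurable stand-ins,
#' not a replication of any third-party predictor.
#'
#' @inheritParams chargeCounts
#' @return named numeric vector of length 12.
#' @export
ptmMotifCounts <- function(seq, schema = defaultFeatureSchema()) {
  m <- schema@motifs
  w <- m$context_window
  nitroA <- .countContext(seq, m$nitros_center, m$context_acidic, w)
  nitroB <- .countContext(seq, m$nitros_center, m$context_basic, w)
  nitroC <- .countContext(seq, m$nitros_center, m$context_hydrophobic, w)
  ynoA <- .countContext(seq, m$nitrotyr_center, m$context_acidic, w)
  ynoB <- .countContext(seq, m$nitrotyr_center, m$context_basic, w)
  ynoC <- .countContext(seq, m$nitrotyr_center, m$context_hydrophobic, w)
  s1 <- .countOverlapping(seq, m$sumo_I)
  s2 <- .countOverlapping(seq, m$sumo_II)
  s3 <- .countOverlapping(seq, m$sumo_III)
  c(nitrosylation_A = nitroA, nitrosylation_B = nitroB, nitrosylation_C = nitroC,
    nitrosylation_total = nitroA + nitroB + nitroC,
    nitrotyrosine_A = ynoA, nitrotyrosine_B = ynoB, nitrotyrosine_C = ynoC,
    nitrotyrosine_total = ynoA + ynoB + ynoC,
    sumoylation_I = s1, sumoylation_II = s2, sumoylation_III = s3,
    sumoylation_total = s1 + s2 + s3)
}

#' Coiled-coil score
#'
#' Heptad-periodicity counter: every window of `ccWindow` residues (default
#' 28) is tested in all seven register offsets; a window counts if, in its
#' best register, at least `ccThreshold` (default 0.75) of the heptad a/d
#' positions are hydrophobic. Sequences shorter than the window score 0. This
#' is a windowed propensity counter, not an external structure predictor.
#'
#' @inheritParams chargeCounts
#' @return number of qualifying windows.
#' @export
coiledCoilScore <- function(seq, schema = defaultFeatureSchema()) {
  ch <- .seqChars(seq)
  w <- schema@ccWindow
  n <- length(ch)
  if (n < w) return(0)
  hyd <- ch %in% schema@hydrophobicSet
  score <- 0L
  for (s in seq_len(n - w + 1L)) {
    win <- hyd[s:(s + w - 1L)]
    best <- 0
    for (r in 0:6) {
      ad <- c(seq(r + 1L, w, by = 7L), seq(r + 4L, w, by = 7L))
      ad <- ad[ad <= w]
      best <- max(best, mean(win[ad]))
    }
    if (best >= schema@ccThreshold) score <- score + 1L
  }
  score
}

#' Extract the 46-feature vector of one sequence
#'
#' Computes all Table-of-features values in schema order; deterministic given
#' the schema.
#'
#' @param seq sanitized protein sequence (see [sanitizeSequence()]).
#' @param schema a [FeatureSchema-class].
#' @return named numeric vector of length 46.
#' @export
extractFeatures <- function(seq, schema = defaultFeatureSchema()) {
  ch <- .seqChars(seq)
  if (!all(ch %in% .STANDARD_AA))
    stop("sequence contains non-standard residues; sanitize first", call. = FALSE)
  cc <- chargeCounts(seq, schema)
  at <- atomCounts(seq)
  v <- c(composition(seq),
         coiled_coil = coiledCoilScore(seq, schema),
         ptmMotifCounts(seq, schema),
         length = length(ch),
         cc,
         molecular_weight = molecularWeight(seq),
         theoretical_pI = theoreticalPi(seq, schema),
         n_C = at[["C"]], n_H = at[["H"]], n_N = at[["N"]],
         n_O = at[["O"]], n_S = at[["S"]],
         instability_index = if (length(ch) >= 2L) instabilityIndex(seq) else 0,
         aliphatic_index = aliphaticIndex(seq),
         gravy = gravy(seq))
  names(v)[1:20] <- paste0("comp_", .STANDARD_AA)
  stopifnot(identical(names(v), schema@featureNames))
  v
}

#' Feature table for a set of sequences
#'
#' Applies [extractFeatures()] to every sequence of an `AAStringSet` (or named
#' character vector) and returns the n x 46 matrix with sequence ids as row
#' names.
#'
#' @param seqs `Biostrings::AAStringSet` or named character vector of
#'   sanitized sequences.
#' @param schema a [FeatureSchema-class].
#' @export
featureTable <- function(seqs, schema = defaultFeatureSchema()) {
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  X <- t(vapply(seqs, extractFeatures, numeric(46L), schema = schema))
  colnames(X) <- schema@featureNames
  X
}
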
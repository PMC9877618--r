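## FeatureSchema: the frozen definition of the 46-feature encoding — feature
## order, motif patterns, pKa set and constant-table versions — hashed so every
## feature table and trained model can be checked against the encoder that
## produced it.

.FEATURE_NAMES <- c(
  paste0("comp_", AA_ORDER),
  "coiled_coil",
  "nitrosylation_A", "nitrosylation_B", "nitrosylation_C", "nitrosylation_total",
  "nitrotyrosine_A", "nitrotyrosine_B", "nitrotyrosine_C", "nitrotyrosine_total",
  "sumoylation_I", "sumoylation_II", "sumoylation_III", "sumoylation_total",
  "length", "n_negative", "n_positive", "molecular_weight", "theoretical_pI",
  "n_C", "n_H", "n_N", "n_O", "n_S",
  "instability_index", "aliphatic_index", "gravy"
)

#' Feature schema for the 46-feature protein encoding
#'
#' Records everything the encoder depends on: the ordered feature names, the
#' post-translational-modification motif patterns in force, the pKa set, the
#' residue sets treated as charged/hydrophobic, the coiled-coil window
#' parameters and the constant-table version. [schemaHash()] digests the
#' schema so downstream artifacts can verify they were built with the same
#' encoding.
#'
#' @slot featureNames ordered names of the 46 features.
#' @slot motifs named list of motif regular expressions (SUMOylation I/II/III)
#'   and context-window definitions (nitrosylation, nitrotyrosine).
#' @slot pKaSet named numeric pKa values (N/C termini and ionisable side chains).
#' @slot pKaSetId identifier of the published pKa scale.
#' @slot positiveResidues,negativeResidues residues counted as charged.
#' @slot hydrophobicSet residues treated as hydrophobic in the coiled-coil
#'   scan and in the \eqn{\psi} position of SUMO motifs.
#' @slot ccWindow,ccThreshold coiled-coil scan window (residues) and minimum
#'   fraction of hydrophobic a/d heptad positions for a window to count.
#' @slot tablesVersion identifier of the mass/hydropathy/instability tables.
#' @export
setClass("FeatureSchema",
         representation(featureNames = "character", motifs = "list",
                        pKaSet = "numeric", pKaSetId = "character",
                        positiveResidues = "character",
                        negativeResidues = "character",
                        hydrophobicSet = "character",
                        ccWindow = "integer", ccThreshold = "numeric",
                        tablesVersion = "character"),
         validity = function(object) {
           if (length(object@featureNames) != 46L)
             return("featureNames must have exactly 46 entries")
           if (anyDuplicated(object@featureNames))
             return("featureNames must be unique")
           if (object@ccWindow < 7L) return("ccWindow must be >= 7")
           if (object@ccThreshold <= 0 || object@ccThreshold > 1)
             return("ccThreshold must be in (0, 1]")
           TRUE
         })

#' Default feature schema
#'
#' The motif definitions are documented, deterministic stand-ins (the field
#' has no single canonical pattern set for these): SUMO I = \eqn{\psi}KxE,
#' SUMO II = \eqn{\psi}KxD, SUMO III = the inverted site [ED]xK\eqn{\psi};
#' nitrosylation A/B/C = a cysteine with acidic, basic, or hydrophobic context
#' within two flanking residues; nitrotyrosine A/B/C analogously around
#' tyrosine. Substitute authoritative patterns by building a modified schema.
#'
#' @return a [FeatureSchema-class] object.
#' @export
defaultFeatureSchema <- function() {
  psi <- "[VILMFAW]"
  new("FeatureSchema",
      featureNames = .FEATURE_NAMES,
      motifs = list(
        sumo_I   = paste0(psi, "K.E"),
        sumo_II  = paste0(psi, "K.D"),
        sumo_III = paste0("[ED].K", psi),
        nitros_center = "C", nitrotyr_center = "Y",
        context_window = 2L,
        context_acidic = c("D", "E"),
        context_basic = c("K", "R", "H"),
        context_hydrophobic = c("V", "I", "L", "M", "F", "A", "W")
      ),
      pKaSet = PKA_EMBOSS, pKaSetId = "EMBOSS",
      positiveResidues = c("K", "R"), negativeResidues = c("D", "E"),
      hydrophobicSet = c("V", "I", "L", "M", "F", "A", "W"),
      ccWindow = 28L, ccThreshold = 0.75,
      tablesVersion = "expasy-average-mass/kyte-doolittle/guruprasad-diwv")
}

#' @describeIn FeatureSchema-class ordered feature names.
#' @param schema a `FeatureSchema`.
#' @export
featureNames <- function(schema) schema@featureNames

#' @describeIn FeatureSchema-class md5 digest of the canonical JSON rendering
#'   of the schema, used to fingerprint feature tables and trained models.
#' @export
schemaHash <- function(schema) {
  canon <- list(featureNames = schema@featureNames,
                motifs = schema@motifs[order(names(schema@motifs))],
                pKaSet = as.list(schema@pKaSet), pKaSetId = schema@pKaSetId,
                positiveResidues = schema@positiveResidues,
                negativeResidues = schema@negativeResidues,
                hydrophobicSet = schema@hydrophobicSet,
                ccWindow = schema@ccWindow, ccThreshold = schema@ccThreshold,
                tablesVersion = schema@tablesVersion)
  txt <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' @describeIn FeatureSchema-class compact display.
#' @param object a `FeatureSchema`.
#' @export
setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf("FeatureSchema: %d features, pKa set %s\n  tables: %s\n  hash: %s\n",
              length(object@featureNames), object@pKaSetId,
              object@tablesVersion, schemaHash(object)))
})
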
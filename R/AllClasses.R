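#' @import methods
#' @importFrom S4Vectors DataFrame
#' @import SummarizedExperiment
NULL

ANNOTATION_COLUMNS <- c("sample_id", "patient_id", "study_id",
                        "cancer_type", "sample_class")

#' ExpressionCompendium: normalized multi-study expression container
#'
#' A \linkS4class{SummarizedExperiment} holding a gene x sample matrix of
#' unitless SD-from-median values (assay \code{"sdu"}) together with the
#' stratified sample annotations (\code{colData} columns \code{sample_id},
#' \code{patient_id}, \code{study_id}, \code{cancer_type},
#' \code{sample_class}, optional \code{biopsy_site}). Genes absent from a
#' study are \code{NA}.
#'
#' Subsetting keeps the object structurally valid but, like any centered
#' matrix, a sample subset no longer satisfies the per-stratum median-0/SD-1
#' property; use [validateStrataNormalization()] to check it on a full
#' compendium.
#'
#' @export
setClass("ExpressionCompendium", contains = "SummarizedExperiment")

setValidity("ExpressionCompendium", function(object) {
  msg <- NULL
  if (!"sdu" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'sdu' missing")
  missingCols <- setdiff(ANNOTATION_COLUMNS,
                         colnames(SummarizedExperiment::colData(object)))
  if (length(missingCols))
    msg <- c(msg, paste("colData lacks columns:",
                        paste(missingCols, collapse = ", ")))
  if (is.null(rownames(object)))
    msg <- c(msg, "gene (row) names required")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionCompendium
#'
#' @param sdu Gene x sample numeric matrix in SD-from-median units (NA where
#'   a gene is absent from a sample's study).
#' @param annotations data.frame with one row per sample and columns
#'   \code{sample_id}, \code{patient_id}, \code{study_id},
#'   \code{cancer_type}, \code{sample_class} (optionally
#'   \code{biopsy_site}), matched to \code{colnames(sdu)} by
#'   \code{sample_id}.
#' @return An \linkS4class{ExpressionCompendium}.
#' @export
ExpressionCompendium <- function(sdu, annotations) {
  annotations <- as.data.frame(annotations)
  if (!all(ANNOTATION_COLUMNS %in% colnames(annotations)))
    stop("annotations must contain columns: ",
         paste(ANNOTATION_COLUMNS, collapse = ", "))
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample_id in annotations")
  idx <- match(colnames(sdu), annotations$sample_id)
  if (anyNA(idx))
    stop("samples without annotation: ",
         paste(utils::head(colnames(sdu)[is.na(idx)]), collapse = ", "))
  cd <- S4Vectors::DataFrame(annotations[idx, , drop = FALSE])
  rownames(cd) <- colnames(sdu)
  new("ExpressionCompendium",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(sdu = sdu), colData = cd))
}

#' @describeIn ExpressionCompendium-class Gene x sample SD-unit matrix.
#' @param x An ExpressionCompendium.
#' @export
sduMatrix <- function(x) SummarizedExperiment::assay(x, "sdu")

#' @describeIn ExpressionCompendium-class Sample annotations as a data.frame.
#' @export
sampleAnnotations <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' SubtypeModel: binary nearest-centroid subtype classifier
#'
#' Holds per-subtype ordered top-gene lists and the \{0,1\} centroid matrix
#' (genes x subtypes) in which entry (g, k) is 1 iff gene g belongs to
#' subtype k's top list. Top lists are disjoint across subtypes.
#'
#' @slot labels Subtype labels (e.g. s1..s4).
#' @slot topGenes Named list of ordered top-gene character vectors.
#' @slot centroids \{0,1\} matrix, rownames = union of top genes.
#' @slot nTop Requested list length.
#' @export
setClass("SubtypeModel",
  representation(labels = "character", topGenes = "list",
                 centroids = "matrix", nTop = "integer"))

setValidity("SubtypeModel", function(object) {
  msg <- NULL
  g <- unlist(object@topGenes, use.names = FALSE)
  if (anyDuplicated(g))
    msg <- c(msg, "top-gene lists must be disjoint across subtypes")
  if (!identical(colnames(object@centroids), object@labels))
    msg <- c(msg, "centroid columns must match labels")
  if (!setequal(rownames(object@centroids), g))
    msg <- c(msg, "centroid rows must be the union of top lists")
  if (length(g) && !all(object@centroids %in% c(0, 1)))
    msg <- c(msg, "centroids must be 0/1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SubtypeModel", function(object) {
  cat("SubtypeModel with", length(object@labels), "subtypes (",
      paste(object@labels, collapse = ", "), ")\n")
  cat("  model genes:", nrow(object@centroids),
      "| top list length:", object@nTop, "\n")
})

#' @describeIn SubtypeModel-class Number of subtypes.
#' @param object A SubtypeModel.
#' @export
nSubtypes <- function(object) length(object@labels)

#' @describeIn SubtypeModel-class Subtype labels.
#' @export
subtypeLabels <- function(object) object@labels

#' @describeIn SubtypeModel-class Genes x subtypes centroid matrix.
#' @export
centroidMatrix <- function(object) object@centroids

#' @describeIn SubtypeModel-class Named list of ordered top-gene vectors.
#' @export
topGeneLists <- function(object) object@topGenes

#' SignedSubtypeModel: signed centroid classifier with significance fallback
#'
#' Centroid entries are -1/0/1 for genes down/absent/up in each subtype's
#' top lists. Profiles whose best centroid correlation is not significant at
#' \code{alpha} (Pearson correlation t-test) are assigned
#' \code{fallbackLabel}.
#'
#' @slot labels Subtype labels.
#' @slot centroids \{-1,0,1\} genes x subtypes matrix.
#' @slot alpha Significance level for the correlation test (default 0.05).
#' @slot fallbackLabel Label for non-aligning profiles.
#' @export
setClass("SignedSubtypeModel",
  representation(labels = "character", centroids = "matrix",
                 alpha = "numeric", fallbackLabel = "character"))

setValidity("SignedSubtypeModel", function(object) {
  msg <- NULL
  if (!all(object@centroids %in% c(-1, 0, 1)))
    msg <- c(msg, "centroids must be -1/0/1")
  if (!identical(colnames(object@centroids), object@labels))
    msg <- c(msg, "centroid columns must match labels")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignedSubtypeModel
#'
#' @param centroids \{-1,0,1\} genes x subtypes matrix with dimnames.
#' @param alpha Correlation-test significance level.
#' @param fallbackLabel Label assigned when no centroid aligns significantly.
#' @return A \linkS4class{SignedSubtypeModel}.
#' @export
SignedSubtypeModel <- function(centroids, alpha = 0.05,
                               fallbackLabel = "unaligned") {
  new("SignedSubtypeModel", labels = colnames(centroids),
      centroids = centroids, alpha = alpha, fallbackLabel = fallbackLabel)
}

setMethod("show", "SignedSubtypeModel", function(object) {
  cat("SignedSubtypeModel with", length(object@labels), "subtypes;",
      nrow(object@centroids), "genes; alpha =", object@alpha,
      "; fallback =", object@fallbackLabel, "\n")
})

#' ConsensusResult: resampled consensus clustering output
#'
#' @slot consensus Named list (by K) of sample x sample consensus matrices
#'   with entries in \[0,1\], symmetric, unit diagonal.
#' @slot assignments Sample x K integer matrix of per-K cluster labels.
#' @slot kRange Integer vector of K values.
#' @slot reps Number of resampling replicates.
#' @slot subsampleFraction Fraction of samples drawn per replicate.
#' @slot seed RNG seed used.
#' @export
setClass("ConsensusResult",
  representation(consensus = "list", assignments = "matrix",
                 kRange = "integer", reps = "integer",
                 subsampleFraction = "numeric", seed = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- NULL
  for (m in object@consensus) {
    if (max(abs(m - t(m))) > 1e-12) { msg <- c(msg, "consensus not symmetric"); break }
    if (any(m < -1e-12 | m > 1 + 1e-12)) { msg <- c(msg, "consensus outside [0,1]"); break }
    if (max(abs(diag(m) - 1)) > 1e-12) { msg <- c(msg, "consensus diagonal != 1"); break }
  }
  if (!identical(length(object@consensus), length(object@kRange)))
    msg <- c(msg, "one consensus matrix per K required")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: K =", paste(range(object@kRange), collapse = ".."),
      "|", object@reps, "replicates at fraction",
      object@subsampleFraction, "|", nrow(object@assignments), "samples\n")
})

#' @describeIn ConsensusResult-class Consensus matrix for one K.
#' @param object A ConsensusResult.
#' @param k Number of clusters.
#' @export
consensusMatrix <- function(object, k)
  object@consensus[[as.character(k)]]

#' @describeIn ConsensusResult-class Integer cluster assignments for one K.
#' @export
consensusAssignments <- function(object, k)
  object@assignments[, as.character(k)]
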
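# Cross-study assembly and normalization of expression compendia.

#' Convert raw counts to TPM
#'
#' Transcripts-per-million: per-feature count rates (counts / length in bp)
#' rescaled so each column sums to one million.
#'
#' @param counts Feature x sample non-negative count matrix.
#' @param lengths Named (or positionally matched) per-feature lengths in bp.
#' @return TPM matrix with the same dimnames.
#' @examples
#' countsToTPM(matrix(c(20, 10), 2, 1, dimnames = list(c("a", "b"), "s1")),
#'             c(a = 2000, b = 1000))
#' @export
countsToTPM <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      stop("missing length for feature(s): ",
           paste(utils::head(miss), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    stop("lengths must cover every feature")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Quantile-normalize a matrix
#'
#' Forces every sample (column) onto the identical distribution: the
#' per-rank means of the input columns (limma's standard algorithm; ties
#' and missing values handled as there).
#'
#' @param x Numeric matrix with at least two columns.
#' @return Quantile-normalized matrix.
#' @export
quantileNormalizeMatrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  bad <- colSums(!is.na(x)) == 0
  if (any(bad))
    stop("all-missing column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse multi-feature genes to their most variable feature
#'
#' When a gene is represented by several features (probes, transcripts),
#' the feature with the highest SD of log2-transformed values across
#' samples is kept; exact SD ties break to the lexicographically smallest
#' feature id. Values are passed through unmodified.
#'
#' @param x Feature x sample matrix (linear scale unless
#'   \code{isLog2 = TRUE}).
#' @param featureToGene Named character vector: feature id -> gene id.
#' @param isLog2 Set when \code{x} is already log2-transformed.
#' @param pseudocount Added before log2 for the SD computation on
#'   linear-scale input.
#' @return Gene x sample matrix (a row subset of \code{x}, rownames
#'   replaced by gene ids).
#' @export
collapseFeatures <- function(x, featureToGene, isLog2 = FALSE,
                             pseudocount = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("feature rownames required")
  genes <- featureToGene[rownames(x)]
  if (anyNA(genes)) stop("features without gene mapping present")
  lg <- if (isLog2) x else log2(x + pseudocount)
  sds <- sqrt(rowVarsNA(lg))
  sds[is.na(sds)] <- -Inf
  ord <- order(genes, -sds, rownames(x), method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- unname(genes[keep])
  out
}

#' Assemble per-study tables into one log2 compendium matrix
#'
#' Defines the gene universe from designated anchor studies (intersection
#' or union of their gene sets), log2-transforms linear-scale tables with a
#' pseudocount, and stacks studies column-wise; genes absent from a study
#' become \code{NA} for its samples.
#'
#' @param tables Named list of gene x sample matrices (one per study).
#' @param annotations Sample annotation data.frame (see
#'   [ExpressionCompendium()]).
#' @param universeRule \code{"intersection"} or \code{"union"}.
#' @param anchorStudies Studies defining the gene universe (default: all).
#' @param isLog2 Logical, per study (recycled): inputs already in log2
#'   (e.g. array intensities), passed through without re-logging.
#' @param pseudocount Pseudocount for the log2 transform of linear-scale
#'   inputs.
#' @return List with \code{log2} (gene x sample matrix over the universe)
#'   and \code{annotations} (rows matching its columns).
#' @export
assembleCompendium <- function(tables, annotations,
                               universeRule = c("intersection", "union"),
                               anchorStudies = names(tables),
                               isLog2 = FALSE, pseudocount = 1) {
  universeRule <- match.arg(universeRule)
  if (is.null(names(tables))) stop("tables must be named by study")
  stopifnot(all(anchorStudies %in% names(tables)))
  isLog2 <- rep_len(isLog2, length(tables))
  geneSets <- lapply(tables[anchorStudies], rownames)
  universe <- Reduce(if (universeRule == "intersection") intersect else union,
                     geneSets)
  universe <- sort(universe)
  allSamples <- unlist(lapply(tables, colnames), use.names = FALSE)
  if (anyDuplicated(allSamples))
    stop("sample ids must be unique across studies")
  if (!all(allSamples %in% annotations$sample_id))
    stop("annotation/sample mismatch: unannotated samples present")
  out <- matrix(NA_real_, length(universe), length(allSamples),
                dimnames = list(universe, allSamples))
  for (i in seq_along(tables)) {
    x <- as.matrix(tables[[i]])
    if (!isLog2[i]) x <- log2(x + pseudocount)
    g <- intersect(rownames(x), universe)
    out[g, colnames(x)] <- x[g, , drop = FALSE]
  }
  ann <- annotations[match(allSamples, annotations$sample_id), , drop = FALSE]
  list(log2 = out, annotations = ann)
}

#' Normalize genes to SD-from-median units within study x cancer-type strata
#'
#' Within each (study, cancer type) stratum, each gene's log2 values are
#' centered on the stratum median and divided by the stratum SD
#' (conventional n-1 sample SD), erasing study- and tissue-level location
#' and scale effects. Genes with fewer than two observed values or zero
#' spread in a stratum are set to 0 there; strata of size one yield
#' all-missing values with a warning.
#'
#' @param log2Matrix Gene x sample log2 matrix (NAs allowed).
#' @param annotations Sample annotation data.frame.
#' @return An [ExpressionCompendium-class].
#' @export
centerScaleWithinStrata <- function(log2Matrix, annotations) {
  annotations <- as.data.frame(annotations)
  idx <- match(colnames(log2Matrix), annotations$sample_id)
  if (anyNA(idx)) stop("unknown stratum key: samples without annotation")
  strata <- paste(annotations$study_id[idx], annotations$cancer_type[idx],
                  sep = "\r")
  out <- log2Matrix
  for (s in unique(strata)) {
    cols <- which(strata == s)
    block <- log2Matrix[, cols, drop = FALSE]
    if (length(cols) < 2) {
      warning("stratum of size 1 (",
              sub("\r", " / ", s), "): values set to missing")
      out[, cols] <- NA_real_
      next
    }
    med <- apply(block, 1, stats::median, na.rm = TRUE)
    sdv <- sqrt(rowVarsNA(block))
    nObs <- rowSums(!is.na(block))
    z <- (block - med) / sdv
    degenerate <- nObs < 2 | is.na(sdv) | sdv == 0
    z[degenerate, ] <- ifelse(is.na(block[degenerate, , drop = FALSE]),
                              NA_real_, 0)
    out[, cols] <- z
  }
  ExpressionCompendium(out, annotations)
}

#' Check the per-stratum normalization invariant
#'
#' For every (study x cancer type, gene) stratum with at least two observed
#' values and nonzero spread, reports the largest absolute deviation of the
#' median from 0 and of the SD from 1.
#'
#' @param compendium An [ExpressionCompendium-class].
#' @return List with \code{maxAbsMedian} and \code{maxAbsSDminus1}.
#' @export
validateStrataNormalization <- function(compendium) {
  x <- sduMatrix(compendium)
  ann <- sampleAnnotations(compendium)
  strata <- paste(ann$study_id, ann$cancer_type, sep = "\r")
  worstMed <- 0; worstSd <- 0
  for (s in unique(strata)) {
    block <- x[, strata == s, drop = FALSE]
    if (ncol(block) < 2) next
    nObs <- rowSums(!is.na(block))
    sdv <- sqrt(rowVarsNA(block))
    keep <- nObs >= 2 & !is.na(sdv) & sdv > 0
    if (!any(keep)) next
    med <- apply(block[keep, , drop = FALSE], 1, stats::median, na.rm = TRUE)
    worstMed <- max(worstMed, max(abs(med)))
    worstSd <- max(worstSd, max(abs(sdv[keep] - 1)))
  }
  list(maxAbsMedian = worstMed, maxAbsSDminus1 = worstSd)
}

#' Paired metastasis-versus-primary normalization
#'
#' Centers each metastasis log2 profile on its paired primary (the primary
#' itself becoming exactly zero), then divides, per study and per gene, by
#' the SD computed across the centered metastasis profiles together with
#' the (all-zero) centered primary profiles of that study. Genes with zero
#' SD yield 0.
#'
#' @param metLog2 Gene x metastasis log2 matrix.
#' @param primaryLog2 Gene x primary log2 matrix.
#' @param pairs data.frame with columns \code{met_id}, \code{primary_id},
#'   \code{study_id} (one row per metastasis).
#' @return List with \code{delta} (gene x metastasis matrix of unitless
#'   differential values) and \code{pairs}.
#' @export
pairedNormalize <- function(metLog2, primaryLog2, pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("met_id", "primary_id", "study_id")
  stopifnot(all(need %in% colnames(pairs)))
  miss <- setdiff(colnames(metLog2), pairs$met_id)
  if (length(miss))
    stop("unpaired metastasis profile(s): ",
         paste(utils::head(miss), collapse = ", "))
  pairs <- pairs[match(colnames(metLog2), pairs$met_id), , drop = FALSE]
  if (!all(pairs$primary_id %in% colnames(primaryLog2)))
    stop("primary profile(s) missing from primary matrix")
  genes <- intersect(rownames(metLog2), rownames(primaryLog2))
  delta <- metLog2[genes, , drop = FALSE] -
    primaryLog2[genes, pairs$primary_id, drop = FALSE]
  for (s in unique(pairs$study_id)) {
    cols <- which(pairs$study_id == s)
    d <- delta[, cols, drop = FALSE]
    # SD across centered metastasis plus the all-zero primary columns
    zeros <- matrix(0, nrow(d), length(cols))
    zeros[is.na(d)] <- NA_real_
    sdv <- sqrt(rowVarsNA(cbind(d, zeros)))
    sdv[is.na(sdv) | sdv == 0] <- Inf
    delta[, cols] <- d / sdv
  }
  list(delta = delta, pairs = pairs)
}

#' Flag lymphoma-like PDX samples by B cell marker or signature
#'
#' Within one study's log2 matrix, a sample is flagged for removal when
#' either the B cell marker gene, standardized across the dataset to
#' SD-from-median units, is at or above \code{cutoff}, or the B cell
#' signature score (mean of the standardized signature-gene values,
#' re-standardized to SD-from-median across the dataset) is at or above
#' \code{cutoff}.
#'
#' @param log2Matrix Gene x sample log2 matrix for a single study.
#' @param markerGene Marker gene id (e.g. CD19).
#' @param signatureGenes Character vector of signature gene ids.
#' @param cutoff Threshold in SD-from-median units (default 3).
#' @return List with \code{kept}, \code{removed}, and a \code{report}
#'   data.frame (sample_id, markerZ, signatureZ, reason).
#' @export
filterLymphomaLike <- function(log2Matrix, markerGene, signatureGenes,
                               cutoff = 3) {
  if (!markerGene %in% rownames(log2Matrix))
    stop("marker gene ", markerGene, " absent from matrix")
  signatureGenes <- intersect(signatureGenes, rownames(log2Matrix))
  if (length(signatureGenes) < 1)
    stop("no signature genes present in matrix")
  standardize <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    (v - stats::median(v, na.rm = TRUE)) / s
  }
  markerZ <- standardize(log2Matrix[markerGene, ])
  sigRaw <- colMeans(
    t(apply(log2Matrix[signatureGenes, , drop = FALSE], 1, standardize)),
    na.rm = TRUE)
  sigZ <- standardize(sigRaw)
  byMarker <- !is.na(markerZ) & markerZ >= cutoff
  bySig <- !is.na(sigZ) & sigZ >= cutoff
  removed <- byMarker | bySig
  reason <- rep("", ncol(log2Matrix))
  reason[byMarker] <- "marker"
  reason[bySig & !byMarker] <- "signature"
  reason[bySig & byMarker] <- "marker+signature"
  report <- data.frame(sample_id = colnames(log2Matrix),
                       markerZ = markerZ, signatureZ = sigZ,
                       removed = removed, reason = reason)
  list(kept = colnames(log2Matrix)[!removed],
       removed = colnames(log2Matrix)[removed],
       report = report)
}
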
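# Subtype discovery: resampled consensus Ward clustering on 1 - Pearson
# correlation distance, minor-cluster reclassification, and the top-gene
# binary centroid model.

#' Randomly select well-represented genes for clustering
#'
#' Uniform sample without replacement from the genes observed (non-missing)
#' in at least \code{minPresence} samples.
#'
#' @param compendium An [ExpressionCompendium-class] (or SD-unit matrix).
#' @param n Number of genes to select.
#' @param minPresence Minimum number of samples in which a gene must be
#'   observed.
#' @param seed RNG seed.
#' @return Character vector of gene ids.
#' @export
selectClusteringGenes <- function(compendium, n, minPresence, seed) {
  x <- if (is(compendium, "ExpressionCompendium"))
    sduMatrix(compendium) else as.matrix(compendium)
  eligible <- rownames(x)[rowSums(!is.na(x)) >= minPresence]
  if (length(eligible) < n)
    stop("eligible gene pool (", length(eligible),
         ") smaller than requested n = ", n)
  withSeed(seed, sample(eligible, n))
}

# Pairwise-complete 1 - Pearson distance; pairs sharing fewer than
# minShared genes get maximal distance 1 (with a single warning).
correlationDistance <- function(x, minShared = 30) {
  suppressWarnings(cc <- stats::cor(x, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(x))
  few <- shared < minShared
  diag(few) <- FALSE
  if (any(few)) {
    warning(sum(few) / 2, " sample pair(s) share fewer than ", minShared,
            " genes; distance set to 1")
    cc[few] <- 0
  }
  cc[is.na(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Monti-style resampled consensus clustering
#'
#' For each replicate, a fraction of samples is drawn without replacement,
#' Ward-linkage (ward.D2) hierarchical clustering is run on the
#' 1 - Pearson correlation distance, and the tree is cut at every K in
#' \code{kRange}. The consensus matrix entry (i, j) is the number of times
#' the pair co-clustered divided by the number of times it was
#' co-subsampled (0 when never co-subsampled; diagonal 1). The per-K
#' assignment is a final hierarchical clustering of 1 - consensus cut
#' at K.
#'
#' @param x Gene x sample SD-unit matrix (missing values allowed;
#'   distances use pairwise-complete observations).
#' @param kRange Integer vector of cluster numbers, within \[2, n-1\].
#' @param reps Number of resampling replicates.
#' @param subsampleFraction Fraction of samples per replicate.
#' @param seed RNG seed.
#' @param minShared Minimum shared genes for a defined correlation.
#' @return A [ConsensusResult-class].
#' @export
consensusCluster <- function(x, kRange = 2:15, reps = 1000,
                             subsampleFraction = 0.8, seed = 1,
                             minShared = 30) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  n <- ncol(x)
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2 || max(kRange) > n - 1)
    stop("kRange must lie within [2, n-1]")
  D <- correlationDistance(x, minShared)
  m <- ceiling(subsampleFraction * n)
  if (m < max(kRange) + 1)
    stop("subsample size too small for max(kRange)")
  counts <- lapply(kRange, function(k) matrix(0, n, n))
  names(counts) <- as.character(kRange)
  togetherN <- matrix(0, n, n)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample(n, m))
      togetherN[idx, idx] <- togetherN[idx, idx] + 1
      hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "ward.D2")
      cl <- stats::cutree(hc, k = kRange)
      if (is.null(dim(cl))) cl <- matrix(cl, ncol = 1)
      for (j in seq_along(kRange)) {
        Z <- outer(cl[, j], cl[, j], "==")
        counts[[j]][idx, idx] <- counts[[j]][idx, idx] + Z
      }
    }
  })
  sampleIds <- colnames(x)
  consensus <- lapply(counts, function(M) {
    C <- ifelse(togetherN > 0, M / togetherN, 0)
    C <- (C + t(C)) / 2
    diag(C) <- 1
    dimnames(C) <- list(sampleIds, sampleIds)
    C
  })
  assignments <- vapply(seq_along(kRange), function(j) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[j]]),
                        method = "ward.D2")
    stats::cutree(hc, k = kRange[j])
  }, integer(n))
  dimnames(assignments) <- list(sampleIds, as.character(kRange))
  new("ConsensusResult", consensus = consensus, assignments = assignments,
      kRange = kRange, reps = as.integer(reps),
      subsampleFraction = subsampleFraction, seed = as.integer(seed))
}

#' Consensus CDF and delta-area diagnostics per K
#'
#' Computes the empirical CDF of the off-diagonal consensus entries for
#' each K and the relative increase in the area under the CDF versus the
#' previous K (Monti's delta-area; the first K reports its own area).
#' Stability of the consensus as K grows guides, but does not automate,
#' the choice of K.
#'
#' @param result A [ConsensusResult-class] covering at least two K values.
#' @return data.frame with columns \code{k}, \code{areaUnderCDF},
#'   \code{deltaArea}.
#' @export
evaluateK <- function(result) {
  kRange <- result@kRange
  if (length(kRange) < 2) stop("need at least two K values")
  areas <- vapply(as.character(kRange), function(k) {
    C <- result@consensus[[k]]
    v <- sort(C[upper.tri(C)])
    # area under the ECDF over [0, 1]
    cdf <- stats::ecdf(v)
    xs <- sort(unique(c(0, v, 1)))
    sum(diff(xs) * cdf(xs[-length(xs)]))
  }, numeric(1))
  delta <- numeric(length(areas))
  delta[1] <- areas[1]
  if (length(areas) > 1)
    delta[-1] <- diff(areas) / areas[-length(areas)]
  data.frame(k = kRange, areaUnderCDF = unname(areas),
             deltaArea = unname(delta))
}

#' Per-subtype ordered top differential genes
#'
#' For every gene and subtype, the Welch t-statistic of subtype versus the
#' rest is computed on pairwise-complete values. A gene is eligible only
#' for the subtype where its t-statistic is maximal; each subtype's list
#' is its eligible genes sorted by descending t (ties by gene id),
#' truncated at \code{nTop}. Lists are therefore disjoint by construction.
#'
#' @param x Gene x sample SD-unit matrix or [ExpressionCompendium-class].
#' @param labels Subtype label per sample (named by sample id or aligned
#'   with columns).
#' @param nTop List length per subtype (default 200).
#' @return Named list of ordered gene id vectors, one per subtype.
#' @export
selectTopGenes <- function(x, labels, nTop = 200) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  labels <- alignLabels(labels, colnames(x))
  subs <- sort(unique(labels))
  if (length(subs) < 2) stop("need at least 2 subtypes")
  small <- names(which(table(labels) < 3))
  if (length(small))
    stop("subtype(s) with fewer than 3 samples: ",
         paste(small, collapse = ", "))
  tmat <- vapply(subs, function(k) rowWelchT(x, labels == k)$t,
                 numeric(nrow(x)))
  rownames(tmat) <- rownames(x)
  ok <- rowSums(is.na(tmat)) == 0
  tmat <- tmat[ok, , drop = FALSE]
  best <- subs[max.col(tmat, ties.method = "first")]
  out <- lapply(subs, function(k) {
    g <- rownames(tmat)[best == k]
    tg <- tmat[g, k]
    g <- g[order(-tg, g, method = "radix")]
    utils::head(g, nTop)
  })
  stats::setNames(out, subs)
}

#' Build the binary centroid subtype model
#'
#' @param topLists Named list of disjoint ordered top-gene vectors.
#' @param nTop Requested list length (defaults to the longest list).
#' @return A [SubtypeModel-class] whose \{0,1\} centroid matrix spans the
#'   union of the lists.
#' @export
buildSubtypeModel <- function(topLists, nTop = max(lengths(topLists))) {
  if (length(topLists) == 0 || sum(lengths(topLists)) == 0)
    stop("empty model: no top genes supplied")
  genes <- unlist(topLists, use.names = FALSE)
  if (anyDuplicated(genes)) stop("top-gene lists must be disjoint")
  labels <- names(topLists)
  M <- vapply(topLists, function(g) as.numeric(genes %in% g),
              numeric(length(genes)))
  dimnames(M) <- list(genes, labels)
  new("SubtypeModel", labels = labels, topGenes = topLists,
      centroids = M, nTop = as.integer(nTop))
}

#' Reclassify minor clusters onto the kept subtypes
#'
#' Builds a top-gene centroid model from the samples currently in the kept
#' clusters (single pass), then reassigns every sample of a non-kept
#' cluster to the kept subtype whose binary centroid correlates best with
#' its profile. Kept-cluster samples retain their labels.
#'
#' @param x Gene x sample SD-unit matrix or [ExpressionCompendium-class].
#' @param assignments Cluster id per sample (named or column-aligned).
#' @param keep Cluster ids to retain as subtypes.
#' @param nTop Top-gene list length for the reclassification model.
#' @param relabel Optional named vector mapping kept cluster ids to final
#'   subtype labels (default \code{s1..sK} in \code{keep} order).
#' @return List with \code{labels} (final label per sample), \code{model}
#'   (the [SubtypeModel-class] used) and \code{reclassified} (ids of the
#'   reassigned samples).
#' @export
reclassifyMinorClusters <- function(x, assignments, keep, nTop = 200,
                                    relabel = NULL) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  assignments <- alignLabels(as.character(assignments), colnames(x))
  keep <- as.character(keep)
  if (!all(keep %in% unique(assignments)))
    stop("keep must be a subset of observed cluster ids")
  if (is.null(relabel))
    relabel <- stats::setNames(paste0("s", seq_along(keep)), keep)
  keptCols <- assignments %in% keep
  keptLabels <- stats::setNames(unname(relabel[assignments[keptCols]]),
                                colnames(x)[keptCols])
  if (any(table(keptLabels) < 3))
    stop("kept cluster with fewer than 3 samples")
  topLists <- selectTopGenes(x[, keptCols, drop = FALSE], keptLabels,
                             nTop = nTop)
  model <- buildSubtypeModel(topLists, nTop = nTop)
  labels <- character(ncol(x))
  names(labels) <- colnames(x)
  labels[keptCols] <- unname(keptLabels)
  reclass <- colnames(x)[!keptCols]
  if (length(reclass)) {
    calls <- classifyDataset(x[, reclass, drop = FALSE], model)
    labels[reclass] <- calls$label
  }
  list(labels = labels, model = model, reclassified = reclass)
}

# Align a (possibly named) label vector to a column-id vector.
alignLabels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss))
      stop("labels missing for sample(s): ",
           paste(utils::head(miss), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named or match the number of samples")
  }
  unname(labels)
}
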
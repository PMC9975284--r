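# Differential expression, gene-set overlap, TF-target and annotation
# enrichment, reference-signature scoring, and drug-response association.

#' Subtype-versus-rest differential expression
#'
#' Welch two-sample t per gene (pairwise-complete), subtype against all
#' other samples, for one or all subtypes. The \code{highest_in_subtype}
#' flag marks genes whose mean in the tested subtype exceeds every other
#' subtype's mean. Genes with degenerate group sizes are kept as skipped
#' rows. q-values (Storey) are reported alongside the nominal p-values.
#'
#' @param x Gene x sample SD-unit matrix or [ExpressionCompendium-class].
#' @param labels Subtype label per sample.
#' @param subtype Single subtype to test (default: all observed).
#' @return data.frame with gene, subtype, t, p, q, mean_diff, direction,
#'   highest_in_subtype, skipped.
#' @export
differentialExpression <- function(x, labels, subtype = NULL) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  labels <- alignLabels(labels, colnames(x))
  subs <- sort(unique(labels))
  means <- vapply(subs, function(k)
    rowMeans(x[, labels == k, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x)))
  if (is.null(dim(means)))
    means <- matrix(means, nrow = nrow(x),
                    dimnames = list(rownames(x), subs))
  test <- if (is.null(subtype)) subs else intersect(subs, subtype)
  if (!length(test)) stop("subtype not present in labels")
  out <- lapply(test, function(k) {
    w <- rowWelchT(x, labels == k)
    top <- means[, k] >= apply(means[, setdiff(subs, k), drop = FALSE],
                               1, max, na.rm = TRUE)
    data.frame(gene = rownames(x), subtype = k, t = w$t, p = w$p,
               q = estimateQValues(w$p),
               mean_diff = w$meanIn - w$meanOut,
               direction = ifelse(is.na(w$t), NA_character_,
                                  ifelse(w$t >= 0, "up", "down")),
               highest_in_subtype = !is.na(w$t) & w$t > 0 & top,
               skipped = w$skipped)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired metastasis-versus-primary differential expression
#'
#' One-sample t of the per-pair normalized deltas against zero per gene
#' (equivalent to a paired t-test of metastasis versus primary). All-zero
#' genes yield t = 0, p = 1; zero-spread nonzero genes are flagged exact
#' with p approaching 0.
#'
#' @param deltas Gene x metastasis matrix of paired differential values
#'   (from [pairedNormalize()]).
#' @param subset Optional metastasis sample ids to restrict to (e.g. one
#'   subtype's pairs).
#' @return data.frame with gene, t, p, q, mean_delta, n, direction,
#'   skipped.
#' @export
pairedDifferential <- function(deltas, subset = NULL) {
  deltas <- as.matrix(deltas)
  if (!is.null(subset))
    deltas <- deltas[, intersect(colnames(deltas), subset), drop = FALSE]
  if (ncol(deltas) < 3) stop("need >= 3 pairs")
  t1 <- rowOneSampleT(deltas)
  data.frame(gene = rownames(deltas), t = t1$t, p = t1$p,
             q = estimateQValues(t1$p), mean_delta = t1$mean, n = t1$n,
             direction = ifelse(is.na(t1$t), NA_character_,
                                ifelse(t1$t >= 0, "up", "down")),
             skipped = t1$skipped)
}

#' One-sided overlap test between two gene sets
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over the
#' universe and tests enrichment of the overlap with the Fisher/chi-square
#' switch.
#'
#' @param setA,setB Character vectors of gene ids (subsets of
#'   \code{universe}).
#' @param universe Character vector defining the gene universe.
#' @param method Passed to [enrichmentTest()].
#' @return One-row data.frame with counts, odds, one-sided p and method.
#' @export
geneSetOverlap <- function(setA, setB, universe,
                           method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  if (length(universe) == 0) stop("empty universe")
  setA <- intersect(setA, universe); setB <- intersect(setB, universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  cc <- length(setB) - a
  d <- length(universe) - a - b - cc
  et <- enrichmentTest(a, b, cc, d, method = method)
  data.frame(n_universe = length(universe), both = a, a_only = b,
             b_only = cc, neither = d, odds = et$odds, p = et$p,
             method = et$method)
}

#' Cross-tabulated overlaps of orthogonal subtype gene-set families
#'
#' Overlaps every subtype's differential set from one comparison family
#' (e.g. subtype versus rest) with every subtype's set from an orthogonal
#' family (e.g. paired metastasis versus primary within subtype), and
#' collects the consensus genes: the union over subtypes of the diagonal
#' intersections whose overlap p passes \code{pCut}.
#'
#' @param setsA,setsB Named lists of gene sets, one per subtype (same
#'   names).
#' @param universe Gene universe for the 2x2 tables.
#' @param pCut Diagonal significance cutoff (default 1e-6).
#' @param method Passed to [enrichmentTest()].
#' @return List with \code{p} (K x K matrix, rows = A subtypes),
#'   \code{consensus} (character vector), and \code{perSubtype} (list of
#'   diagonal intersections passing the cut).
#' @export
orthogonalOverlapMatrix <- function(setsA, setsB, universe, pCut = 1e-6,
                                    method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(identical(names(setsA), names(setsB)))
  subs <- names(setsA)
  P <- matrix(NA_real_, length(subs), length(subs),
              dimnames = list(subs, subs))
  for (i in subs) for (j in subs)
    P[i, j] <- geneSetOverlap(setsA[[i]], setsB[[j]], universe,
                              method = method)$p
  perSub <- lapply(subs, function(k)
    if (!is.na(P[k, k]) && P[k, k] < pCut)
      intersect(setsA[[k]], setsB[[k]]) else character(0))
  names(perSub) <- subs
  list(p = P, consensus = sort(unique(unlist(perSub))),
       perSubtype = perSub)
}

#' Score samples against a centered reference differential profile
#'
#' Pearson correlation between each sample's SD-unit profile and the
#' reference profile over their shared (pairwise-complete) genes.
#'
#' @param x Gene x sample SD-unit matrix or [ExpressionCompendium-class].
#' @param reference Named numeric vector (centered reference profile).
#' @param referenceId Identifier recorded in the output.
#' @param minShared Minimum shared genes per sample (default 30).
#' @return data.frame with sample_id, reference_id, score, n_shared.
#' @export
signatureScore <- function(x, reference, referenceId = "reference",
                           minShared = 30) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  genes <- intersect(rownames(x), names(reference))
  if (length(genes) < minShared)
    stop("only ", length(genes), " shared genes; floor is ", minShared)
  xr <- x[genes, , drop = FALSE]
  ref <- reference[genes]
  score <- vapply(seq_len(ncol(xr)), function(j) {
    ok <- !is.na(xr[, j]) & !is.na(ref)
    if (sum(ok) < minShared) return(NA_real_)
    suppressWarnings(stats::cor(xr[ok, j], ref[ok]))
  }, numeric(1))
  nShared <- colSums(!is.na(xr) & !is.na(ref))
  data.frame(sample_id = colnames(x), reference_id = referenceId,
             score = score, n_shared = nShared)
}

#' Transcription-factor target enrichment with expression confirmation
#'
#' A TF passes for a subtype when its target set overlaps that subtype's
#' high-expression gene set at \code{overlapCut} in BOTH dataset families
#' AND the TF's own gene is differentially expressed (p below
#' \code{exprCut}, either direction, recorded) in that subtype in both
#' families.
#'
#' @param tfSets Named list of TF target gene sets; names are TF gene ids.
#' @param deSets1,deSets2 Named lists (by subtype) of high-expression gene
#'   sets for the two dataset families.
#' @param expr1,expr2 Gene x sample SD-unit matrices for the two families
#'   (must contain the TF genes to be testable).
#' @param labels1,labels2 Subtype labels for the two matrices.
#' @param universe1,universe2 Gene universes for the overlap tables.
#' @param overlapCut Overlap significance cutoff (default 1e-6).
#' @param exprCut TF-gene t-test cutoff (default 0.05).
#' @param method Passed to [enrichmentTest()].
#' @return data.frame with tf, subtype, overlap p in both families, TF
#'   gene t/p in both families, direction, and \code{passes}.
#' @export
tfEnrichment <- function(tfSets, deSets1, deSets2, expr1, expr2,
                         labels1, labels2,
                         universe1 = rownames(expr1),
                         universe2 = rownames(expr2),
                         overlapCut = 1e-6, exprCut = 0.05,
                         method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(identical(names(deSets1), names(deSets2)))
  subs <- names(deSets1)
  expr1 <- if (is(expr1, "ExpressionCompendium")) sduMatrix(expr1) else
    as.matrix(expr1)
  expr2 <- if (is(expr2, "ExpressionCompendium")) sduMatrix(expr2) else
    as.matrix(expr2)
  labels1 <- alignLabels(labels1, colnames(expr1))
  labels2 <- alignLabels(labels2, colnames(expr2))
  rows <- list()
  for (tf in names(tfSets)) {
    if (!(tf %in% rownames(expr1)) || !(tf %in% rownames(expr2))) next
    for (k in subs) {
      p1 <- geneSetOverlap(tfSets[[tf]], deSets1[[k]], universe1,
                           method = method)$p
      p2 <- geneSetOverlap(tfSets[[tf]], deSets2[[k]], universe2,
                           method = method)$p
      w1 <- rowWelchT(expr1[tf, , drop = FALSE], labels1 == k)
      w2 <- rowWelchT(expr2[tf, , drop = FALSE], labels2 == k)
      dir1 <- if (is.na(w1$t)) NA_character_ else
        if (w1$t >= 0) "up" else "down"
      passes <- !is.na(p1) && !is.na(p2) && p1 < overlapCut &&
        p2 < overlapCut && !is.na(w1$p) && !is.na(w2$p) &&
        w1$p < exprCut && w2$p < exprCut
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, subtype = k, overlap_p1 = p1, overlap_p2 = p2,
        tf_t1 = w1$t, tf_p1 = w1$p, tf_t2 = w2$t, tf_p2 = w2$p,
        direction = dir1, passes = passes)
    }
  }
  if (!length(rows))
    return(data.frame(tf = character(0), subtype = character(0),
                      overlap_p1 = numeric(0), overlap_p2 = numeric(0),
                      tf_t1 = numeric(0), tf_p1 = numeric(0),
                      tf_t2 = numeric(0), tf_p2 = numeric(0),
                      direction = character(0), passes = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotation-term enrichment within a gene set
#'
#' One-sided Fisher's exact test of each annotation term's gene set
#' against the query set over the universe, sorted by p.
#'
#' @param geneSet Character vector of query genes.
#' @param annotation Named list of term gene sets (e.g. from
#'   [readGMT()]).
#' @param universe Gene universe.
#' @return data.frame with term, counts, odds, p, sorted ascending by p.
#' @export
annotationEnrichment <- function(geneSet, annotation, universe) {
  if (!length(annotation)) stop("annotation is empty")
  rows <- lapply(names(annotation), function(term) {
    ov <- geneSetOverlap(geneSet, annotation[[term]], universe,
                         method = "fisher")
    data.frame(term = term, set_size = ov$both + ov$b_only,
               overlap = ov$both, odds = ov$odds, p = ov$p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two ln IC50 tables
#'
#' Cell-wise mean where a (drug, cell line) is measured in both tables;
#' the available single value otherwise; missing where neither. Symmetric
#' in argument order.
#'
#' @param table1,table2 Drug x cell-line matrices with dimnames.
#' @return Merged matrix over the union of drugs and cell lines.
#' @export
mergeIC50 <- function(table1, table2) {
  drugs <- sort(union(rownames(table1), rownames(table2)))
  lines <- sort(union(colnames(table1), colnames(table2)))
  expand <- function(m) {
    out <- matrix(NA_real_, length(drugs), length(lines),
                  dimnames = list(drugs, lines))
    out[rownames(m), colnames(m)] <- as.matrix(m)
    out
  }
  a <- expand(table1); b <- expand(table2)
  both <- !is.na(a) & !is.na(b)
  out <- ifelse(both, (a + b) / 2, ifelse(is.na(a), b, a))
  dimnames(out) <- list(drugs, lines)
  out
}

#' Drug response association with subtypes
#'
#' Welch t per (drug, subtype) comparing ln IC50 of the subtype's cell
#' lines with the rest; direction is "sensitive" when the subtype mean is
#' lower. Drugs with fewer than 3 measured lines in either group are kept
#' as skipped rows.
#'
#' @param lnIC50 Drug x cell-line matrix of natural-log IC50 values.
#' @param labels Subtype label per cell line.
#' @return data.frame with drug, subtype, n_in, n_out, mean_diff
#'   (in minus out), t, p, q, direction, skipped.
#' @export
drugResponseAssociation <- function(lnIC50, labels) {
  lnIC50 <- as.matrix(lnIC50)
  labels <- alignLabels(labels, colnames(lnIC50))
  subs <- sort(unique(labels))
  out <- lapply(subs, function(k) {
    w <- rowWelchT(lnIC50, labels == k)
    data.frame(drug = rownames(lnIC50), subtype = k,
               n_in = w$nIn, n_out = w$nOut,
               mean_diff = w$meanIn - w$meanOut, t = w$t, p = w$p,
               q = estimateQValues(w$p),
               direction = ifelse(is.na(w$t), NA_character_,
                                  ifelse(w$meanIn < w$meanOut,
                                         "sensitive", "resistant")),
               skipped = w$skipped)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
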
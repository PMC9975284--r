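# Nearest-centroid subtype assignment and concordance statistics.

corWithCentroids <- function(profile, centroids) {
  genes <- intersect(names(profile), rownames(centroids))
  v <- profile[genes]
  genes <- genes[!is.na(v)]
  v <- profile[genes]
  n <- length(genes)
  r <- rep(NA_real_, ncol(centroids))
  if (n >= 3)
    suppressWarnings(
      r <- as.vector(stats::cor(v, centroids[genes, , drop = FALSE])))
  list(r = r, n = n)
}

#' Assign a profile to a subtype by binary centroid correlation
#'
#' Pearson correlation between the profile (restricted to model genes,
#' pairwise-complete) and each \{0,1\} centroid column; the label is the
#' argmax, with exact ties broken to the lowest subtype index and flagged.
#'
#' @param profile Named numeric vector of SD-unit gene values.
#' @param model A [SubtypeModel-class].
#' @param minGenes Minimum number of model genes that must be observed
#'   (default 30).
#' @return List with \code{label}, \code{correlations} (named vector),
#'   \code{nGenes} and \code{tie} flag.
#' @export
assignSubtype <- function(profile, model, minGenes = 30) {
  cw <- corWithCentroids(profile, centroidMatrix(model))
  if (cw$n < minGenes)
    stop("only ", cw$n, " model genes observed; floor is ", minGenes)
  r <- stats::setNames(cw$r, subtypeLabels(model))
  if (all(is.na(r)))
    return(list(label = NA_character_, correlations = r, nGenes = cw$n,
                tie = FALSE))
  best <- which(r == max(r, na.rm = TRUE))
  list(label = subtypeLabels(model)[best[1]], correlations = r,
       nGenes = cw$n, tie = length(best) > 1)
}

#' Assign a profile with the signed centroid scheme and fallback
#'
#' Correlates the profile against \{-1,0,1\} centroids; the best label's
#' correlation is tested via t = r * sqrt((n - 2) / (1 - r^2)) against
#' Student's t with n - 2 df (two-sided, one test). When p >= alpha the
#' profile is assigned the model's fallback label.
#'
#' @param profile Named numeric vector of SD-unit gene values.
#' @param model A [SignedSubtypeModel-class].
#' @param minGenes Minimum observed model genes.
#' @return List with \code{label}, \code{correlations}, \code{nGenes},
#'   \code{p} and \code{fallback} flag.
#' @export
assignSignedSubtype <- function(profile, model, minGenes = 30) {
  cw <- corWithCentroids(profile, model@centroids)
  if (cw$n <= 2)
    stop("only ", cw$n, " shared genes; need > 2")
  if (cw$n < minGenes)
    stop("only ", cw$n, " model genes observed; floor is ", minGenes)
  r <- stats::setNames(cw$r, model@labels)
  if (all(is.na(r)))
    return(list(label = model@fallbackLabel, correlations = r,
                nGenes = cw$n, p = NA_real_, fallback = TRUE))
  best <- which.max(r)
  rb <- unname(r[best])
  tstat <- rb * sqrt((cw$n - 2) / max(1 - rb^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), cw$n - 2)
  if (is.na(p) || p >= model@alpha)
    list(label = model@fallbackLabel, correlations = r, nGenes = cw$n,
         p = p, fallback = TRUE)
  else
    list(label = model@labels[best], correlations = r, nGenes = cw$n,
         p = p, fallback = FALSE)
}

#' Classify every sample of a matrix by subtype
#'
#' Column-wise [assignSubtype()] (or [assignSignedSubtype()] for a signed
#' model). Samples with too few observed model genes are kept as flagged
#' rows with an \code{NA} label rather than failing the run.
#'
#' @param x Gene x sample SD-unit matrix or [ExpressionCompendium-class].
#' @param model A [SubtypeModel-class] or [SignedSubtypeModel-class].
#' @param minGenes Minimum observed model genes per sample.
#' @return data.frame with sample_id, label, one correlation column per
#'   subtype (\code{corr_<label>}), n_genes, and flags (\code{tie},
#'   \code{too_few_genes}; \code{fallback} for signed models).
#' @export
classifyDataset <- function(x, model, minGenes = 30) {
  x <- if (is(x, "ExpressionCompendium")) sduMatrix(x) else as.matrix(x)
  if (nrow(centroidMatrixAny(model)) == 0 ||
      length(labelsAny(model)) == 0)
    stop("empty model")
  signed <- is(model, "SignedSubtypeModel")
  labels <- labelsAny(model)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    prof <- x[, j]
    a <- tryCatch(
      if (signed) assignSignedSubtype(prof, model, minGenes)
      else assignSubtype(prof, model, minGenes),
      error = function(e) NULL)
    if (is.null(a)) {
      a <- list(label = NA_character_,
                correlations = stats::setNames(rep(NA_real_, length(labels)),
                                               labels),
                nGenes = sum(!is.na(prof[rownames(centroidMatrixAny(model))])),
                tie = FALSE, p = NA_real_, fallback = FALSE)
      a$too_few <- TRUE
    } else a$too_few <- FALSE
    a
  })
  out <- data.frame(sample_id = colnames(x),
                    label = vapply(rows, `[[`, character(1), "label"))
  cors <- t(vapply(rows, `[[`, numeric(length(labels)), "correlations"))
  colnames(cors) <- paste0("corr_", labels)
  out <- cbind(out, cors)
  out$n_genes <- vapply(rows, `[[`, numeric(1), "nGenes")
  out$too_few_genes <- vapply(rows, `[[`, logical(1), "too_few")
  if (signed) {
    out$p <- vapply(rows, function(r) r$p %||% NA_real_, numeric(1))
    out$fallback <- vapply(rows, function(r) isTRUE(r$fallback), logical(1))
  } else {
    out$tie <- vapply(rows, function(r) isTRUE(r$tie), logical(1))
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

centroidMatrixAny <- function(model)
  if (is(model, "SignedSubtypeModel")) model@centroids else
    centroidMatrix(model)

labelsAny <- function(model)
  if (is(model, "SignedSubtypeModel")) model@labels else
    subtypeLabels(model)

#' Plurality concordance of subtype labels across a patient's tumors
#'
#' For each patient with two or more tumors, the plurality label is the
#' unique strict mode of their labels; patients whose modal count is tied
#' have no plurality. The overall fraction is over multi-tumor patients.
#'
#' @param labels Subtype label per sample (named by sample id or aligned
#'   with \code{patients}).
#' @param patients Patient id per sample.
#' @return List with \code{perPatient} data.frame (patient_id, n_tumors,
#'   plurality_label, has_plurality), \code{fraction} and \code{nPatients}.
#' @export
pluralityConcordance <- function(labels, patients) {
  stopifnot(length(labels) == length(patients))
  keep <- !is.na(labels)
  labels <- labels[keep]; patients <- patients[keep]
  tabs <- split(labels, patients)
  tabs <- tabs[lengths(tabs) >= 2]
  if (length(tabs) < 1)
    stop("no patient with >= 2 tumors")
  per <- lapply(names(tabs), function(p) {
    tt <- sort(table(tabs[[p]]), decreasing = TRUE)
    strict <- length(tt) == 1 || tt[1] > tt[2]
    data.frame(patient_id = p, n_tumors = length(tabs[[p]]),
               plurality_label = if (strict) names(tt)[1] else NA_character_,
               has_plurality = strict)
  })
  per <- do.call(rbind, per)
  list(perPatient = per, fraction = mean(per$has_plurality),
       nPatients = nrow(per))
}

#' Metastasis-versus-primary subtype agreement and per-subtype overlap
#'
#' Overall agreement fraction plus, for each subtype k, the 2x2 table of
#' (metastasis assigned k or not) x (primary assigned k or not) with a
#' one-sided Fisher's exact enrichment p.
#'
#' @param metLabels Subtype label per metastasis (named by met sample id
#'   or aligned with \code{pairs}).
#' @param primaryLabels Subtype label per primary.
#' @param pairs data.frame with columns \code{met_id}, \code{primary_id}.
#' @return List with \code{agreement}, \code{nPairs} and \code{overlap}
#'   data.frame (subtype, four 2x2 counts, odds, p).
#' @export
pairedConcordance <- function(metLabels, primaryLabels, pairs) {
  pairs <- as.data.frame(pairs)
  m <- if (!is.null(names(metLabels))) metLabels[pairs$met_id] else metLabels
  p <- if (!is.null(names(primaryLabels)))
    primaryLabels[pairs$primary_id] else primaryLabels
  if (anyNA(m) || anyNA(p))
    stop("every pair must have both labels")
  subs <- sort(unique(c(m, p)))
  n <- length(m)
  overlap <- do.call(rbind, lapply(subs, function(k) {
    a <- sum(m == k & p == k); b <- sum(m == k & p != k)
    cc <- sum(m != k & p == k); d <- n - a - b - cc
    et <- enrichmentTest(a, b, cc, d, method = "fisher")
    data.frame(subtype = k, met_and_primary = a, met_only = b,
               primary_only = cc, neither = d, odds = et$odds, p = et$p)
  }))
  list(agreement = mean(m == p), nPairs = n, overlap = overlap)
}
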
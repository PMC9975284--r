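# Copy-number ploidy correction, gain/loss calling, CNA burden, and
# per-gene copy-gain / mutation enrichment by subtype.

#' Ploidy-correct a gene copy matrix
#'
#' Per sample, every gene copy value is divided by the median copy value
#' across genes and multiplied by 2, so the post-correction per-sample
#' median is 2 (diploid baseline). Idempotent.
#'
#' @param copies Gene x sample non-negative copy matrix.
#' @return Corrected (possibly non-integer) matrix.
#' @export
ploidyCorrect <- function(copies) {
  copies <- as.matrix(copies)
  med <- apply(copies, 2, stats::median, na.rm = TRUE)
  if (any(med == 0, na.rm = TRUE))
    stop("per-sample median copy of 0 for sample(s): ",
         paste(utils::head(colnames(copies)[which(med == 0)]),
               collapse = ", "))
  sweep(copies, 2, med / 2, "/")
}

#' Call copy loss / neutral / gain / amplification
#'
#' Thresholds on (possibly ploidy-corrected, unrounded) copy values:
#' loss below 2, neutral in \[2, 3), gain in \[3, 5\], amplification
#' above 5.
#'
#' @param values Gene x sample non-negative copy matrix.
#' @return Character matrix of calls.
#' @export
callGainLoss <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("copy values must be >= 0")
  calls <- matrix(NA_character_, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  calls[values < 2] <- "loss"
  calls[values >= 2 & values < 3] <- "neutral"
  calls[values >= 3 & values <= 5] <- "gain"
  calls[values > 5] <- "amplification"
  calls
}

#' Per-sample CNA burden index
#'
#' Raw burden is the SD of copy values across genes for each sample;
#' centered burden re-expresses it in SD-from-median units across the
#' samples of each dataset (degenerate spread yields 0).
#'
#' @param copies Gene x sample copy matrix (at least two genes).
#' @param dataset Dataset id per sample (single id recycled).
#' @return data.frame with sample_id, dataset, raw, centered.
#' @export
cnaBurden <- function(copies, dataset = "dataset1") {
  copies <- as.matrix(copies)
  if (nrow(copies) < 2) stop("need >= 2 genes")
  dataset <- rep_len(dataset, ncol(copies))
  raw <- apply(copies, 2, stats::sd, na.rm = TRUE)
  centered <- raw
  for (d in unique(dataset)) {
    i <- dataset == d
    s <- stats::sd(raw[i], na.rm = TRUE)
    centered[i] <- if (is.na(s) || s == 0) 0 else
      (raw[i] - stats::median(raw[i], na.rm = TRUE)) / s
  }
  data.frame(sample_id = colnames(copies), dataset = dataset,
             raw = unname(raw), centered = unname(centered))
}

# Shared engine for binary event-by-subtype enrichment.
eventEnrichment <- function(events, labels, method) {
  labels <- alignLabels(labels, colnames(events))
  subs <- sort(unique(labels))
  if (length(subs) < 2) stop("need >= 2 subtypes")
  out <- lapply(subs, function(k) {
    inK <- labels == k
    a <- rowSums(events[, inK, drop = FALSE], na.rm = TRUE)
    b <- rowSums(events[, !inK, drop = FALSE], na.rm = TRUE)
    nIn <- rowSums(!is.na(events[, inK, drop = FALSE]))
    nOut <- rowSums(!is.na(events[, !inK, drop = FALSE]))
    et <- enrichmentTest(a, b, nIn - a, nOut - b, method = method)
    data.frame(gene = rownames(events), subtype = k,
               event_in = a, event_out = b,
               n_in = nIn, n_out = nOut,
               odds = et$odds, p = et$p, method = et$method)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-gene copy-gain enrichment by subtype
#'
#' For each (gene, subtype), builds the 2x2 table of gain (gain or
#' amplification call) versus not, in-subtype versus rest, and computes
#' the one-sided enrichment p with the module-wide Fisher/chi-square
#' switch (see [enrichmentTest()]).
#'
#' @param calls Gene x sample call matrix from [callGainLoss()].
#' @param labels Subtype label per sample.
#' @param method Passed to [enrichmentTest()].
#' @return data.frame with gene, subtype, counts, odds, p, method.
#' @export
gainEnrichmentBySubtype <- function(calls, labels,
                                    method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  gained <- matrix(as.integer(calls %in% c("gain", "amplification")),
                   nrow(calls), ncol(calls), dimnames = dimnames(calls))
  gained[is.na(calls)] <- NA_integer_
  eventEnrichment(gained, labels, method)
}

#' Per-gene mutation enrichment by subtype
#'
#' As [gainEnrichmentBySubtype()] with a binary mutation table, optionally
#' restricted to a gene panel.
#'
#' @param mutations Binary gene x sample matrix.
#' @param labels Subtype label per sample.
#' @param panel Optional gene panel to restrict to.
#' @param method Passed to [enrichmentTest()].
#' @return data.frame with gene, subtype, counts, odds, p, method.
#' @export
mutationEnrichmentBySubtype <- function(mutations, labels, panel = NULL,
                                        method = c("auto", "fisher",
                                                   "chisq")) {
  method <- match.arg(method)
  mutations <- as.matrix(mutations)
  if (!is.null(panel))
    mutations <- mutations[intersect(panel, rownames(mutations)), ,
                           drop = FALSE]
  eventEnrichment(mutations, labels, method)
}
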
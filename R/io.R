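# Plain-text interchange: gene x sample TSV matrices, GMT gene sets, and
# subtype-model serialization (TSV table + JSON header).

#' Read a gene x sample TSV matrix
#'
#' First column gene ids, header of sample ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
readMatrixTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write a gene x sample TSV matrix
#'
#' @param x Matrix with dimnames.
#' @param path File path.
#' @param idColumn Name of the first (gene id) column.
#' @export
writeMatrixTSV <- function(x, path, idColumn = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1] <- idColumn
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of gene id character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene id vectors.
#' @param path Output path.
#' @param descriptions Optional second-column descriptions (defaults to
#'   the set names).
#' @export
writeGMT <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a SubtypeModel to TSV + JSON header
#'
#' Writes a long table (gene, subtype, rank, weight) and a small JSON
#' header (K, labels, nTop) next to it.
#'
#' @param model A [SubtypeModel-class].
#' @param path TSV path; the header goes to \code{<path>.json}.
#' @export
writeSubtypeModel <- function(model, path) {
  rows <- do.call(rbind, lapply(subtypeLabels(model), function(k) {
    g <- topGeneLists(model)[[k]]
    data.frame(gene = g, subtype = k, rank = seq_along(g), weight = 1)
  }))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  header <- list(K = nSubtypes(model), labels = subtypeLabels(model),
                 nTop = model@nTop)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a SubtypeModel written by [writeSubtypeModel()]
#'
#' @param path TSV path (expects \code{<path>.json} alongside).
#' @return A [SubtypeModel-class].
#' @export
readSubtypeModel <- function(path) {
  rows <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  header <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  lists <- lapply(header$labels, function(k) {
    r <- rows[rows$subtype == k, , drop = FALSE]
    r$gene[order(r$rank)]
  })
  names(lists) <- header$labels
  buildSubtypeModel(lists, nTop = as.integer(header$nTop))
}

#' Write sample annotations as TSV
#'
#' @param annotations data.frame of sample annotations.
#' @param path Output path.
#' @export
writeAnnotationsTSV <- function(annotations, path) {
  data.table::fwrite(annotations, path, sep = "\t", quote = FALSE)
  invisible(path)
}
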
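## BEELINE-dialect readers/writers. ExpressionData.csv: header row of cell
## ids, first column gene ids. Network CSV: header Gene1,Gene2 or TF,Target.
## Ranked predictions: TSV TF/Target/Score sorted by descending score.

#' Read a BEELINE-style expression matrix
#'
#' Parses a CSV whose first row is a header of cell identifiers and whose
#' first column holds gene identifiers; remaining cells are expression
#' values. Rows are returned in file order.
#'
#' @param path path to the CSV file.
#' @return numeric matrix, genes in rows (rownames = gene ids), cells in
#'   columns (colnames = cell ids).
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("gene,c1,c2", "G1,0,1.5", "G2,2,0"), tmp)
#' readExpression(tmp)
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nc <- length(fields[[1L]])
  ragged <- which(vapply(fields, length, 1L) != nc)
  if (length(ragged)) {
    stop(sprintf("ragged row in %s at line %d (expected %d fields)",
                 path, ragged[1L], nc))
  }
  cellIds <- fields[[1L]][-1L]
  body <- fields[-1L]
  geneIdsRaw <- vapply(body, `[[`, "", 1L)
  dup <- unique(geneIdsRaw[duplicated(tolower(geneIdsRaw))])
  if (length(dup)) {
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = nc - 1L)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in %s at row %d (gene %s), column %d",
                   path, i + 1L, geneIdsRaw[i], bad[1L] + 1L))
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(geneIdsRaw, cellIds)
  vals
}

#' Read a prior regulatory network edge list
#'
#' Accepts a two-column CSV with header \code{Gene1,Gene2} or
#' \code{TF,Target} (case-insensitive). Duplicate edges (case-insensitive)
#' and self-edges are dropped with a message reporting the counts;
#' self-pairs are never scored by the model, so they carry no supervision.
#'
#' @param path path to the CSV file.
#' @param sourceLabel free-text provenance recorded on the result.
#' @return data.frame with character columns \code{tf}, \code{target}, in
#'   file order after filtering; attribute \code{sourceLabel}.
#' @export
readNetwork <- function(path, sourceLabel = "unspecified") {
  if (!file.exists(path)) stop("network file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  hdr <- tolower(names(df))
  if (!(identical(hdr[1:2], c("gene1", "gene2")) || identical(hdr[1:2], c("tf", "target")))) {
    stop("network header must be Gene1,Gene2 or TF,Target; got: ",
         paste(names(df), collapse = ","))
  }
  if (!nrow(df)) stop("network file has no edges: ", path)
  tf <- df[[1L]]; tg <- df[[2L]]
  self <- tolower(tf) == tolower(tg)
  if (any(self)) message(sum(self), " self-edge(s) dropped from ", basename(path))
  tf <- tf[!self]; tg <- tg[!self]
  key <- paste(tolower(tf), tolower(tg))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) dropped from ", basename(path))
  out <- data.frame(tf = tf[!dup], target = tg[!dup], stringsAsFactors = FALSE)
  if (!nrow(out)) stop("network is empty after dropping self-edges/duplicates: ", path)
  attr(out, "sourceLabel") <- sourceLabel
  out
}

#' Read a transcription-factor list
#'
#' One identifier per line, or a single-column CSV with optional header
#' \code{TF}. Duplicates (case-insensitive) are dropped with a message;
#' original case of first occurrence is preserved.
#'
#' @param path path to the file.
#' @return character vector of unique TF ids.
#' @export
readTFList <- function(path) {
  if (!file.exists(path)) stop("TF list not found: ", path)
  x <- readLines(path)
  x <- trimws(sub(",.*$", "", x))  # tolerate a stray index column
  x <- x[nzchar(x)]
  if (length(x) && tolower(x[1L]) == "tf") x <- x[-1L]
  if (!length(x)) stop("TF list is empty: ", path)
  dup <- duplicated(tolower(x))
  if (any(dup)) message(sum(dup), " duplicate TF id(s) dropped from ", basename(path))
  x[!dup]
}

#' Assemble a GRNData object from its three parts
#'
#' Harmonizes identifiers across expression, network and TF list
#' (case-insensitive matching; expression-file case wins) and drops
#' network edges or TFs whose gene has no expression row, with a message.
#'
#' @param expression numeric matrix from [readExpression()] (or equivalent).
#' @param network data.frame from [readNetwork()].
#' @param tfs character vector from [readTFList()].
#' @param sourceLabel provenance label; defaults to the network attribute.
#' @return a [GRNData-class] object.
#' @export
grnData <- function(expression, network, tfs,
                    sourceLabel = attr(network, "sourceLabel") %||% "unspecified") {
  ids <- rownames(expression)
  lut <- setNames(ids, tolower(ids))
  canon <- function(x) unname(lut[tolower(x)])
  tfC <- canon(tfs)
  if (anyNA(tfC)) {
    message(sum(is.na(tfC)), " TF id(s) absent from expression dropped")
    tfC <- tfC[!is.na(tfC)]
  }
  if (!length(tfC)) stop("no TF has an expression row")
  nt <- canon(network$tf); ng <- canon(network$target)
  keep <- !is.na(nt) & !is.na(ng)
  if (any(!keep)) {
    message(sum(!keep), " network edge(s) with genes absent from expression dropped")
  }
  nw <- data.frame(tf = nt[keep], target = ng[keep], stringsAsFactors = FALSE)
  if (!nrow(nw)) stop("no network edge survives gene filtering")
  new("GRNData", expression = expression, network = nw, tfs = tfC,
      sourceLabel = sourceLabel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ranked edge predictions
#'
#' Emits a TSV with header \code{TF\\tTarget\\tScore}, sorted by
#' descending score with ties broken lexicographically by (TF, Target) so
#' output is byte-stable across runs.
#'
#' @param predictions data.frame with columns \code{tf}, \code{target},
#'   \code{score} (finite).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRankedEdges <- function(predictions, path) {
  stopifnot(all(c("tf", "target", "score") %in% names(predictions)))
  if (nrow(predictions) && !all(is.finite(predictions$score))) {
    stop("prediction scores must be finite")
  }
  ord <- order(-predictions$score, predictions$tf, predictions$target,
               method = "radix")
  out <- predictions[ord, c("tf", "target", "score")]
  names(out) <- c("TF", "Target", "Score")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("TF\tTarget\tScore", con)
  if (nrow(out)) {
    writeLines(paste(out$TF, out$Target,
                     formatC(out$Score, format = "g", digits = 17), sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a ranked edge file
#'
#' Inverse of [writeRankedEdges()]; used for round-trips and downstream
#' diagnostics on saved predictions.
#'
#' @param path path to the TSV.
#' @return data.frame with columns \code{tf}, \code{target}, \code{score}.
#' @export
readRankedEdges <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("TF", "Target", "Score") %in% names(df))) {
    stop("ranked edge file needs TF/Target/Score columns: ", path)
  }
  data.frame(tf = as.character(df$TF), target = as.character(df$Target),
             score = as.numeric(df$Score), stringsAsFactors = FALSE)
}
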
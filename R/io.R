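# Readers and writers for the plain-text interchange formats: PSM tables,
# channel designs, gene sets (GMT), flat gene lists, result tables, and a
# YAML run configuration.

.mandatory_psm_cols <- c("experiment", "peptide", "protein", "gene",
                         "confidence", "is_decoy", "is_contaminant")

#' Normalize gene symbols to the mouse convention
#'
#' First letter capitalized, the rest lower case (so \code{"LY6H"},
#' \code{"ly6h"} and \code{"Ly6h"} agree before any set operation). Mixed
#' UniProt entry names and mouse symbols are common in published tables;
#' normalizing once up front keeps overlap and enrichment arithmetic honest.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @examples normalizeGeneSymbols(c("LY6H", "plp1"))
#' @export
normalizeGeneSymbols <- function(x) {
  x <- trimws(as.character(x))
  has <- nchar(x) > 0
  x[has] <- paste0(toupper(substr(x[has], 1L, 1L)),
                   tolower(substring(x[has], 2L)))
  x
}

#' Read a PSM table
#'
#' Tab-separated, one row per PSM, with the mandatory columns
#' \code{experiment}, \code{peptide}, \code{protein}, \code{gene},
#' \code{confidence}, \code{is_decoy}, \code{is_contaminant} plus one
#' intensity column per reporter channel (named like \code{i113}). Empty
#' cells and the literal \code{NA} in intensity columns are parsed as
#' missing reporter peaks, never as zero.
#'
#' @param path file path.
#' @return A \linkS4class{PSMSet}.
#' @export
readPSMTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), check.names = FALSE)
  absent <- setdiff(.mandatory_psm_cols, names(d))
  if (length(absent))
    stop("PSM table format error: missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  channels <- grep("^i[0-9]+$", names(d), value = TRUE)
  if (!length(channels))
    stop("PSM table format error: no reporter channel columns (i<number>)",
         call. = FALSE)
  for (ch in channels) {
    bad <- which(!is.na(d[[ch]]) & d[[ch]] < 0)
    if (length(bad))
      stop(sprintf("PSM table validation error: negative intensity in %s at data row %d",
                   ch, bad[1L]), call. = FALSE)
  }
  psmSet(d, channels)
}

#' Write a PSM table
#'
#' Missing reporter peaks are written as literal \code{NA} cells;
#' \code{readPSMTable(writePSMTable(x))} round-trips value-identically.
#'
#' @param x a \linkS4class{PSMSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePSMTable <- function(x, path) {
  stopifnot(is(x, "PSMSet"))
  utils::write.table(psmData(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a channel design table
#'
#' TSV with columns \code{experiment}, \code{channel}, \code{condition}.
#'
#' @param path file path.
#' @param numerator,denominator condition labels defining the reported
#'   ratio.
#' @return A \linkS4class{ChannelDesign}.
#' @export
readChannelDesign <- function(path, numerator = "KO", denominator = "WT") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  channelDesign(d, numerator, denominator)
}

#' Write a channel design table
#' @param x a \linkS4class{ChannelDesign}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeChannelDesign <- function(x, path) {
  utils::write.table(designTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one term per line, tab-separated
#' \code{term_id <tab> description <tab> gene1 <tab> ...}. A description of
#' the form \code{"BP|synaptic transmission"} carries the namespace (BP, CC
#' or MF); otherwise the namespace is \code{"other"}. Genes outside the
#' supplied universe are dropped with a message stating the count, and
#' terms left empty are removed.
#'
#' @param path GMT file path.
#' @param universe background gene symbols; defaults to the union of all
#'   genes named in the file.
#' @return A \linkS4class{GeneSetDb}.
#' @export
readGeneSets <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    uni <- normalizeGeneSymbols(if (is.null(universe)) character() else universe)
    return(geneSetDb(character(), character(), character(), list(), uni))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT format error: fewer than 3 fields at line %d", short[1L]),
         call. = FALSE)
  term_id <- vapply(fields, `[[`, character(1L), 1L)
  descr <- vapply(fields, `[[`, character(1L), 2L)
  genes <- lapply(fields, function(f) unique(normalizeGeneSymbols(f[-(1:2)])))
  ns <- ifelse(grepl("^(BP|CC|MF)\\|", descr), sub("\\|.*$", "", descr), "other")
  name <- sub("^(BP|CC|MF)\\|", "", descr)
  uni <- if (is.null(universe)) unique(unlist(genes))
         else unique(normalizeGeneSymbols(universe))
  n_before <- sum(lengths(genes))
  genes <- lapply(genes, intersect, y = uni)
  n_drop <- n_before - sum(lengths(genes))
  if (n_drop > 0)
    message(n_drop, " gene annotation(s) outside the universe dropped")
  keep <- lengths(genes) > 0L
  if (any(!keep))
    message(sum(!keep), " empty term(s) removed")
  geneSetDb(term_id[keep], ns[keep], name[keep], genes[keep], uni)
}

#' Read a flat gene list
#'
#' One symbol per line; blank lines and lines starting with \code{#} are
#' ignored; symbols are case-normalized.
#'
#' @param path file path.
#' @return character vector of unique normalized gene symbols, in file
#'   order.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalizeGeneSymbols(x))
}

#' Write a results table
#'
#' Tab-separated with a header, stable column order, literal \code{NA} for
#' missing fields, and p-values (any column whose name starts with
#' \code{p}) at full precision (at least 6 significant digits).
#'
#' @param rows a data.frame of results sharing one schema.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 10, format = "g"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table
#'
#' Inverse of \code{\link{writeResultsTable}}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readResultsTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read a YAML pipeline configuration
#'
#' Recognized keys match the arguments of \code{\link{pipelineConfig}};
#' unknown keys raise an error rather than being silently ignored.
#'
#' @param path YAML file path.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, vals)
}
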
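# Accessors and show methods for the core classes.

#' PSM data accessor
#' @param object a \linkS4class{PSMSet}.
#' @return data.frame of PSM records.
#' @export
setGeneric("psmData", function(object) standardGeneric("psmData"))

#' @rdname psmData
#' @export
setMethod("psmData", "PSMSet", function(object) object@psm)

#' Reporter channel names
#' @param object a \linkS4class{PSMSet} or \linkS4class{ChannelDesign}.
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "PSMSet", function(object) object@channels)

#' @rdname channelNames
#' @export
setMethod("channelNames", "ChannelDesign",
          function(object) unique(object@design$channel))

#' Design table and ratio-orientation accessors
#' @param object a \linkS4class{ChannelDesign}.
#' @return \code{designTable}: the long design data.frame;
#'   \code{numeratorCondition}/\code{denominatorCondition}: condition labels.
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname designTable
#' @export
setMethod("designTable", "ChannelDesign", function(object) object@design)

#' @rdname designTable
#' @export
setGeneric("numeratorCondition",
           function(object) standardGeneric("numeratorCondition"))

#' @rdname designTable
#' @export
setMethod("numeratorCondition", "ChannelDesign",
          function(object) object@numerator)

#' @rdname designTable
#' @export
setGeneric("denominatorCondition",
           function(object) standardGeneric("denominatorCondition"))

#' @rdname designTable
#' @export
setMethod("denominatorCondition", "ChannelDesign",
          function(object) object@denominator)

#' Look up the channel carrying a condition in one experiment
#'
#' @param design a \linkS4class{ChannelDesign}.
#' @param experiment experiment identifier.
#' @param condition condition label.
#' @return channel label (length-1 character).
#' @export
channelFor <- function(design, experiment, condition) {
  d <- designTable(design)
  hit <- d$channel[d$experiment == experiment & d$condition == condition]
  if (length(hit) != 1L)
    stop(sprintf("no unique channel for condition '%s' in experiment '%s'",
                 condition, experiment), call. = FALSE)
  hit
}

#' Swap numerator and denominator conditions of a design
#'
#' Useful for label-swap symmetry checks: every downstream ratio inverts.
#'
#' @param design a \linkS4class{ChannelDesign}.
#' @return a \linkS4class{ChannelDesign} with the ratio orientation flipped.
#' @export
swapDesign <- function(design) {
  channelDesign(designTable(design),
                numerator = denominatorCondition(design),
                denominator = numeratorCondition(design))
}

#' Gene-set accessors
#' @param object a \linkS4class{GeneSetDb}.
#' @return \code{geneSets}: named list of gene vectors; \code{setUniverse}:
#'   the background gene vector; \code{setNamespaces}: named namespace
#'   vector.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname geneSets
#' @export
setMethod("geneSets", "GeneSetDb", function(object) {
  stats::setNames(object@genes, object@term_id)
})

#' @rdname geneSets
#' @export
setGeneric("setUniverse", function(object) standardGeneric("setUniverse"))

#' @rdname geneSets
#' @export
setMethod("setUniverse", "GeneSetDb", function(object) object@universe)

#' @rdname geneSets
#' @export
setGeneric("setNamespaces", function(object) standardGeneric("setNamespaces"))

#' @rdname geneSets
#' @export
setMethod("setNamespaces", "GeneSetDb", function(object) {
  stats::setNames(object@namespace, object@term_id)
})

#' Differential-result accessors
#' @param object a \linkS4class{DifferentialResults}.
#' @return \code{resultsTable}: per-protein results data.frame;
#'   \code{referenceStats}: list(gene, mean, sd, n);
#'   \code{significantGenes}: genes called at the stored alpha.
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @rdname resultsTable
#' @export
setMethod("resultsTable", "DifferentialResults", function(object) object@table)

#' @rdname resultsTable
#' @export
setGeneric("referenceStats", function(object) standardGeneric("referenceStats"))

#' @rdname resultsTable
#' @export
setMethod("referenceStats", "DifferentialResults",
          function(object) object@reference)

#' @rdname resultsTable
#' @export
setGeneric("significantGenes",
           function(object) standardGeneric("significantGenes"))

#' @rdname resultsTable
#' @export
setMethod("significantGenes", "DifferentialResults", function(object) {
  object@table$gene[object@table$significant]
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "PSMSet", function(object) {
  d <- object@psm
  cat("PSMSet with", nrow(d), "records across",
      length(unique(d$experiment)), "experiment(s)\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  if (nrow(d))
    cat("  decoys:", sum(d$is_decoy),
        " contaminants:", sum(d$is_contaminant), "\n")
})

setMethod("show", "ChannelDesign", function(object) {
  cat("ChannelDesign:", object@numerator, "/", object@denominator,
      "over", length(unique(object@design$experiment)), "experiment(s)\n")
  print(object@design, row.names = FALSE)
})

setMethod("show", "GeneSetDb", function(object) {
  cat("GeneSetDb with", length(object@term_id), "term(s) over a universe of",
      length(object@universe), "genes\n")
  if (length(object@term_id))
    print(table(object@namespace))
})

setMethod("show", "DifferentialResults", function(object) {
  d <- object@table
  cat("DifferentialResults:", nrow(d), "protein(s) tested against reference",
      object@reference$gene, sprintf("(%.2f +/- %.3f, n = %d)\n",
      object@reference$mean, object@reference$sd, object@reference$n))
  cat(sprintf("  %d significant at alpha = %g (%d decreased, %d increased)\n",
              sum(d$significant), object@alpha,
              sum(d$significant & d$direction == "decreased"),
              sum(d$significant & d$direction == "increased")))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(paste0("SimParams: %d proteins x %d experiments, %g-%g PSMs/",
                     "protein, sigma_p = %g, sigma_e = %g, seed = %d\n"),
              object@n_proteins, object@n_experiments,
              object@peptides_per_protein[1L], object@peptides_per_protein[2L],
              object@sigma_p, object@sigma_e, as.integer(object@seed)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(paste0("PipelineConfig: confidence > %g%%, alpha = %g, ",
                     "reference = %s, fdr = %s, scale = %s\n"),
              object@confidence_threshold, object@alpha,
              object@reference_gene, object@fdr_method, object@test_scale))
})
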
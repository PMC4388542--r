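#' @import methods
NULL

# ---- ChannelDesign ----------------------------------------------------------

#' Channel-to-condition design for 2-plex reporter-ion experiments
#'
#' Maps each reporter channel (e.g. \code{i113}, \code{i114}) to a biological
#' condition (e.g. \code{"KO"}, \code{"WT"}) per experiment, and fixes which
#' condition is the numerator and which the denominator of every reported
#' ratio. Which physical channel carried which genotype is a free choice of
#' the experimental design, so it is always stated explicitly here.
#'
#' @slot design data.frame with columns \code{experiment}, \code{channel},
#'   \code{condition}; exactly one channel per condition per experiment.
#' @slot numerator single condition label (ratio numerator, e.g. "KO").
#' @slot denominator single condition label (ratio denominator, e.g. "WT").
#' @export
setClass("ChannelDesign",
  representation(design = "data.frame",
                 numerator = "character",
                 denominator = "character"))

setValidity("ChannelDesign", function(object) {
  d <- object@design
  msgs <- character()
  need <- c("experiment", "channel", "condition")
  if (!all(need %in% names(d)))
    return(paste("design must have columns", paste(need, collapse = ", ")))
  if (length(object@numerator) != 1L || length(object@denominator) != 1L)
    msgs <- c(msgs, "numerator and denominator must be single labels")
  if (identical(object@numerator, object@denominator))
    msgs <- c(msgs, "numerator and denominator conditions must differ")
  dup <- duplicated(d[, c("experiment", "condition")])
  if (any(dup))
    msgs <- c(msgs, "exactly one channel per condition per experiment")
  for (cond in c(object@numerator, object@denominator)) {
    miss <- setdiff(unique(d$experiment),
                    d$experiment[d$condition == cond])
    if (length(miss))
      msgs <- c(msgs, sprintf("condition '%s' missing for experiment(s): %s",
                              cond, paste(miss, collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a ChannelDesign
#'
#' @param design data.frame with columns \code{experiment}, \code{channel},
#'   \code{condition}.
#' @param numerator,denominator condition labels defining the reported ratio
#'   (numerator/denominator).
#' @return A \linkS4class{ChannelDesign}.
#' @examples
#' channelDesign(data.frame(experiment = "E1",
#'                          channel = c("i113", "i114"),
#'                          condition = c("WT", "KO")))
#' @export
channelDesign <- function(design, numerator = "KO", denominator = "WT") {
  design$experiment <- as.character(design$experiment)
  design$channel <- as.character(design$channel)
  design$condition <- as.character(design$condition)
  new("ChannelDesign", design = design,
      numerator = as.character(numerator),
      denominator = as.character(denominator))
}

# ---- PSMSet -----------------------------------------------------------------

#' A set of peptide-spectrum matches with reporter-ion intensities
#'
#' One row per PSM. Reporter intensities live in one numeric column per
#' channel; a missing reporter peak is \code{NA}, which is deliberately
#' distinct from an intensity of 0 (a recorded zero peak).
#'
#' @slot psm data.frame with columns \code{experiment}, \code{peptide},
#'   \code{protein}, \code{gene}, \code{confidence} (percent in [0, 100]),
#'   one numeric column per reporter channel, \code{is_decoy},
#'   \code{is_contaminant}.
#' @slot channels character vector naming the reporter-intensity columns.
#' @export
setClass("PSMSet",
  representation(psm = "data.frame", channels = "character"))

setValidity("PSMSet", function(object) {
  d <- object@psm
  msgs <- character()
  need <- c("experiment", "peptide", "protein", "gene", "confidence",
            "is_decoy", "is_contaminant")
  absent <- setdiff(need, names(d))
  if (length(absent))
    return(paste("missing mandatory column(s):", paste(absent, collapse = ", ")))
  if (length(object@channels) < 1L)
    msgs <- c(msgs, "at least one reporter channel column is required")
  absent <- setdiff(object@channels, names(d))
  if (length(absent))
    msgs <- c(msgs, paste("channel column(s) absent:", paste(absent, collapse = ", ")))
  if (nrow(d)) {
    if (any(is.na(d$confidence)) || any(d$confidence < 0 | d$confidence > 100))
      msgs <- c(msgs, "confidence must lie in [0, 100]")
    for (ch in intersect(object@channels, names(d))) {
      bad <- which(!is.na(d[[ch]]) & d[[ch]] < 0)
      if (length(bad))
        msgs <- c(msgs, sprintf("negative intensity in column %s at row %d",
                                ch, bad[1L]))
    }
    shared <- intersect(d$gene[d$is_decoy], d$gene[!d$is_decoy])
    if (length(shared))
      msgs <- c(msgs, paste("decoy records share gene symbol(s) with targets:",
                            paste(utils::head(shared, 3L), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a PSMSet
#'
#' @param psm data.frame of PSMs (see \linkS4class{PSMSet} for columns).
#' @param channels names of the reporter-intensity columns; by default all
#'   columns matching \code{^i[0-9]+$}.
#' @return A \linkS4class{PSMSet}.
#' @export
psmSet <- function(psm, channels = grep("^i[0-9]+$", names(psm), value = TRUE)) {
  for (col in c("experiment", "peptide", "protein", "gene"))
    if (col %in% names(psm)) psm[[col]] <- as.character(psm[[col]])
  if ("is_decoy" %in% names(psm)) psm$is_decoy <- as.logical(psm$is_decoy)
  if ("is_contaminant" %in% names(psm))
    psm$is_contaminant <- as.logical(psm$is_contaminant)
  rownames(psm) <- NULL
  new("PSMSet", psm = psm, channels = channels)
}

# ---- GeneSetDb --------------------------------------------------------------

#' A collection of gene sets over a fixed gene universe
#'
#' @slot term_id character vector of unique term identifiers.
#' @slot namespace per-term namespace, one of "BP", "CC", "MF", "other".
#' @slot term_name per-term human-readable name.
#' @slot genes list of character vectors (gene symbols), parallel to
#'   \code{term_id}; always a subset of \code{universe}.
#' @slot universe background gene symbols (the population for enrichment).
#' @export
setClass("GeneSetDb",
  representation(term_id = "character", namespace = "character",
                 term_name = "character", genes = "list",
                 universe = "character"))

setValidity("GeneSetDb", function(object) {
  msgs <- character()
  n <- length(object@term_id)
  if (anyDuplicated(object@term_id))
    msgs <- c(msgs, "term ids must be unique")
  if (length(object@namespace) != n || length(object@term_name) != n ||
      length(object@genes) != n)
    msgs <- c(msgs, "term_id, namespace, term_name and genes must be parallel")
  if (n && !all(object@namespace %in% c("BP", "CC", "MF", "other")))
    msgs <- c(msgs, "namespace must be one of BP, CC, MF, other")
  out <- setdiff(unlist(object@genes), object@universe)
  if (length(out))
    msgs <- c(msgs, paste("term genes outside universe:",
                          paste(utils::head(out, 3L), collapse = ", ")))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GeneSetDb
#'
#' @param term_id,namespace,term_name parallel per-term vectors.
#' @param genes list of gene-symbol vectors, parallel to \code{term_id}.
#' @param universe background gene universe.
#' @return A \linkS4class{GeneSetDb}.
#' @export
geneSetDb <- function(term_id, namespace, term_name, genes, universe) {
  new("GeneSetDb",
      term_id = as.character(term_id),
      namespace = as.character(namespace),
      term_name = as.character(term_name),
      genes = lapply(genes, function(g) normalizeGeneSymbols(as.character(g))),
      universe = normalizeGeneSymbols(as.character(universe)))
}

# ---- PipelineConfig ---------------------------------------------------------

#' Pipeline configuration
#'
#' @slot confidence_threshold PSM confidence cutoff in percent; strictly
#'   greater-than is applied (a PSM at exactly the threshold is rejected).
#' @slot alpha significance level for differential calls.
#' @slot min_experiments number of experiments a protein must be quantified
#'   in to enter the combined analysis; \code{NA} means "all experiments
#'   present in the data".
#' @slot reference_gene gene symbol of the internal reference protein, or
#'   \code{"AUTO"} to pick the quantified gene whose mean ratio is closest
#'   to 1 (ties: smallest sd, then lexicographic).
#' @slot contaminant_genes gene symbols treated as contaminants (keratins by
#'   default) in addition to per-record flags.
#' @slot fdr_method \code{"decoy_over_target"} (D/T) or
#'   \code{"combined"} (2D/(T+D)).
#' @slot test_scale \code{"ratio"} (t-test on raw per-experiment ratios) or
#'   \code{"log"} (on log ratios).
#' @slot var_equal pooled-variance (Student) t-test when TRUE, Welch otherwise.
#' @slot seed integer seed for any stochastic stage.
#' @export
setClass("PipelineConfig",
  representation(confidence_threshold = "numeric", alpha = "numeric",
                 min_experiments = "numeric", reference_gene = "character",
                 contaminant_genes = "character", fdr_method = "character",
                 test_scale = "character", var_equal = "logical",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msgs <- c(msgs, "alpha must lie strictly between 0 and 1")
  if (!is.na(object@min_experiments) && object@min_experiments < 1)
    msgs <- c(msgs, "min_experiments must be >= 1")
  if (object@confidence_threshold < 0 || object@confidence_threshold > 100)
    msgs <- c(msgs, "confidence_threshold must lie in [0, 100]")
  if (!object@fdr_method %in% c("decoy_over_target", "combined"))
    msgs <- c(msgs, "fdr_method must be 'decoy_over_target' or 'combined'")
  if (!object@test_scale %in% c("ratio", "log"))
    msgs <- c(msgs, "test_scale must be 'ratio' or 'log'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a PipelineConfig
#'
#' @param confidence_threshold percent; PSMs must exceed it strictly.
#' @param alpha significance level.
#' @param min_experiments required number of experiments with a valid ratio
#'   (NA = all).
#' @param reference_gene internal reference gene symbol or "AUTO".
#' @param contaminant_genes contaminant gene symbols (keratin family default).
#' @param fdr_method decoy FDR formula.
#' @param test_scale scale of the differential t-test.
#' @param var_equal use the pooled-variance t-test (default) or Welch.
#' @param seed integer seed.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(confidence_threshold = 95, alpha = 0.05,
                           min_experiments = NA_real_,
                           reference_gene = "AUTO",
                           contaminant_genes = c("Krt1", "Krt2", "Krt5",
                                                 "Krt9", "Krt10", "Krt14"),
                           fdr_method = "decoy_over_target",
                           test_scale = "ratio", var_equal = TRUE,
                           seed = 1L) {
  new("PipelineConfig",
      confidence_threshold = as.numeric(confidence_threshold),
      alpha = as.numeric(alpha),
      min_experiments = as.numeric(min_experiments),
      reference_gene = as.character(reference_gene),
      contaminant_genes = as.character(contaminant_genes),
      fdr_method = fdr_method, test_scale = test_scale,
      var_equal = var_equal, seed = as.numeric(seed))
}

# ---- SimParams --------------------------------------------------------------

#' Parameters of the synthetic 2-plex reporter-ion generator
#'
#' The generator emulates the study design the pipeline assumes: a small
#' series of independent 2-plex experiments, each measuring the same
#' proteins, with two noise tiers on the natural-log scale - a
#' between-experiment (biological) tier \code{sigma_e} applied once per
#' protein and experiment, and a peptide-level (technical) tier
#' \code{sigma_p} applied per PSM.
#'
#' @slot n_proteins number of target proteins.
#' @slot n_experiments number of 2-plex experiments (replicates).
#' @slot peptides_per_protein integer range (min, max) of PSMs per protein
#'   per experiment.
#' @slot true_ratios named numeric vector of true KO/WT fold changes for a
#'   subset of genes; unnamed genes default to 1.
#' @slot sigma_p SD of the natural-log peptide ratio within an experiment.
#' @slot sigma_e SD of the natural-log protein ratio between experiments.
#' @slot base_log_intensity_mean,base_log_intensity_sd natural-log scale of
#'   the denominator reporter intensity.
#' @slot missing_peak_prob probability that any single reporter peak is
#'   absent (independently per channel).
#' @slot subthreshold_prob probability a PSM confidence falls below the
#'   identification threshold.
#' @slot confidence_threshold the threshold the confidence draws straddle.
#' @slot decoy_frac,contaminant_frac fractions of extra decoy / keratin-like
#'   contaminant records appended to each experiment.
#' @slot seed integer seed; the generator is fully deterministic given it.
#' @export
setClass("SimParams",
  representation(n_proteins = "numeric", n_experiments = "numeric",
                 peptides_per_protein = "numeric", true_ratios = "numeric",
                 sigma_p = "numeric", sigma_e = "numeric",
                 base_log_intensity_mean = "numeric",
                 base_log_intensity_sd = "numeric",
                 missing_peak_prob = "numeric", subthreshold_prob = "numeric",
                 confidence_threshold = "numeric",
                 decoy_frac = "numeric", contaminant_frac = "numeric",
                 seed = "numeric"))

setValidity("SimParams", function(object) {
  msgs <- character()
  if (object@n_proteins < 1)
    msgs <- c(msgs, "n_proteins must be >= 1")
  if (object@n_experiments < 1)
    msgs <- c(msgs, "n_experiments must be >= 1")
  pp <- object@peptides_per_protein
  if (length(pp) != 2L || any(pp < 1) || pp[1L] > pp[2L])
    msgs <- c(msgs, "peptides_per_protein must be an increasing pair >= 1")
  if (any(object@true_ratios <= 0))
    msgs <- c(msgs, "true ratios must be > 0")
  if (object@sigma_p < 0 || object@sigma_e < 0 ||
      object@base_log_intensity_sd < 0)
    msgs <- c(msgs, "all SDs must be >= 0")
  probs <- c(object@missing_peak_prob, object@subthreshold_prob,
             object@decoy_frac, object@contaminant_frac)
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "all probabilities/fractions must lie in [0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct simulation parameters
#'
#' Defaults mirror the study conditions the pipeline is built for: three
#' independent 2-plex experiments, a few PSMs per protein per experiment,
#' and two-tier lognormal noise (sigma_p = 0.2 within experiment,
#' sigma_e = 0.1 between experiments) sized so that realistic
#' between-experiment SDs of the protein ratio (roughly 0.02-0.6) are
#' reachable.
#'
#' @param n_proteins,n_experiments,peptides_per_protein see
#'   \linkS4class{SimParams}.
#' @param true_ratios named numeric vector of true fold changes (KO/WT) for
#'   selected genes; all other genes are null (ratio 1).
#' @param sigma_p,sigma_e log-scale noise SDs.
#' @param base_log_intensity_mean,base_log_intensity_sd reporter intensity
#'   scale (natural log).
#' @param missing_peak_prob,subthreshold_prob,decoy_frac,contaminant_frac
#'   data-quality corruption rates.
#' @param confidence_threshold percent threshold the confidence draws
#'   straddle.
#' @param seed integer seed.
#' @return A \linkS4class{SimParams}.
#' @export
simParams <- function(n_proteins = 60, n_experiments = 3,
                      peptides_per_protein = c(3, 6),
                      true_ratios = numeric(),
                      sigma_p = 0.2, sigma_e = 0.1,
                      base_log_intensity_mean = 8,
                      base_log_intensity_sd = 1,
                      missing_peak_prob = 0.05, subthreshold_prob = 0.05,
                      confidence_threshold = 95,
                      decoy_frac = 0.05, contaminant_frac = 0.02,
                      seed = 1L) {
  new("SimParams",
      n_proteins = as.numeric(n_proteins),
      n_experiments = as.numeric(n_experiments),
      peptides_per_protein = as.numeric(peptides_per_protein),
      true_ratios = true_ratios,
      sigma_p = sigma_p, sigma_e = sigma_e,
      base_log_intensity_mean = base_log_intensity_mean,
      base_log_intensity_sd = base_log_intensity_sd,
      missing_peak_prob = missing_peak_prob,
      subthreshold_prob = subthreshold_prob,
      confidence_threshold = confidence_threshold,
      decoy_frac = decoy_frac, contaminant_frac = contaminant_frac,
      seed = as.numeric(seed))
}

# ---- DifferentialResults ----------------------------------------------------

#' Differential-abundance results against an internal reference
#'
#' @slot table data.frame with one row per tested protein: \code{gene},
#'   \code{mean_ratio}, \code{sd_ratio}, \code{n}, \code{t_statistic},
#'   \code{df}, \code{p_value}, \code{p_bh}, \code{significant},
#'   \code{direction}.
#' @slot reference list with the reference protein's \code{gene},
#'   \code{mean}, \code{sd}, \code{n}.
#' @slot alpha the significance level the calls were made at.
#' @export
setClass("DifferentialResults",
  representation(table = "data.frame", reference = "list", alpha = "numeric"))

setValidity("DifferentialResults", function(object) {
  d <- object@table
  need <- c("gene", "mean_ratio", "sd_ratio", "n", "t_statistic", "df",
            "p_value", "p_bh", "significant", "direction")
  absent <- setdiff(need, names(d))
  if (length(absent))
    return(paste("missing column(s):", paste(absent, collapse = ", ")))
  msgs <- character()
  if (nrow(d)) {
    if (any(d$p_value < 0 | d$p_value > 1, na.rm = TRUE))
      msgs <- c(msgs, "p-values must lie in [0, 1]")
    if (!identical(d$significant, d$p_value < object@alpha))
      msgs <- c(msgs, "significant flag must equal p_value < alpha")
    dir_ok <- ifelse(d$mean_ratio > 1, "increased",
                     ifelse(d$mean_ratio < 1, "decreased", "unchanged"))
    if (!identical(d$direction, dir_ok))
      msgs <- c(msgs, "direction must follow the sign of mean_ratio - 1")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
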
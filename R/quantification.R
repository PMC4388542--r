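# Quantification: per-PSM reporter-ion ratios and the peptide-to-protein
# rollup with geometric statistics (log-space mean and sample SD).

#' Per-peptide reporter-ion ratios
#'
#' For each PSM, ratio = intensity(numerator channel) / intensity
#' (denominator channel), using the channel assignment of that record's
#' experiment. A ratio is invalid - never coerced to 0 or dropped silently -
#' when either relevant peak is missing (\code{missing_peak}) or the
#' denominator or numerator intensity is <= 0 (\code{zero_intensity}).
#'
#' @param x a \linkS4class{PSMSet} of filtered PSMs.
#' @param design a \linkS4class{ChannelDesign} covering every experiment in
#'   \code{x}.
#' @return data.frame with columns \code{experiment}, \code{gene},
#'   \code{peptide}, \code{ratio} (NA when invalid), \code{invalid_reason}
#'   (\code{"none"}, \code{"missing_peak"} or \code{"zero_intensity"}).
#' @export
peptideRatios <- function(x, design) {
  stopifnot(is(x, "PSMSet"), is(design, "ChannelDesign"))
  d <- psmData(x)
  exps <- unique(d$experiment)
  dtab <- designTable(design)
  absent <- setdiff(exps, unique(dtab$experiment))
  if (length(absent))
    stop("configuration error: design lacks experiment(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  num <- numeric(nrow(d)); den <- numeric(nrow(d))
  for (e in exps) {
    idx <- d$experiment == e
    ch_n <- channelFor(design, e, numeratorCondition(design))
    ch_d <- channelFor(design, e, denominatorCondition(design))
    for (ch in c(ch_n, ch_d))
      if (!ch %in% channelNames(x))
        stop("configuration error: channel '", ch,
             "' not present in PSM table", call. = FALSE)
    num[idx] <- d[[ch_n]][idx]
    den[idx] <- d[[ch_d]][idx]
  }
  reason <- rep("none", nrow(d))
  reason[!is.na(num) & !is.na(den) & (num <= 0 | den <= 0)] <- "zero_intensity"
  reason[is.na(num) | is.na(den)] <- "missing_peak"
  ratio <- ifelse(reason == "none", num / den, NA_real_)
  data.frame(experiment = d$experiment, gene = d$gene, peptide = d$peptide,
             ratio = ratio, invalid_reason = reason,
             stringsAsFactors = FALSE)
}

#' Roll peptide ratios up to protein-level geometric statistics
#'
#' Per gene and experiment: the geometric mean of the valid peptide ratios,
#' exp(mean(ln r)); the geometric SD, exp(sample SD of ln r), reported only
#' when at least two valid ratios contribute (single-peptide proteins stay
#' quantified with a missing spread); and the counts of quantified vs
#' identified peptides. Proteins with zero valid ratios in an experiment
#' are dropped from that experiment's quantification with a message (they
#' still count as identified there).
#'
#' @param ratios data.frame from \code{\link{peptideRatios}}.
#' @return data.frame with columns \code{experiment}, \code{gene},
#'   \code{gm_ratio}, \code{geometric_sd}, \code{n_peptides_quantified},
#'   \code{n_peptides_identified}, sorted by experiment then gene.
#' @export
rollupProteins <- function(ratios) {
  stopifnot(all(c("experiment", "gene", "ratio") %in% names(ratios)))
  if (!nrow(ratios))
    return(data.frame(experiment = character(), gene = character(),
                      gm_ratio = numeric(), geometric_sd = numeric(),
                      n_peptides_quantified = integer(),
                      n_peptides_identified = integer(),
                      stringsAsFactors = FALSE))
  key <- interaction(ratios$experiment, ratios$gene, drop = TRUE, sep = "\r")
  parts <- split(ratios, key)
  rows <- lapply(parts, function(g) {
    r <- g$ratio[!is.na(g$ratio)]
    lr <- log(r)
    data.frame(experiment = g$experiment[1L], gene = g$gene[1L],
               gm_ratio = if (length(r)) exp(mean(lr)) else NA_real_,
               geometric_sd = if (length(r) >= 2L) exp(stats::sd(lr))
                              else NA_real_,
               n_peptides_quantified = length(r),
               n_peptides_identified = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- out$n_peptides_quantified == 0L
  if (any(dropped))
    message(sum(dropped), " protein-experiment group(s) had no valid ",
            "peptide ratio (all peaks missing/rejected) and carry no ratio")
  out <- out[order(out$experiment, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
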
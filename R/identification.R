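# Identification-stage filtering: strict confidence cutoff, decoy
# accounting, contaminant (keratin) exclusion, and the decoy-based FDR
# summary reported per experiment.

#' Decoy-based FDR percentage
#'
#' FDR = 100 * decoys / targets among above-threshold matches (the
#' decoys-over-targets convention). The symmetrized alternative
#' 2D/(T + D) is available via \code{method = "combined"}. Returns 0 when
#' no decoys matched and \code{NA} when there are no target matches.
#'
#' @param n_decoy number of decoy matches above threshold.
#' @param n_target number of target matches above threshold.
#' @param method \code{"decoy_over_target"} (default) or \code{"combined"}.
#' @return FDR in percent.
#' @examples
#' computeFDR(0, 257)   # 0
#' computeFDR(7, 575)   # 1.217...
#' @export
computeFDR <- function(n_decoy, n_target,
                       method = c("decoy_over_target", "combined")) {
  method <- match.arg(method)
  if (n_decoy < 0 || n_target < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (n_target == 0) return(NA_real_)
  if (n_decoy == 0) return(0)
  switch(method,
         decoy_over_target = 100 * n_decoy / n_target,
         combined = 100 * 2 * n_decoy / (n_target + n_decoy))
}

#' Filter PSMs of one experiment
#'
#' Applies, in order: (1) the strict confidence cutoff - only PSMs with
#' confidence strictly greater than the threshold survive, so a PSM at
#' exactly 95 is rejected under the default; (2) decoy removal, with decoys
#' (flag or \code{REV_} accession prefix) counted first for the FDR
#' summary; (3) contaminant removal (flag or configured gene symbols,
#' keratins by default). Every removed class is counted, so
#' \code{n_input = passing + rejected_confidence + decoys + contaminants}.
#'
#' @param x a \linkS4class{PSMSet} whose records share one experiment id.
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with \code{psms} (the passing \linkS4class{PSMSet}) and
#'   \code{stats} (one-row data.frame: \code{experiment}, \code{n_input},
#'   \code{n_pass_confidence}, \code{n_target_matches},
#'   \code{n_decoy_matches}, \code{fdr_percent},
#'   \code{n_contaminant_removed}, \code{n_confidence_rejected}).
#' @export
filterPSMs <- function(x, config = pipelineConfig()) {
  stopifnot(is(x, "PSMSet"), is(config, "PipelineConfig"))
  d <- psmData(x)
  exps <- unique(d$experiment)
  if (length(exps) > 1L)
    stop("filterPSMs validation error: records span multiple experiments: ",
         paste(exps, collapse = ", "), call. = FALSE)
  thr <- config@confidence_threshold
  pass_conf <- d$confidence > thr
  dd <- d[pass_conf, , drop = FALSE]
  is_decoy <- dd$is_decoy | startsWith(dd$protein, "REV_")
  contam_syms <- normalizeGeneSymbols(config@contaminant_genes)
  is_contam <- !is_decoy &
    (dd$is_contaminant | normalizeGeneSymbols(dd$gene) %in% contam_syms)
  n_decoy <- sum(is_decoy)
  n_target <- sum(!is_decoy)
  out <- dd[!is_decoy & !is_contam, , drop = FALSE]
  stats <- data.frame(
    experiment = if (length(exps)) exps else NA_character_,
    n_input = nrow(d),
    n_pass_confidence = nrow(dd),
    n_target_matches = n_target,
    n_decoy_matches = n_decoy,
    fdr_percent = computeFDR(n_decoy, n_target, config@fdr_method),
    n_contaminant_removed = sum(is_contam),
    n_confidence_rejected = nrow(d) - nrow(dd),
    stringsAsFactors = FALSE)
  list(psms = psmSet(out, channelNames(x)), stats = stats)
}

#' Filter a multi-experiment PSMSet
#'
#' Splits by experiment, applies \code{\link{filterPSMs}} to each, and
#' returns the recombined passing records plus the per-experiment
#' statistics table.
#'
#' @inheritParams filterPSMs
#' @return list with \code{psms} (\linkS4class{PSMSet}) and \code{stats}
#'   (data.frame, one row per experiment).
#' @export
filterAllExperiments <- function(x, config = pipelineConfig()) {
  d <- psmData(x)
  exps <- unique(d$experiment)
  parts <- lapply(exps, function(e) {
    filterPSMs(psmSet(d[d$experiment == e, , drop = FALSE],
                      channelNames(x)), config)
  })
  psms <- do.call(rbind, lapply(parts, function(p) psmData(p$psms)))
  if (is.null(psms)) psms <- d[0, , drop = FALSE]
  list(psms = psmSet(psms, channelNames(x)),
       stats = do.call(rbind, lapply(parts, `[[`, "stats")))
}
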
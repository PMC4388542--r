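# Synthetic 2-plex reporter-ion data generator. The model, all on the
# natural-log scale (lognormal noise, consistent with the geometric
# statistics used downstream):
#
#   realized log-ratio of protein i in experiment e:
#       ln r_ie = ln(true_ratio_i) + Normal(0, sigma_e^2)
#   per PSM j: denominator intensity ~ LogNormal(base_mean, base_sd),
#       numerator = denominator * exp(ln r_ie + Normal(0, sigma_p^2))
#
# Each reporter peak then goes missing independently with
# missing_peak_prob; confidences straddle the identification threshold
# with subthreshold_prob below it; decoy (reversed-peptide, REV_ prefix)
# and keratin-like contaminant records are appended with no truth effect.

.aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
         "T","V","W","Y")

.random_peptides <- function(n, len_range = c(8L, 15L)) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(l) paste(sample(.aa, l, replace = TRUE),
                                 collapse = ""), character(1L))
}

.reverse_seq <- function(x) {
  vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
         character(1L))
}

.sim_channels <- function(i) {
  # alternate the two published 2-plex tag pairs across experiments;
  # the first listed channel carries the denominator (WT) condition
  if (i %% 2L == 1L) c("i113", "i114") else c("i117", "i118")
}

#' Generate a multi-experiment 2-plex reporter-ion dataset
#'
#' Deterministic given \code{params@seed}: two calls with identical
#' parameters produce byte-identical tables. The returned truth table
#' records every realized per-experiment ratio so downstream estimates can
#' be verified draw by draw.
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{psms} (a \linkS4class{PSMSet} spanning all
#'   experiments), \code{truth} (data.frame: \code{gene},
#'   \code{true_ratio}, one \code{realized_<experiment>} and one
#'   \code{n_peptides_<experiment>} column per experiment,
#'   \code{is_decoy}, \code{is_contaminant}) and \code{design} (a
#'   \linkS4class{ChannelDesign}).
#' @export
simulateDataset <- function(params = simParams()) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(as.integer(params@seed))
  n_prot <- as.integer(params@n_proteins)
  n_exp <- as.integer(params@n_experiments)
  genes <- sprintf("Simg%03d", seq_len(n_prot))
  true_ratio <- stats::setNames(rep(1, n_prot), genes)
  extra <- setdiff(names(params@true_ratios), genes)
  if (length(extra))
    stop("true_ratios name unknown gene(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  true_ratio[names(params@true_ratios)] <- params@true_ratios
  exp_ids <- sprintf("E%d", seq_len(n_exp))

  design <- do.call(rbind, lapply(seq_len(n_exp), function(i) {
    ch <- .sim_channels(i)
    data.frame(experiment = exp_ids[i], channel = ch,
               condition = c("WT", "KO"), stringsAsFactors = FALSE)
  }))
  all_channels <- sort(unique(design$channel))

  pp <- as.integer(params@peptides_per_protein)
  thr <- params@confidence_threshold
  psm_rows <- list(); truth_rows <- list()
  realized <- matrix(NA_real_, n_prot, n_exp,
                     dimnames = list(genes, exp_ids))
  pepcount <- matrix(0L, n_prot, n_exp, dimnames = list(genes, exp_ids))

  for (e in seq_len(n_exp)) {
    ch <- .sim_channels(e)   # ch[1] = WT (denominator), ch[2] = KO
    log_realized <- log(true_ratio) + stats::rnorm(n_prot, 0, params@sigma_e)
    realized[, e] <- exp(log_realized)
    n_pep <- sample(seq(pp[1L], pp[2L]), n_prot, replace = TRUE)
    pepcount[, e] <- n_pep
    idx <- rep(seq_len(n_prot), n_pep)
    m <- length(idx)
    den <- stats::rlnorm(m, params@base_log_intensity_mean,
                         params@base_log_intensity_sd)
    num <- den * exp(log_realized[idx] + stats::rnorm(m, 0, params@sigma_p))
    den[stats::runif(m) < params@missing_peak_prob] <- NA_real_
    num[stats::runif(m) < params@missing_peak_prob] <- NA_real_
    sub <- stats::runif(m) < params@subthreshold_prob
    conf <- ifelse(sub, stats::runif(m, 0, thr),
                   thr + (100 - thr) * stats::runif(m)^0.5)
    target <- data.frame(experiment = exp_ids[e],
                         peptide = .random_peptides(m),
                         protein = paste0("P_", genes[idx]),
                         gene = genes[idx], confidence = conf,
                         stringsAsFactors = FALSE)
    target[[ch[1L]]] <- den
    target[[ch[2L]]] <- num
    target$is_decoy <- FALSE
    target$is_contaminant <- FALSE

    extras <- list()
    n_decoy <- round(params@decoy_frac * m)
    if (n_decoy > 0) {
      dden <- stats::rlnorm(n_decoy, params@base_log_intensity_mean,
                            params@base_log_intensity_sd)
      dec <- data.frame(experiment = exp_ids[e],
                        peptide = .reverse_seq(.random_peptides(n_decoy)),
                        protein = sprintf("REV_P%03d", seq_len(n_decoy)),
                        gene = sprintf("Revg%03d", seq_len(n_decoy)),
                        confidence = stats::runif(n_decoy, 80, 100),
                        stringsAsFactors = FALSE)
      dec[[ch[1L]]] <- dden
      dec[[ch[2L]]] <- dden * exp(stats::rnorm(n_decoy, 0, params@sigma_p))
      dec$is_decoy <- TRUE
      dec$is_contaminant <- FALSE
      extras <- c(extras, list(dec))
    }
    n_cont <- round(params@contaminant_frac * m)
    if (n_cont > 0) {
      cden <- stats::rlnorm(n_cont, params@base_log_intensity_mean,
                            params@base_log_intensity_sd)
      krt <- sample(c("Krt1", "Krt2", "Krt5", "Krt10"), n_cont,
                    replace = TRUE)
      con <- data.frame(experiment = exp_ids[e],
                        peptide = .random_peptides(n_cont),
                        protein = paste0("P_", krt), gene = krt,
                        confidence = thr + (100 - thr) *
                          stats::runif(n_cont)^0.5,
                        stringsAsFactors = FALSE)
      con[[ch[1L]]] <- cden
      con[[ch[2L]]] <- cden * exp(stats::rnorm(n_cont, 0, params@sigma_p))
      con$is_decoy <- FALSE
      con$is_contaminant <- TRUE
      extras <- c(extras, list(con))
    }
    block <- do.call(rbind, c(list(target), extras))
    for (miss_ch in setdiff(all_channels, ch)) block[[miss_ch]] <- NA_real_
    psm_rows[[e]] <- block
  }

  psm <- do.call(rbind, psm_rows)
  ord <- c("experiment", "peptide", "protein", "gene", "confidence",
           all_channels, "is_decoy", "is_contaminant")
  psm <- psm[, ord]
  truth <- data.frame(gene = genes, true_ratio = unname(true_ratio),
                      stringsAsFactors = FALSE)
  for (e in seq_len(n_exp)) {
    truth[[paste0("realized_", exp_ids[e])]] <- realized[, e]
    truth[[paste0("n_peptides_", exp_ids[e])]] <- pepcount[, e]
  }
  truth$is_decoy <- FALSE
  truth$is_contaminant <- FALSE
  list(psms = psmSet(psm, all_channels), truth = truth,
       design = channelDesign(design))
}

#' Generate a battery of all-null datasets
#'
#' \code{n_reps} independent datasets whose proteins all have true ratio 1,
#' seeded \code{seed, seed + 1, ...} so replicates differ but the battery
#' is reproducible. Used for Monte-Carlo estimation of the pipeline's
#' type-I error rate.
#'
#' @param n_reps number of datasets.
#' @param params a \linkS4class{SimParams}; any \code{true_ratios} are
#'   reset to null.
#' @return list of \code{n_reps} results of \code{\link{simulateDataset}},
#'   each carrying its seed as attribute \code{"seed"}.
#' @export
makeNullBattery <- function(n_reps, params = simParams()) {
  stopifnot(n_reps >= 1)
  params@true_ratios <- numeric()
  lapply(seq_len(n_reps) - 1L, function(i) {
    p <- params
    p@seed <- params@seed + i
    out <- simulateDataset(p)
    attr(out, "seed") <- p@seed
    out
  })
}
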
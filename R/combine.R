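# Cross-experiment combination and the internal-reference-anchored
# differential test. The per-experiment protein ratios are averaged
# arithmetically (the published summary statistics behave as arithmetic
# mean/SD in the reproduced tests), and each protein is compared to a
# stable reference protein with ratio ~1 by a pooled two-sample t-test.

#' Combine per-experiment protein quantifications
#'
#' Genes identified in any experiment form the identified set; genes with a
#' valid ratio in at least \code{min_experiments} experiments form the
#' quantified set, each carrying the arithmetic mean and sample SD of its
#' per-experiment geometric-mean ratios (SD is \code{NA} below 2 values).
#'
#' @param quant data.frame from \code{\link{rollupProteins}} covering all
#'   experiments (distinct \code{experiment} ids).
#' @param min_experiments required number of experiments with a valid
#'   ratio; \code{NA} (default) means every experiment present in
#'   \code{quant}.
#' @return list with \code{quantified} (data.frame: \code{gene},
#'   \code{n_experiments}, \code{mean_ratio}, \code{sd_ratio}, plus one
#'   \code{ratio_<experiment>} column per experiment) and \code{identified}
#'   (character vector of all genes seen in any experiment).
#' @export
combineExperiments <- function(quant, min_experiments = NA) {
  if (!nrow(quant))
    return(list(quantified = data.frame(gene = character(),
                                        n_experiments = integer(),
                                        mean_ratio = numeric(),
                                        sd_ratio = numeric(),
                                        stringsAsFactors = FALSE),
                identified = character()))
  exps <- sort(unique(quant$experiment))
  if (is.na(min_experiments)) min_experiments <- length(exps)
  identified <- sort(unique(quant$gene))
  # gene x experiment matrix of per-experiment geometric-mean ratios
  wide <- matrix(NA_real_, nrow = length(identified), ncol = length(exps),
                 dimnames = list(identified, exps))
  ok <- !is.na(quant$gm_ratio)
  wide[cbind(match(quant$gene[ok], identified),
             match(quant$experiment[ok], exps))] <- quant$gm_ratio[ok]
  n_present <- rowSums(!is.na(wide))
  keep <- n_present >= min_experiments
  q <- data.frame(gene = identified[keep],
                  n_experiments = n_present[keep],
                  mean_ratio = apply(wide[keep, , drop = FALSE], 1L, mean,
                                     na.rm = TRUE),
                  sd_ratio = apply(wide[keep, , drop = FALSE], 1L,
                                   function(r) {
                                     r <- r[!is.na(r)]
                                     if (length(r) >= 2L) stats::sd(r)
                                     else NA_real_
                                   }),
                  stringsAsFactors = FALSE)
  for (e in exps) q[[paste0("ratio_", e)]] <- wide[keep, e]
  rownames(q) <- NULL
  list(quantified = q, identified = identified)
}

#' Select the internal reference protein
#'
#' When the configuration names a gene, its combined statistics are
#' returned (error if the gene was not quantified or has fewer than 2
#' experiments). Under \code{"AUTO"}, the quantified gene minimizing
#' |mean_ratio - 1| wins, with ties broken by smallest sd_ratio, then
#' lexicographically smallest gene symbol.
#'
#' @param quantified data.frame from \code{\link{combineExperiments}}.
#' @param config a \linkS4class{PipelineConfig} (its \code{reference_gene}
#'   is used).
#' @return list with \code{gene}, \code{mean}, \code{sd}, \code{n}.
#' @export
selectReference <- function(quantified, config = pipelineConfig()) {
  if (!nrow(quantified))
    stop("configuration error: no quantified proteins to select a reference from",
         call. = FALSE)
  ref <- config@reference_gene
  if (!identical(ref, "AUTO")) {
    hit <- which(quantified$gene == ref)
    if (!length(hit))
      stop("configuration error: reference gene '", ref,
           "' absent from the quantified set", call. = FALSE)
    row <- quantified[hit[1L], ]
  } else {
    ord <- order(abs(quantified$mean_ratio - 1), quantified$sd_ratio,
                 quantified$gene)
    row <- quantified[ord[1L], ]
  }
  if (is.na(row$sd_ratio) || row$n_experiments < 2L)
    stop("insufficient replication: reference '", row$gene,
         "' has fewer than 2 experiments", call. = FALSE)
  list(gene = row$gene, mean = row$mean_ratio, sd = row$sd_ratio,
       n = as.integer(row$n_experiments))
}

#' Two-sample t-test of a protein against the internal reference
#'
#' Pooled-variance (Student) two-tailed test from summary statistics:
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \quad
#'       t = \frac{\bar{x}_{ref} - \bar{x}}{s_p\sqrt{1/n_1 + 1/n_2}},}
#' with \eqn{df = n_1+n_2-2} and p from the central t distribution. Welch's
#' unequal-variance form is available via \code{var_equal = FALSE}. With
#' zero pooled variance, p is 1 for equal means and 0 otherwise.
#'
#' @param mean,sd,n protein summary statistics (sample SD, n >= 2).
#' @param ref_mean,ref_sd,ref_n reference summary statistics.
#' @param alpha significance level for the call.
#' @return one-row data.frame: \code{mean_ratio}, \code{sd_ratio},
#'   \code{n}, \code{t_statistic} (magnitude), \code{df}, \code{p_value},
#'   \code{significant}, \code{direction}.
#' @examples
#' referenceTTest(0.76, 0.020, 3, 1.01, 0.064, 3)  # p ~ 0.003, decreased
#' @export
referenceTTest <- function(mean, sd, n, ref_mean, ref_sd, ref_n,
                           alpha = 0.05, var_equal = TRUE) {
  if (n < 2 || ref_n < 2)
    stop("insufficient replication: both sides need n >= 2", call. = FALSE)
  if (sd < 0 || ref_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  delta <- ref_mean - mean
  if (var_equal) {
    df <- n + ref_n - 2
    sp2 <- ((n - 1) * sd^2 + (ref_n - 1) * ref_sd^2) / df
    se <- sqrt(sp2 * (1 / n + 1 / ref_n))
  } else {
    v1 <- sd^2 / n; v2 <- ref_sd^2 / ref_n
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n - 1) + v2^2 / (ref_n - 1))
          else n + ref_n - 2
  }
  if (se == 0) {
    t_stat <- if (delta == 0) 0 else Inf
    p <- if (delta == 0) 1 else 0
  } else {
    t_stat <- abs(delta) / se
    p <- 2 * stats::pt(-t_stat, df)
  }
  data.frame(mean_ratio = mean, sd_ratio = sd, n = as.integer(n),
             t_statistic = t_stat, df = df, p_value = p,
             significant = p < alpha,
             direction = if (mean > 1) "increased"
                         else if (mean < 1) "decreased" else "unchanged",
             stringsAsFactors = FALSE)
}

#' Reference t-test from raw per-experiment ratio vectors
#'
#' Equivalent entry point to \code{\link{referenceTTest}}: computes the
#' summary statistics of the two vectors and delegates, so the two paths
#' agree exactly. With \code{scale = "log"} the test is run on natural-log
#' ratios (the reported \code{mean_ratio} stays the arithmetic mean of the
#' raw ratios, and direction follows it).
#'
#' @param ratios numeric vector of the protein's per-experiment ratios.
#' @param ref_ratios numeric vector of the reference's per-experiment
#'   ratios.
#' @param alpha significance level.
#' @param var_equal pooled (default) vs Welch.
#' @param scale \code{"ratio"} or \code{"log"}.
#' @return one-row data.frame as in \code{\link{referenceTTest}}.
#' @export
referenceTTestRaw <- function(ratios, ref_ratios, alpha = 0.05,
                              var_equal = TRUE,
                              scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  ratios <- ratios[!is.na(ratios)]
  ref_ratios <- ref_ratios[!is.na(ref_ratios)]
  x <- if (scale == "log") log(ratios) else ratios
  y <- if (scale == "log") log(ref_ratios) else ref_ratios
  out <- referenceTTest(base::mean(x), stats::sd(x), length(x),
                        base::mean(y), stats::sd(y), length(y),
                        alpha = alpha, var_equal = var_equal)
  # report on the ratio scale regardless of the testing scale
  out$mean_ratio <- base::mean(ratios)
  out$sd_ratio <- stats::sd(ratios)
  out$direction <- if (out$mean_ratio > 1) "increased"
                   else if (out$mean_ratio < 1) "decreased" else "unchanged"
  out
}

#' Differential-abundance testing of all quantified proteins
#'
#' Tests every quantified protein against the reference. No multiple-testing
#' correction enters the primary call (significance is raw p < alpha, as in
#' the anchored-reference design); a Benjamini-Hochberg column \code{p_bh}
#' is emitted alongside for inspection.
#'
#' @param quantified data.frame from \code{\link{combineExperiments}}.
#' @param reference list from \code{\link{selectReference}}.
#' @param config a \linkS4class{PipelineConfig}; \code{alpha},
#'   \code{test_scale} and \code{var_equal} are used.
#' @return A \linkS4class{DifferentialResults}.
#' @export
diffTest <- function(quantified, reference, config = pipelineConfig()) {
  alpha <- config@alpha
  ratio_cols <- grep("^ratio_", names(quantified), value = TRUE)
  testable <- quantified[quantified$n_experiments >= 2L &
                           !is.na(quantified$sd_ratio), , drop = FALSE]
  rows <- lapply(seq_len(nrow(testable)), function(i) {
    g <- testable[i, ]
    if (config@test_scale == "log" && length(ratio_cols)) {
      ref_row <- quantified[quantified$gene == reference$gene, , drop = FALSE]
      res <- referenceTTestRaw(as.numeric(g[ratio_cols]),
                               as.numeric(ref_row[1L, ratio_cols]),
                               alpha = alpha, var_equal = config@var_equal,
                               scale = "log")
    } else {
      res <- referenceTTest(g$mean_ratio, g$sd_ratio, g$n_experiments,
                            reference$mean, reference$sd, reference$n,
                            alpha = alpha, var_equal = config@var_equal)
    }
    cbind(data.frame(gene = g$gene, stringsAsFactors = FALSE), res)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(), mean_ratio = numeric(),
                         sd_ratio = numeric(), n = integer(),
                         t_statistic = numeric(), df = numeric(),
                         p_value = numeric(), significant = logical(),
                         direction = character(), stringsAsFactors = FALSE)
  tab$p_bh <- bhAdjust(tab$p_value)
  tab <- tab[, c("gene", "mean_ratio", "sd_ratio", "n", "t_statistic", "df",
                 "p_value", "p_bh", "significant", "direction")]
  rownames(tab) <- NULL
  new("DifferentialResults", table = tab, reference = reference,
      alpha = alpha)
}

#' Summarize the significant candidate set
#'
#' @param results a \linkS4class{DifferentialResults}.
#' @return list with \code{significant} (gene vector), \code{n_tested},
#'   \code{n_significant}, \code{percent_of_quantified},
#'   \code{n_increased}, \code{n_decreased}.
#' @export
callCandidates <- function(results) {
  stopifnot(is(results, "DifferentialResults"))
  d <- resultsTable(results)
  sig <- d[d$significant, , drop = FALSE]
  list(significant = sig$gene,
       n_tested = nrow(d),
       n_significant = nrow(sig),
       percent_of_quantified = if (nrow(d)) 100 * nrow(sig) / nrow(d)
                               else 0,
       n_increased = sum(sig$direction == "increased"),
       n_decreased = sum(sig$direction == "decreased"))
}
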
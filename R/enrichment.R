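# Over-representation analysis (DAVID-style arithmetic) and target-list
# overlap statistics.

#' One-sided hypergeometric over-representation test
#'
#' p = P(X >= k) where X counts query genes falling in the term when
#' |query| genes are drawn without replacement from the population
#' containing |term| annotated genes - equivalently the one-sided Fisher
#' exact test. The EASE-penalized variant (replace k by k - 1, the
#' conservative score behind DAVID) is available via \code{ease = TRUE}.
#'
#' @param query gene-symbol set of interest (must lie within
#'   \code{population}).
#' @param term_genes gene-symbol set annotated to the term (within
#'   \code{population}).
#' @param population background gene universe.
#' @param ease apply the EASE k-1 penalty.
#' @return list with \code{k} (overlap count) and \code{p_value}.
#' @export
oraTest <- function(query, term_genes, population, ease = FALSE) {
  query <- unique(query); term_genes <- unique(term_genes)
  population <- unique(population)
  out <- setdiff(query, population)
  if (length(out))
    stop("validation error: query gene(s) outside population: ",
         paste(out, collapse = ", "), call. = FALSE)
  term_genes <- intersect(term_genes, population)
  k <- length(intersect(query, term_genes))
  kk <- if (ease) max(k - 1L, 0L) else k
  p <- if (kk == 0L) 1
       else stats::phyper(kk - 1L, length(term_genes),
                          length(population) - length(term_genes),
                          length(query), lower.tail = FALSE)
  list(k = k, p_value = p)
}

#' Fold enrichment
#'
#' (k/n) / (K/N): the query's annotated fraction over the background's.
#' Returns \code{NA} when k = 0.
#'
#' @param k query genes in the term.
#' @param n query size.
#' @param K population genes in the term.
#' @param N population size.
#' @return dimensionless enrichment ratio.
#' @examples foldEnrichment(10, 50, 100, 10000)  # 20
#' @export
foldEnrichment <- function(k, n, K, N) {
  if (n <= 0 || N <= 0 || K <= 0)
    stop("parameter error: n, K and N must be > 0", call. = FALSE)
  if (k == 0) return(NA_real_)
  (k / n) / (K / N)
}

#' Bonferroni adjustment of a single p-value
#'
#' @param p raw p-value in [0, 1].
#' @param m number of tests (>= 1).
#' @return min(1, m * p).
#' @export
bonferroniAdjust <- function(p, m) {
  stopifnot(p >= 0, p <= 1, m >= 1)
  pmin(1, m * p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up adjusted values, returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a query list against a gene-set
#' collection
#'
#' One row per term with at least one query gene: the overlap count, the
#' percent of the query annotated, the one-sided hypergeometric p, the
#' fold enrichment, and Bonferroni / Benjamini-Hochberg corrected
#' p-values. Corrections are applied within each namespace (BP/CC/MF/
#' other) separately, with m = number of terms tested in that namespace,
#' mirroring per-category enrichment tables.
#'
#' @param query gene-symbol vector (normalized internally).
#' @param db a \linkS4class{GeneSetDb}.
#' @param ease use the EASE k-1 penalized score.
#' @return data.frame with columns \code{term_id}, \code{namespace},
#'   \code{term_name}, \code{count}, \code{percent}, \code{p_value},
#'   \code{fold_enrichment}, \code{bonferroni}, \code{benjamini}, sorted
#'   by namespace then p-value.
#' @export
enrichTerms <- function(query, db, ease = FALSE) {
  stopifnot(is(db, "GeneSetDb"))
  query <- unique(normalizeGeneSymbols(query))
  population <- setUniverse(db)
  out <- setdiff(query, population)
  if (length(out))
    stop("validation error: query gene(s) outside universe: ",
         paste(utils::head(out, 5L), collapse = ", "), call. = FALSE)
  sets <- geneSets(db)
  ns <- setNamespaces(db)
  names_tab <- stats::setNames(db@term_name, db@term_id)
  n <- length(query); N <- length(population)
  rows <- lapply(names(sets), function(id) {
    tg <- sets[[id]]
    res <- oraTest(query, tg, population, ease = ease)
    if (res$k == 0L) return(NULL)
    data.frame(term_id = id, namespace = unname(ns[id]),
               term_name = unname(names_tab[id]),
               count = res$k, percent = 100 * res$k / n,
               p_value = res$p_value,
               fold_enrichment = foldEnrichment(res$k, n, length(tg), N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(term_id = character(), namespace = character(),
                      term_name = character(), count = integer(),
                      percent = numeric(), p_value = numeric(),
                      fold_enrichment = numeric(), bonferroni = numeric(),
                      benjamini = numeric(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab$bonferroni <- NA_real_; tab$benjamini <- NA_real_
  for (nsp in unique(tab$namespace)) {
    idx <- tab$namespace == nsp
    m <- sum(idx)
    tab$bonferroni[idx] <- bonferroniAdjust(tab$p_value[idx], m)
    tab$benjamini[idx] <- bhAdjust(tab$p_value[idx])
  }
  tab <- tab[order(tab$namespace, tab$p_value, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Overlap of a query gene list with a target list
#'
#' Symbols are case-normalized before intersecting; the percent is taken
#' over a caller-chosen denominator (e.g. the full identified proteome or
#' the quantified subset). Query genes matching no target are not an
#' error; symbol discrepancies between published lists are the caller's to
#' inspect via the returned overlap.
#'
#' @param query gene-symbol vector.
#' @param targets target gene-symbol vector.
#' @param denominator count the percent is taken over (> 0).
#' @return list with \code{query_size}, \code{target_list_size},
#'   \code{overlap} (sorted gene vector), \code{overlap_count},
#'   \code{percent_of_denominator}.
#' @export
overlapStats <- function(query, targets, denominator = length(unique(query))) {
  if (denominator <= 0)
    stop("parameter error: denominator must be > 0", call. = FALSE)
  q <- unique(normalizeGeneSymbols(query))
  t <- unique(normalizeGeneSymbols(targets))
  ov <- sort(intersect(q, t))
  miss <- setdiff(t, q)
  if (length(miss))
    message(length(miss), " target gene(s) not found in the query list: ",
            paste(utils::head(miss, 5L), collapse = ", "))
  list(query_size = length(q), target_list_size = length(t),
       overlap = ov, overlap_count = length(ov),
       percent_of_denominator = 100 * length(ov) / denominator)
}
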
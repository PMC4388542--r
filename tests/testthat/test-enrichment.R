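test_that("hypergeometric upper tail equals exhaustive enumeration on small populations", {
  set.seed(13)
  pop20 <- sprintf("g%02d", 1:20)
  # the worked case: |population| 20, |term| 5, |query| 5, k = 3
  term <- pop20[1:5]
  query <- c(pop20[1:3], pop20[10:11])
  res <- oraTest(query, term, pop20)
  expect_equal(res$k, 3)
  expect_equal(res$p_value, enumerate_upper_tail(pop20, term, 5, 3),
               tolerance = 1e-12)
  # randomized instances across population sizes up to 25
  for (i in 1:12) {
    N <- sample(8:25, 1)
    pop <- sprintf("g%02d", seq_len(N))
    term <- sample(pop, sample(2:(N - 2), 1))
    query <- sample(pop, sample(2:(N - 2), 1))
    res <- oraTest(query, term, pop)
    expect_equal(res$p_value,
                 enumerate_upper_tail(pop, term, length(query), res$k),
                 tolerance = 1e-10)
  }
})

test_that("saturated and empty overlaps hit the boundary p-values", {
  pop <- sprintf("g%d", 1:6)
  sat <- oraTest(pop, pop, pop)
  expect_equal(sat$k, 6)
  expect_equal(sat$p_value, 1)
  none <- oraTest(pop[1:2], pop[5:6], pop)
  expect_equal(none$k, 0)
  expect_equal(none$p_value, 1)
  expect_error(oraTest(c("zz", pop[1]), pop[1:2], pop), "outside population")
})

test_that("p is non-increasing in the overlap count for a fixed design", {
  N <- 100; K <- 20; n <- 15
  ps <- vapply(0:15, function(k)
    if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    numeric(1))
  pop <- sprintf("g%03d", 1:N)
  term <- pop[1:K]
  got <- vapply(0:15, function(k) {
    query <- c(pop[seq_len(k)], pop[(K + 1):(K + n - k)])
    oraTest(query, term, pop)$p_value
  }, numeric(1))
  expect_equal(got, ps, tolerance = 1e-12)
  expect_true(all(diff(got) <= 1e-15))
})

test_that("fold enrichment and the percent column follow their definitions", {
  expect_equal(foldEnrichment(5, 50, 100, 1000), 1)
  expect_equal(foldEnrichment(10, 50, 100, 10000), 20)
  expect_true(is.na(foldEnrichment(0, 50, 100, 1000)))
  expect_error(foldEnrichment(1, 0, 10, 100), "parameter error")
  expect_equal(100 * 48 / 85, 56.47, tolerance = 0.005)
})

test_that("Bonferroni and BH corrections match their textbook definitions", {
  expect_equal(bonferroniAdjust(0.01, 5), 0.05)
  expect_equal(bonferroniAdjust(0.3, 5), 1)
  expect_equal(bonferroniAdjust(0.2, 1), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.4), 0.4)
  set.seed(29)
  for (i in 1:40) {
    p <- runif(sample(1:30, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("enrichment rows are mutually consistent and corrected per namespace", {
  pop <- sprintf("g%02d", 1:40)
  db <- geneSetDb(term_id = c("CC:1", "CC:2", "BP:1"),
                  namespace = c("CC", "CC", "BP"),
                  term_name = c("membrane", "synapse", "adhesion"),
                  genes = list(pop[1:10], pop[5:8], pop[1:4]),
                  universe = pop)
  query <- pop[1:8]
  tab <- enrichTerms(query, db)
  expect_equal(nrow(tab), 3)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$percent[i], 100 * tab$count[i] / length(query))
    K <- length(geneSets(db)[[tab$term_id[i]]])
    expect_equal(tab$fold_enrichment[i],
                 (tab$count[i] / length(query)) / (K / length(pop)))
    expect_gte(tab$bonferroni[i], tab$p_value[i])
    expect_gte(tab$benjamini[i], tab$p_value[i])
    expect_lte(tab$bonferroni[i], 1)
  }
  # corrections use the within-namespace test count
  cc <- tab[tab$namespace == "CC", ]
  expect_equal(cc$bonferroni, pmin(1, 2 * cc$p_value))
  bp <- tab[tab$namespace == "BP", ]
  expect_equal(bp$bonferroni, bp$p_value)
  expect_equal(bp$benjamini, bp$p_value)
})

test_that("overlap statistics normalize symbols and use the chosen denominator", {
  ov <- overlapStats(c("a", "b", "c"), c("B", "C", "d"), denominator = 3)
  expect_equal(ov$overlap, c("B", "C"))
  expect_equal(ov$overlap_count, 2)
  expect_equal(ov$percent_of_denominator, 100 * 2 / 3, tolerance = 1e-9)
  expect_error(overlapStats("a", "a", denominator = 0), "denominator")
  expect_message(overlapStats(c("a"), c("a", "x")), "not found")
})
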
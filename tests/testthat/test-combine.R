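quant_df <- function(...) {
  # rows: list(experiment, gene, gm)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(experiment = r[[1]], gene = r[[2]],
               gm_ratio = as.numeric(r[[3]]), geometric_sd = NA_real_,
               n_peptides_quantified = 2L, n_peptides_identified = 2L,
               stringsAsFactors = FALSE)))
}

test_that("cross-experiment combination applies the all-experiments rule", {
  q <- quant_df(list("E1", "Ga", 0.80), list("E2", "Ga", 0.75),
                list("E3", "Ga", 0.73),
                list("E1", "Gb", 1.1), list("E2", "Gb", 1.2))
  out <- combineExperiments(q, min_experiments = 3)
  expect_equal(out$quantified$gene, "Ga")
  expect_equal(out$quantified$mean_ratio, 0.76)
  expect_equal(out$quantified$sd_ratio, sd(c(0.80, 0.75, 0.73)))
  expect_lt(abs(out$quantified$sd_ratio - 0.0361), 1e-3)
  # Gb is identified (2/3 experiments) but not quantified
  expect_setequal(out$identified, c("Ga", "Gb"))

  single <- combineExperiments(quant_df(list("E1", "Ga", 1.4)),
                               min_experiments = 1)
  expect_equal(single$quantified$mean_ratio, 1.4)
  expect_true(is.na(single$quantified$sd_ratio))

  empty <- combineExperiments(quant_df(list("E1", "Ga", 1))[0, ])
  expect_equal(nrow(empty$quantified), 0L)
  expect_length(empty$identified, 0L)
})

test_that("an experiment with no valid ratio counts as identified only", {
  q <- quant_df(list("E1", "Ga", 1), list("E2", "Ga", 1),
                list("E3", "Ga", 1), list("E1", "Gb", 1.2),
                list("E2", "Gb", 1.1))
  q <- rbind(q, data.frame(experiment = "E3", gene = "Gb",
                           gm_ratio = NA_real_, geometric_sd = NA_real_,
                           n_peptides_quantified = 0L,
                           n_peptides_identified = 3L,
                           stringsAsFactors = FALSE))
  out <- combineExperiments(q, min_experiments = 3)
  expect_false("Gb" %in% out$quantified$gene)
  expect_true("Gb" %in% out$identified)
})

test_that("reference selection honors the named gene and the AUTO tie-breaks", {
  q <- quant_df(list("E1", "Hspa8", 0.95), list("E2", "Hspa8", 1.00),
                list("E3", "Hspa8", 1.08),
                list("E1", "Ga", 1.00), list("E2", "Ga", 0.80),
                list("E3", "Ga", 1.20),
                list("E1", "Gb", 1.01), list("E2", "Gb", 1.02),
                list("E3", "Gb", 1.03))
  comb <- combineExperiments(q, 3)$quantified
  named <- selectReference(comb, pipelineConfig(reference_gene = "Hspa8"))
  expect_equal(named$gene, "Hspa8")
  expect_equal(named$mean, mean(c(0.95, 1.00, 1.08)))
  expect_error(selectReference(comb, pipelineConfig(reference_gene = "Gz")),
               "absent")
  # AUTO: Ga (mean 1.00) beats Gb (mean 1.02) despite larger sd
  auto <- selectReference(comb, pipelineConfig())
  expect_equal(auto$gene, "Ga")
  # sd tie-break between two genes with equal |mean - 1|
  q2 <- quant_df(list("E1", "Ga", 0.95), list("E2", "Ga", 1.00),
                 list("E3", "Ga", 1.05),
                 list("E1", "Gb", 0.99), list("E2", "Gb", 1.00),
                 list("E3", "Gb", 1.01))
  comb2 <- combineExperiments(q2, 3)$quantified
  expect_equal(selectReference(comb2, pipelineConfig())$gene, "Gb")
})

test_that("the pooled reference t-test reproduces printed summary rows", {
  ref <- ref_stats()
  ly6h <- referenceTTest(0.76, 0.020, 3, ref$mean, ref$sd, ref$n)
  expect_lt(abs(ly6h$p_value - 0.003), 0.001)
  expect_equal(ly6h$df, 4)
  expect_equal(ly6h$direction, "decreased")
  expect_true(ly6h$significant)

  plp1 <- referenceTTest(1.55, 0.176, 3, ref$mean, ref$sd, ref$n)
  expect_lt(abs(plp1$p_value - 0.008), 0.001)
  expect_equal(plp1$direction, "increased")
  expect_true(plp1$significant)

  flot1 <- referenceTTest(0.80, 0.146, 3, ref$mean, ref$sd, ref$n)
  expect_lt(abs(flot1$p_value - 0.084), 0.001)
  expect_false(flot1$significant)

  self <- referenceTTest(ref$mean, ref$sd, 3, ref$mean, ref$sd, ref$n)
  expect_equal(self$t_statistic, 0)
  expect_equal(self$p_value, 1)
})

test_that("summary and raw-vector t-test paths agree with each other and t.test", {
  set.seed(31)
  for (i in 1:25) {
    x <- exp(rnorm(3, 0.1, 0.15))
    y <- exp(rnorm(3, 0, 0.1))
    raw <- referenceTTestRaw(x, y)
    summ <- referenceTTest(mean(x), sd(x), 3, mean(y), sd(y), 3)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
    expect_equal(raw$t_statistic, summ$t_statistic, tolerance = 1e-12)
    # independent oracle: stats::t.test pooled two-sample
    oracle <- t.test(y, x, var.equal = TRUE)
    expect_equal(raw$p_value, oracle$p.value, tolerance = 1e-12)
    expect_equal(raw$t_statistic, abs(unname(oracle$statistic)),
                 tolerance = 1e-10)
    welch <- referenceTTestRaw(x, y, var_equal = FALSE)
    oracle_w <- t.test(y, x)
    expect_equal(welch$p_value, oracle_w$p.value, tolerance = 1e-12)
  }
})

test_that("the t-test is symmetric in its arguments and monotone in the effect", {
  ref <- ref_stats()
  a <- referenceTTest(0.8, 0.1, 3, ref$mean, ref$sd, ref$n)
  b <- referenceTTest(ref$mean, ref$sd, ref$n, 0.8, 0.1, 3)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  means <- seq(1.02, 1.6, by = 0.02)
  ps <- vapply(means, function(m)
    referenceTTest(m, 0.1, 3, ref$mean, ref$sd, ref$n)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate inputs follow the stated contracts", {
  expect_error(referenceTTest(1, 0.1, 1, 1, 0.1, 3), "n >= 2")
  equal0 <- referenceTTest(1.2, 0, 3, 1.2, 0, 3)
  expect_equal(equal0$p_value, 1)
  diff0 <- referenceTTest(1.2, 0, 3, 1.0, 0, 3)
  expect_equal(diff0$p_value, 0)
})

test_that("candidate calling summarizes count, percent and direction split", {
  ref <- ref_stats()
  q <- quant_df(list("E1", "Hspa8", 0.95), list("E2", "Hspa8", 1.01),
                list("E3", "Hspa8", 1.07),
                list("E1", "Up", 1.50), list("E2", "Up", 1.55),
                list("E3", "Up", 1.60),
                list("E1", "Dn", 0.70), list("E2", "Dn", 0.72),
                list("E3", "Dn", 0.74),
                list("E1", "Null", 1.00), list("E2", "Null", 0.90),
                list("E3", "Null", 1.10))
  comb <- combineExperiments(q, 3)$quantified
  res <- diffTest(comb, selectReference(comb,
                  pipelineConfig(reference_gene = "Hspa8")))
  calls <- callCandidates(res)
  expect_setequal(calls$significant, c("Up", "Dn"))
  expect_equal(calls$n_increased, 1L)
  expect_equal(calls$n_decreased, 1L)
  expect_equal(calls$percent_of_quantified, 100 * 2 / 4)
  # empty input
  empty <- diffTest(comb[0, ], ref)
  expect_length(callCandidates(empty)$significant, 0L)
  expect_equal(callCandidates(empty)$n_significant, 0L)
})
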
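noiseless_params <- function(...) {
  simParams(n_proteins = 4, peptides_per_protein = c(3, 3),
            true_ratios = c(Simg002 = 2.0), sigma_p = 0, sigma_e = 0,
            missing_peak_prob = 0, subthreshold_prob = 0,
            decoy_frac = 0, contaminant_frac = 0, seed = 5, ...)
}

test_that("the noiseless limit yields exact peptide and protein ratios", {
  sim <- simulateDataset(noiseless_params())
  r <- peptideRatios(sim$psms, sim$design)
  expect_equal(unique(r$ratio[r$gene == "Simg002"]), 2.0)
  expect_equal(unique(r$ratio[r$gene != "Simg002"]), 1.0)
  quant <- rollupProteins(r)
  comb <- combineExperiments(quant)$quantified
  expect_equal(comb$mean_ratio[comb$gene == "Simg002"], 2.0)
  expect_equal(comb$sd_ratio[comb$gene == "Simg002"], 0)
  expect_equal(sim$truth$true_ratio[sim$truth$gene == "Simg002"], 2.0)
})

test_that("missing_peak_prob = 1 leaves no quantifiable ratio", {
  p <- noiseless_params()
  p@missing_peak_prob <- 1
  sim <- simulateDataset(p)
  d <- psmData(sim$psms)
  expect_true(all(is.na(d$i113) | is.na(d$i114) |
                    is.na(d$i117) | is.na(d$i118)))
  r <- peptideRatios(sim$psms, sim$design)
  expect_true(all(is.na(r$ratio)))
  expect_true(all(r$invalid_reason == "missing_peak"))
})

test_that("generation is deterministic given the seed and varies across seeds", {
  p <- simParams(n_proteins = 10, seed = 99)
  a <- simulateDataset(p)
  b <- simulateDataset(p)
  expect_identical(psmData(a$psms), psmData(b$psms))
  expect_identical(a$truth, b$truth)
  p2 <- p; p2@seed <- 100
  expect_false(identical(psmData(a$psms), psmData(simulateDataset(p2)$psms)))
})

test_that("the null battery produces distinct, seeded, all-null datasets", {
  batt <- makeNullBattery(2, simParams(n_proteins = 5, seed = 10))
  expect_length(batt, 2)
  expect_equal(attr(batt[[1]], "seed"), 10)
  expect_equal(attr(batt[[2]], "seed"), 11)
  expect_false(identical(psmData(batt[[1]]$psms), psmData(batt[[2]]$psms)))
  expect_true(all(batt[[1]]$truth$true_ratio == 1))
})

test_that("decoys and contaminants carry the advertised markers", {
  p <- simParams(n_proteins = 20, decoy_frac = 0.2, contaminant_frac = 0.1,
                 seed = 3)
  d <- psmData(simulateDataset(p)$psms)
  dec <- d[d$is_decoy, ]
  expect_gt(nrow(dec), 0)
  expect_true(all(startsWith(dec$protein, "REV_")))
  expect_false(any(dec$gene %in% d$gene[!d$is_decoy]))
  con <- d[d$is_contaminant, ]
  expect_gt(nrow(con), 0)
  expect_true(all(grepl("^Krt", con$gene)))
})

test_that("per-experiment estimates converge to the realized ratio as sigma_p -> 0", {
  p <- simParams(n_proteins = 6, peptides_per_protein = c(50, 50),
                 sigma_p = 0, sigma_e = 0.2, missing_peak_prob = 0,
                 subthreshold_prob = 0, decoy_frac = 0,
                 contaminant_frac = 0, seed = 21)
  sim <- simulateDataset(p)
  quant <- rollupProteins(peptideRatios(sim$psms, sim$design))
  for (e in c("E1", "E2", "E3")) {
    est <- quant$gm_ratio[quant$experiment == e][order(quant$gene[quant$experiment == e])]
    truth <- sim$truth[order(sim$truth$gene), paste0("realized_", e)]
    expect_equal(est, truth, tolerance = 1e-9)
  }
})

test_that("swapping the ratio orientation inverts estimates and keeps log-scale p-values", {
  p <- simParams(n_proteins = 8, true_ratios = c(Simg002 = 1.5),
                 missing_peak_prob = 0, subthreshold_prob = 0,
                 decoy_frac = 0, contaminant_frac = 0, seed = 17)
  sim <- simulateDataset(p)
  cfg <- pipelineConfig(reference_gene = "Simg001", test_scale = "log")
  fwd <- runPipeline(cfg, psms = sim$psms, design = sim$design)
  rev <- runPipeline(cfg, psms = sim$psms, design = swapDesign(sim$design))
  f <- fwd$combined[order(fwd$combined$gene), ]
  r <- rev$combined[order(rev$combined$gene), ]
  ratio_cols <- grep("^ratio_", names(f), value = TRUE)
  for (col in ratio_cols)
    expect_equal(r[[col]], 1 / f[[col]], tolerance = 1e-12)
  ft <- resultsTable(fwd$results); rt <- resultsTable(rev$results)
  ft <- ft[order(ft$gene), ]; rt <- rt[order(rt$gene), ]
  expect_equal(rt$p_value, ft$p_value, tolerance = 1e-12)
})

test_that("empirical power at a 1.55-fold effect matches the noncentral-t oracle", {
  n_rep <- 300
  sigma_e <- 0.15; sigma_p <- 0.1; m_pep <- 5
  cfg <- pipelineConfig(reference_gene = "Simg001")
  hits <- 0L; n_eval <- 0L
  for (i in seq_len(n_rep)) {
    p <- simParams(n_proteins = 2, true_ratios = c(Simg002 = 1.55),
                   sigma_e = sigma_e, sigma_p = sigma_p,
                   peptides_per_protein = c(m_pep, m_pep),
                   missing_peak_prob = 0, subthreshold_prob = 0,
                   decoy_frac = 0, contaminant_frac = 0, seed = 5000 + i)
    res <- runPipeline(cfg, sim_params = p)
    tab <- resultsTable(res$results)
    hits <- hits + tab$significant[tab$gene == "Simg002"]
    n_eval <- n_eval + 1L
  }
  power_emp <- hits / n_eval
  # noncentral-t oracle: delta-method SDs of the lognormal ratio estimates
  sig_tot <- sqrt(sigma_e^2 + sigma_p^2 / m_pep)
  s1 <- 1.55 * sqrt(exp(sig_tot^2) - 1)
  s0 <- 1.00 * sqrt(exp(sig_tot^2) - 1)
  se <- sqrt((s1^2 + s0^2) / 2) * sqrt(2 / 3)
  ncp <- 0.55 / se
  tc <- qt(0.975, 4)
  power_oracle <- 1 - pt(tc, 4, ncp) + pt(-tc, 4, ncp)
  expect_gt(power_emp, 0.5)
  expect_lt(abs(power_emp - power_oracle), 0.1)
})

test_that("combined ratio estimates are unbiased on the log scale", {
  effects <- c(0.66, 0.76, 0.82, 1.17, 1.27, 1.29, 1.55)
  names(effects) <- sprintf("Simg%03d", 2:8)
  cfg <- pipelineConfig(reference_gene = "Simg001")
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, length(effects),
                dimnames = list(NULL, names(effects)))
  for (i in seq_len(n_rep)) {
    p <- simParams(n_proteins = 8, true_ratios = effects,
                   missing_peak_prob = 0, subthreshold_prob = 0,
                   decoy_frac = 0, contaminant_frac = 0, seed = 9000 + i)
    comb <- runPipeline(cfg, sim_params = p)$combined
    est[i, ] <- comb$mean_ratio[match(names(effects), comb$gene)]
  }
  # geometric rollup is mean-unbiased in log space; allow 4 MC standard errors
  for (g in names(effects)) {
    lm_est <- mean(log(est[, g]))
    mc_se <- sd(log(est[, g])) / sqrt(n_rep)
    expect_lt(abs(lm_est - log(effects[[g]])), 4 * mc_se + 1e-3)
  }
})

test_that("degenerate parameters are rejected", {
  expect_error(simParams(n_proteins = 0), "n_proteins")
  expect_error(simParams(missing_peak_prob = 1.2), "probabilities")
  expect_error(simParams(sigma_p = -1), "SDs")
  expect_error(simulateDataset(simParams(n_proteins = 2,
                                         true_ratios = c(Nope = 2))),
               "unknown gene")
})
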
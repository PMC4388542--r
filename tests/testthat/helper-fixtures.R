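# In-code fixtures used across test files.

# a two-experiment, two-channel-pair PSM table with hand-set intensities
tiny_psm <- function() {
  d <- data.frame(
    experiment = c("E1", "E1", "E1", "E2"),
    peptide = c("AAK", "CCK", "DDR", "AAK"),
    protein = c("P_Ga", "P_Ga", "P_Gb", "P_Ga"),
    gene = c("Ga", "Ga", "Gb", "Ga"),
    confidence = c(99, 97, 96, 98),
    i113 = c(100, 200, NA, NA),
    i114 = c(200, 100, 300, NA),
    i117 = c(NA, NA, NA, 50),
    i118 = c(NA, NA, NA, 150),
    is_decoy = FALSE,
    is_contaminant = FALSE,
    stringsAsFactors = FALSE)
  psmSet(d)
}

tiny_design <- function() {
  channelDesign(data.frame(
    experiment = c("E1", "E1", "E2", "E2"),
    channel = c("i113", "i114", "i117", "i118"),
    condition = c("WT", "KO", "WT", "KO"),
    stringsAsFactors = FALSE))
}

# one-experiment PSMSet built from explicit columns
psm_one <- function(confidence, gene = "Ga", wt = 100, ko = 200,
                    is_decoy = FALSE, is_contaminant = FALSE,
                    experiment = "E1") {
  n <- max(lengths(list(confidence, gene, wt, ko)))
  d <- data.frame(
    experiment = rep_len(experiment, n),
    peptide = sprintf("PEP%d", seq_len(n)),
    protein = paste0(ifelse(rep_len(is_decoy, n), "REV_P_", "P_"),
                     rep_len(gene, n)),
    gene = rep_len(gene, n),
    confidence = rep_len(confidence, n),
    i113 = rep_len(wt, n),
    i114 = rep_len(ko, n),
    is_decoy = rep_len(is_decoy, n),
    is_contaminant = rep_len(is_contaminant, n),
    stringsAsFactors = FALSE)
  psmSet(d)
}

# reference summary statistics printed for the internal reference protein
ref_stats <- function() list(gene = "Hspa8", mean = 1.01, sd = 0.064, n = 3L)

# brute-force hypergeometric upper tail by exhaustive enumeration of draws
enumerate_upper_tail <- function(population, term_genes, n_query, k) {
  draws <- utils::combn(length(population), n_query)
  in_term <- population %in% term_genes
  hits <- apply(draws, 2L, function(ix) sum(in_term[ix]))
  mean(hits >= k)
}

# textbook step-up BH, written independently of stats::p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}
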
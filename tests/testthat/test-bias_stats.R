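test_that("region partition splits deterministically and rejects short seqs", {
  p <- partition_regions(strrep("A", 50))
  expect_equal(nchar(p$nterm), 20L)
  expect_equal(nchar(p$bulk), 10L)
  expect_equal(nchar(p$cterm), 20L)

  expect_message(p41 <- partition_regions(strrep("A", 41)), "excluded")
  expect_null(p41)

  s <- paste(rep(LETTERS[1:25], 4), collapse = "")  # 100-mer
  p100 <- partition_regions(s)
  expect_identical(p100$bulk, substr(s, 21, 80))
})

test_that("position_bias reproduces the 2x2 arithmetic and the printed OR", {
  # terminal frequency 16.2% vs bulk 6.01% at realizing counts
  or <- (162 * (10000 - 601)) / ((1000 - 162) * 601)
  expect_equal(round(or, 2), 3.02)

  # pipe the same counts through a constructed bias table cell
  cells <- data.frame(symbol = "K", position = -1L, obs_count = 162L,
                      obs_total = 1000L, bulk_count = 601L,
                      bulk_total = 10000L)
  bt <- ctermbias:::finish_bias_table(cells, fdr = 0.05, flag_power = FALSE)
  expect_equal(round(bt$odds_ratio, 2), 3.02)
  expect_equal(bt$p_value, oracle_fisher_p(162, 838, 601, 9399))
})

test_that("Fisher p-values equal brute-force hypergeometric enumeration", {
  cases <- rbind(c(3, 7, 10, 90), c(0, 10, 5, 5), c(12, 3, 2, 13),
                 c(1, 0, 0, 1), c(5, 5, 5, 5), c(20, 80, 10, 90))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; b <- cases[i, 2]; c_ <- cases[i, 3]; d <- cases[i, 4]
    expected <- oracle_fisher_p(a, b, c_, d)
    expect_equal(stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                           byrow = TRUE))$p.value,
                 expected, tolerance = 1e-10)
    expect_equal(ctermbias:::fisher_p2(a, b, c_, d), expected,
                 tolerance = 1e-10)
  }
})

test_that("a null proteome yields odds ratios near 1 and almost no calls", {
  tab <- gen_proteome(3000, seed = 21)
  bt <- position_bias(tab, "aa", positions = -5:-1, flag_power = FALSE)
  expect_lte(mean(bt$significant), 0.05)
  lor <- log2(bt$odds_ratio[is.finite(bt$odds_ratio)])
  expect_lt(mean(abs(lor)), 0.25)
})

test_that("per-position counts sum to the number of sequences", {
  tab <- gen_proteome(500, seed = 22)
  bt <- position_bias(tab, "aa", positions = -3:-1, flag_power = FALSE)
  for (p in unique(bt$position)) {
    expect_equal(sum(bt$obs_count[bt$position == p]), bt$obs_total[1])
  }
  # bulk counts are shared across positions
  expect_equal(length(unique(tapply(bt$bulk_count, bt$symbol, unique))), 20L)
})

test_that("BH-corrected calls equal the textbook step-up rule", {
  tab <- gen_proteome(2000, mu = local({
    m <- mu_matrix(); m["K", "-1"] <- 2; m["T", "-1"] <- 0.5; m
  }), seed = 23)
  bt <- position_bias(tab, "aa", positions = -2:-1, flag_power = FALSE)
  expect_setequal(which(bt$significant), oracle_bh_reject(bt$p_value, 0.05))
})

test_that("an injected per-position multiplier is recovered as the OR", {
  mu <- mu_matrix()
  mu["K", "-1"] <- 2.32
  tab <- gen_proteome(8000, mu = mu, seed = 24)
  bt <- position_bias(tab, "aa", positions = -1, flag_power = FALSE)
  expect_equal(bt$odds_ratio[bt$symbol == "K"], 2.32, tolerance = 0.15)
  expect_true(bt$significant[bt$symbol == "K"])
})

test_that("underpowered flag matches a direct search oracle", {
  # plenty of power: common symbol, large terminal sample
  expect_false(flag_underpowered(10000, 500, 10000))
  # expected 0.2 observations: hopeless
  expect_true(flag_underpowered(20, 100, 10000))
  # absent from bulk: no power by construction
  expect_true(flag_underpowered(1000, 0, 5000))

  direct <- function(N, bc, bt) {
    for (m in 1:N) {
      obs <- round(0.5 * m)
      p <- stats::fisher.test(matrix(c(obs, N - obs, bc, bt - bc), 2,
                                     byrow = TRUE))$p.value
      if (p < 0.05) return(N * bc / bt < m)
    }
    TRUE
  }
  for (case in list(c(200, 30, 3000), c(50, 5, 1000), c(500, 100, 2000))) {
    expect_equal(flag_underpowered(case[1], case[2], case[3]),
                 direct(case[1], case[2], case[3]))
  }
})

test_that("dipeptide counts equal hand enumeration on a constructed set", {
  set.seed(31)
  seqs <- vapply(1:30, function(i) {
    paste(sample(c("K", "T", "A"), 45, TRUE), collapse = "")
  }, "")
  bt <- dipeptide_bias(seqs)
  # hand enumeration
  term <- table(substr(seqs, 44, 45))
  for (s in names(term)) {
    expect_equal(bt$obs_count[bt$symbol == s], as.integer(term[[s]]))
  }
  bulk_pairs <- unlist(lapply(seqs, function(s) {
    b <- substr(s, 21, 25)
    substring(b, 1:4, 2:5)
  }))
  expect_equal(bt$bulk_total[1], length(bulk_pairs))
  tb <- table(bulk_pairs)
  for (s in names(tb)) {
    expect_equal(bt$bulk_count[bt$symbol == s], as.integer(tb[[s]]))
  }
})

test_that("a terminal-only dipeptide gets an infinite odds-ratio sentinel", {
  seqs <- vapply(1:10, function(i) {
    paste0(strrep("ATG", 15), "KK")                 # 47-mers ending KK
  }, "")
  bt <- dipeptide_bias(seqs)
  kk <- bt[bt$symbol == "KK", ]
  expect_equal(kk$obs_count, 10L)
  expect_equal(kk$bulk_count, 0L)
  expect_identical(kk$odds_ratio, Inf)
  expect_lt(kk$p_value, 1)
})

test_that("stratified bias on a single group equals the plain computation", {
  tab <- gen_proteome(800, seed = 25)
  grouping <- stats::setNames(rep("all", nrow(tab)), tab$protein_id)
  strat <- stratified_bias(tab, grouping, positions = -1, flag_power = FALSE)
  plain <- position_bias(tab, "aa", positions = -1, flag_power = FALSE)
  expect_equal(strat$all$odds_ratio, plain$odds_ratio)
  expect_equal(strat$all$p_value, plain$p_value)
})

test_that("per-group injected enrichments are recovered separately", {
  mu_a <- mu_matrix(); mu_a["K", "-1"] <- 3
  tab_a <- gen_proteome(4000, mu = mu_a, genome_id = "ga", seed = 26)
  tab_b <- gen_proteome(4000, genome_id = "gb", seed = 27)
  tab_b$protein_id <- paste0("b_", tab_b$protein_id)
  tab <- rbind(tab_a, tab_b)
  class(tab) <- c("gene_table", "data.frame")
  grouping <- stats::setNames(ifelse(tab$genome_id == "ga", "A", "B"),
                              tab$protein_id)
  strat <- stratified_bias(tab, grouping, positions = -1, flag_power = FALSE)
  expect_equal(strat$A$odds_ratio[strat$A$symbol == "K"], 3, tolerance = 0.2)
  expect_equal(strat$B$odds_ratio[strat$B$symbol == "K"], 1, tolerance = 0.2)
})

test_that("unlabeled records are ignored with a count", {
  tab <- gen_proteome(100, seed = 28)
  grouping <- stats::setNames(rep("g", 50), tab$protein_id[1:50])
  expect_message(stratified_bias(tab, grouping, positions = -1,
                                 flag_power = FALSE),
                 "50 unlabeled")
})

test_that("a one-sequence group is fully underpowered", {
  tab <- gen_proteome(5, seed = 29)
  bt <- position_bias(tab[1, , drop = FALSE], "aa", positions = -1)
  expect_true(all(bt$underpowered))
})

test_that("abundance bins follow within-species percentiles", {
  tab <- gen_proteome(10, seed = 30)
  ppm <- data.frame(protein_id = tab$protein_id, ppm = 1:10)
  bins <- abundance_bins(tab, ppm)
  expect_setequal(names(bins)[bins == "low"], tab$protein_id[1:2])
  expect_setequal(names(bins)[bins == "high"], tab$protein_id[9:10])
  expect_setequal(names(bins)[bins == "medium"], tab$protein_id[3:8])
})

test_that("species below the abundance coverage threshold are excluded", {
  tab <- gen_proteome(10, seed = 32)
  ppm <- data.frame(protein_id = tab$protein_id[1:3], ppm = 1:3)  # 30%
  expect_message(bins <- abundance_bins(tab, ppm), "excluded")
  expect_length(bins, 0L)
})

test_that("multiple abundance matches for one protein are averaged", {
  tab <- gen_proteome(5, seed = 33)
  ppm <- data.frame(protein_id = c(tab$protein_id, tab$protein_id[1]),
                    ppm = c(10, 2, 3, 4, 5, 30))
  bins <- abundance_bins(tab, ppm, coverage_min = 0)
  # protein 1 averages to 20: the highest value, hence "high"
  expect_equal(unname(bins[tab$protein_id[1]]), "high")
})

test_that("stop-context classes with no genes are absent", {
  tab <- gen_proteome(200, seed = 34)
  tab$stop_codon <- "TAA"
  sc <- stop_context_bias(tab, flag_power = FALSE)
  expect_identical(names(sc), "TAA")
  plain <- position_bias(tab, "codon", positions = -1, flag_power = FALSE)
  expect_equal(sc$TAA$odds_ratio, plain$odds_ratio)
})

test_that("overlap exclusion removes an injected NNA preference", {
  tab <- gen_proteome(6000, overlap_frac = 0.9, seed = 35)
  with_ov <- stop_context_bias(tab, exclude_overlap = FALSE,
                               flag_power = FALSE)
  without_ov <- suppressMessages(
    stop_context_bias(tab, exclude_overlap = TRUE, flag_power = FALSE))
  c_with <- third_base_comparison(with_ov$TGA)
  c_without <- third_base_comparison(without_ov$TGA)
  shift_with <- c_with$mean_log2_or_a[1] - c_with$mean_log2_or_b[1]
  shift_without <- c_without$mean_log2_or_a[1] - c_without$mean_log2_or_b[1]
  expect_gt(shift_with, 0.3)
  expect_lt(abs(shift_without), shift_with / 2)
})

test_that("third-base contrast detects a known log2 shift", {
  bt <- data.frame(symbol = sense_codons(11),
                   odds_ratio = 1, stringsAsFactors = FALSE)
  set.seed(36)
  lor <- rnorm(nrow(bt), 0, 0.1)
  third_a <- substr(bt$symbol, 3, 3) == "A"
  lor[third_a] <- lor[third_a] + 0.5
  bt$odds_ratio <- 2^lor
  res <- third_base_comparison(bt)
  expect_lt(res$p[res$contrast == "NNA_vs_other"], 1e-4)
  expect_gt(res$mean_log2_or_a[1] - res$mean_log2_or_b[1], 0.3)

  # degenerate case: all odds ratios identical
  bt$odds_ratio <- 1
  res0 <- third_base_comparison(bt)
  expect_equal(res0$t, c(0, 0))
  expect_equal(res0$p, c(1, 1))
})
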
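test_that("triplet selection respects the dS acceptance window", {
  ds3 <- data.frame(species_a = c("a", "a", "b"),
                    species_b = c("b", "c", "c"),
                    dS = c(0.3, 0.45, 0.45))
  got <- select_triplets(ds3)
  expect_equal(nrow(got), 1L)
  expect_setequal(c(got$in1, got$in2), c("a", "b"))
  expect_equal(got$out, "c")

  ds_low <- ds3
  ds_low$dS[1] <- 0.15                   # ingroup below the window
  expect_message(got2 <- select_triplets(ds_low), "no valid triplet")
  expect_equal(nrow(got2), 0L)
})

test_that("triplet selection equals exhaustive scoring on 5 species", {
  set.seed(51)
  sp <- letters[1:5]
  d <- matrix(0, 5, 5, dimnames = list(sp, sp))
  d[upper.tri(d)] <- runif(10, 0.1, 1.2)
  d <- d + t(d)
  long <- data.frame(species_a = sp[row(d)[upper.tri(d)]],
                     species_b = sp[col(d)[upper.tri(d)]],
                     dS = d[upper.tri(d)])
  got <- select_triplets(long)

  # brute force over all (pair, outgroup) combinations
  best <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    din <- d[i, j]
    if (din < 0.2 || din > 1.0) next
    for (o in setdiff(1:5, c(i, j))) {
      if (d[o, i] < 1.2 * din || d[o, i] > 2 * din) next
      if (d[o, j] < 1.2 * din || d[o, j] > 2 * din) next
      cand <- list(in1 = sp[i], in2 = sp[j], out = sp[o],
                   pair_score = abs(din - 0.2),
                   out_score = abs((d[o, i] + d[o, j]) / 2 - 1.5 * din))
      if (is.null(best) || cand$pair_score < best$pair_score ||
          (cand$pair_score == best$pair_score &&
             cand$out_score < best$out_score)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    expect_equal(nrow(got), 0L)
  } else {
    expect_equal(got$in1, best$in1)
    expect_equal(got$in2, best$in2)
    expect_equal(got$out, best$out)
  }
})

test_that("alignment filter looks only at the last three columns", {
  aln <- list(seq_in1 = "MKTAY", seq_in2 = "MKTAY", seq_out = "MKTAY")
  expect_true(filter_alignment(aln))
  gap_last <- list(seq_in1 = "MKTAY", seq_in2 = "MKTAY", seq_out = "MKTA-")
  expect_false(filter_alignment(gap_last))
  gap_internal <- list(seq_in1 = "-KTAY", seq_in2 = "MKTAY",
                       seq_out = "MKTAY")
  expect_true(filter_alignment(gap_internal))
})

test_that("the 3-taxon rule classifies canonical columns correctly", {
  same <- infer_ancestral("K", "K", "K")
  expect_equal(same$status, "no_change")
  expect_equal(same$ancestral, "K")

  sub <- infer_ancestral("K", "T", "K")
  expect_equal(sub$status, "substitution")
  expect_equal(sub$from, "K")
  expect_equal(sub$to, "T")
  expect_equal(sub$branch, 2L)

  sub1 <- infer_ancestral("T", "K", "K")
  expect_equal(sub1$branch, 1L)

  expect_equal(infer_ancestral("K", "R", "T")$status, "excluded")
  expect_equal(infer_ancestral("K", "K", "T")$status, "excluded")
})

test_that("the rule matches minimum-change enumeration on sampled columns", {
  set.seed(52)
  aa <- ctermbias:::AA20
  cols <- cbind(sample(aa, 80, TRUE), sample(aa, 80, TRUE),
                sample(aa, 80, TRUE))
  cols <- rbind(cols, c("K", "K", "K"), c("K", "T", "K"), c("T", "K", "K"),
                c("K", "K", "T"), c("K", "R", "T"))
  got <- infer_ancestral(cols[, 1], cols[, 2], cols[, 3])
  for (i in seq_len(nrow(cols))) {
    oracle <- oracle_parsimony(cols[i, 1], cols[i, 2], cols[i, 3])
    expect_equal(got$status[i], oracle$status)
    if (oracle$status != "excluded") {
      expect_equal(got$ancestral[i], oracle$ancestral)
    }
    if (oracle$status == "substitution") {
      expect_equal(got$branch[i], oracle$branch)
    }
  }
})

test_that("substitution counting attributes events to end-anchored positions", {
  aln <- list(orthogroup_id = "og1",
              seq_in1 = paste0(strrep("A", 24), "K"),
              seq_in2 = paste0(strrep("A", 24), "T"),
              seq_out = paste0(strrep("A", 24), "K"))
  ct <- count_substitutions(list(aln))
  expect_equal(ct$sites["-1", "K"], 1L)
  expect_equal(ct$subs["-1", "K", "T"], 1L)
  expect_equal(sum(ct$subs), 1L)
  expect_equal(ct$sites["-2", "A"], 1L)
  expect_equal(unname(ct$sites["bulk", "A"]), 5L)  # columns -25..-21
})

test_that("site totals conserve the number of countable columns", {
  alns <- gen_triplets(200, len = 30, p_in = 0.05, seed = 53)
  ct <- count_substitutions(alns)
  # every column is ungapped; at each resolved position the site counts must
  # equal the number of alignments minus the excluded columns there
  ev <- attr(alns, "truth")$events
  for (pos in c("-1", "-5")) {
    counted <- sum(ct$sites[pos, ])
    expect_lte(counted, 200L)
    expect_gt(counted, 100L)             # exclusions are the minority
  }
  # totals: each substitution event also counts as a site
  expect_true(all(ct$subs <= array(rep(ct$sites, 20),
                                   dim = c(nrow(ct$sites), 20, 20))))
})

test_that("counts are invariant to alignment order", {
  alns <- gen_triplets(50, len = 20, p_in = 0.1, seed = 54)
  ct1 <- count_substitutions(alns)
  ct2 <- count_substitutions(rev(alns))
  expect_identical(ct1$sites, ct2$sites)
  expect_identical(ct1$subs, ct2$subs)
})

test_that("group rates divide events by ancestral-group sites", {
  labs <- ctermbias:::position_labels(20)
  sites <- matrix(0L, length(labs), 20, dimnames = list(labs,
                                                        ctermbias:::AA20))
  subs <- array(0L, c(length(labs), 20, 20),
                dimnames = list(labs, ctermbias:::AA20, ctermbias:::AA20))
  sites["-1", "K"] <- 100L
  subs["-1", "K", "T"] <- 1L
  ct <- structure(list(sites = sites, subs = subs, max_pos = 20),
                  class = "substitution_counts")
  gr <- group_rates(ct)
  expect_equal(gr$rate[gr$position == "-1" & gr$from_group == "positive" &
                         gr$to_group == "T"], 0.01)
  # empty-denominator rates are missing
  expect_true(is.na(gr$rate[gr$position == "-1" &
                              gr$from_group == "hydrophobic"][1]))
})

test_that("rates from a group sum to its total substitution frequency", {
  alns <- gen_triplets(300, len = 25, p_in = 0.08, seed = 55)
  ct <- count_substitutions(alns)
  gr <- group_rates(ct)
  g1 <- gr[gr$position == "-1" & gr$from_group == "positive", ]
  total <- sum(ct$subs["-1", c("K", "R"), ]) / sum(ct$sites["-1", c("K", "R")])
  expect_equal(sum(g1$rate), total, tolerance = 1e-12)
})

test_that("position comparison reduces to Fisher on the event table", {
  labs <- ctermbias:::position_labels(20)
  sites <- matrix(0L, length(labs), 20, dimnames = list(labs,
                                                        ctermbias:::AA20))
  subs <- array(0L, c(length(labs), 20, 20),
                dimnames = list(labs, ctermbias:::AA20, ctermbias:::AA20))
  sites["-1", "K"] <- 100L; subs["-1", "K", "T"] <- 20L
  sites["-2", "K"] <- 100L; subs["-2", "K", "T"] <- 10L
  ct <- structure(list(sites = sites, subs = subs, max_pos = 20),
                  class = "substitution_counts")
  got <- compare_positions(ct, -1, -2, "positive", "T")
  expect_equal(got$ratio, 2)
  expect_equal(got$p, oracle_fisher_p(20, 80, 10, 90), tolerance = 1e-10)

  subs["-2", "K", "T"] <- 20L
  ct$subs <- subs
  same <- compare_positions(ct, -1, -2, "positive", "T")
  expect_equal(same$ratio, 1)
  expect_equal(same$p, 1)
})

test_that("a doubled substitution rate at -1 is recovered", {
  alns <- gen_triplets(4000, len = 25,
                       p_in = c("-1" = 0.10, bulk = 0.05), seed = 56)
  ct <- count_substitutions(alns)
  freq <- function(pos) sum(ct$subs[pos, , ]) / sum(ct$sites[pos, ])
  expect_equal(freq("-1") / freq("bulk"), 2, tolerance = 0.25)
})

test_that("triplets round-trip through aligned FASTA and a manifest", {
  alns <- gen_triplets(5, len = 15, p_in = 0.1, seed = 57)
  dir <- withr::local_tempdir()
  manifest <- write_triplets(alns, dir)
  back <- load_triplets(manifest)
  for (i in seq_along(alns)) {
    expect_equal(back[[i]]$seq_in1, alns[[i]]$seq_in1)
    expect_equal(back[[i]]$seq_out, alns[[i]]$seq_out)
  }
})
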
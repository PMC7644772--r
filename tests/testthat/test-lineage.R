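# Diagnostic sites, assignment scoring and uncorrected distances

test_that("diagnostic sites follow the fixed-and-different definition", {
  pan <- dplyr::bind_rows(
    toy_panel(c("ACG", "ACG"), c("L1", "L1"), ids = c("a1", "a2")),
    toy_panel(c("ATG", "ATG"), c("L2", "L2"), ids = c("b1", "b2"))
  )
  sites <- find_diagnostic_sites(pan, "16S", "lineage")
  expect_equal(sites$column, 1L)
  expect_equal(sites$L1, "C")
  expect_equal(sites$L2, "T")

  # polymorphism within a group disqualifies the column
  pan2 <- pan
  pan2$seq[2] <- "AAG"
  expect_equal(nrow(find_diagnostic_sites(pan2, "16S", "lineage")), 0)

  # missing characters are ignored when testing monomorphism
  pan3 <- pan
  pan3$seq[1] <- "ANG"
  sites3 <- find_diagnostic_sites(pan3, "16S", "lineage")
  expect_equal(sites3$column, 1L)
  expect_equal(sites3$L1, "C")

  expect_error(find_diagnostic_sites(pan, "16S", "lineage",
                                     focal_groups = c("L1", "LX")),
               "unknown")
})

test_that("every reported site survives brute-force re-verification", {
  sim <- simulate_lineages(sim_config(seed = 19, loci = c("16S" = 300L)))
  pan <- sim$panel
  sites <- find_diagnostic_sites(pan, "16S", "lineage")
  expect_gt(nrow(sites), 0)
  for (col in sites$column) {
    expect_true(oracle_is_diagnostic(pan$seq, pan$lineage, col,
                                     c("L1", "L2")),
                info = sprintf("column %d", col))
  }
  # and no non-reported column is diagnostic
  others <- setdiff(0:299, sites$column)
  truths <- vapply(others, function(col)
    oracle_is_diagnostic(pan$seq, pan$lineage, col, c("L1", "L2")),
    logical(1))
  expect_false(any(truths))
})

test_that("query scoring counts agreements and renders a strict verdict", {
  pan <- dplyr::bind_rows(
    toy_panel(c("ACGTAC", "ACGTAC"), c("L1", "L1"), ids = c("a1", "a2")),
    toy_panel(c("ATGCAT", "ATGCAT"), c("L2", "L2"), ids = c("b1", "b2"))
  )
  sites <- find_diagnostic_sites(pan, "16S", "lineage")
  # columns 1 (C/T), 3 (T/C), 5 (C/T) are diagnostic; verify by enumeration
  expect_equal(sites$column, c(1L, 3L, 5L))
  for (col in 0:5) {
    expect_equal(col %in% sites$column,
                 oracle_is_diagnostic(pan$seq, pan$lineage, col,
                                      c("L1", "L2")))
  }
  # query matches L1 at cols 1 and 3, L2 at col 5 -> (2,1), verdict L1
  rep <- score_query("ACGTAT", sites)
  expect_equal(unname(rep$counts), c(2L, 1L))
  expect_equal(rep$verdict, "L1")

  # query identical to an L1 member: all sites for L1
  rep2 <- score_query(pan$seq[1], sites)
  expect_equal(unname(rep2$counts), c(3L, 0L))
  expect_equal(rep2$verdict, "L1")

  # all-N query is uninformative
  rep3 <- score_query("NNNNNN", sites)
  expect_equal(rep3$n_sites_query_informative, 0L)
  expect_equal(rep3$verdict, "ambiguous")

  # off-pattern states are counted separately
  rep4 <- score_query("AGGTAC", sites)  # col 1 = G matches neither
  expect_equal(rep4$n_off_pattern, 1L)

  # IUPAC ambiguity matches weakly
  rep5 <- score_query("AYGTAC", sites)  # Y = C/T covers both groups: no credit
  expect_equal(sum(rep5$counts), 2L)    # cols 3 and 5 only
  rep6 <- score_query("AMGTAC", sites)  # M = A/C -> matches L1's C, weak
  expect_true(rep6$site_table$weak[rep6$site_table$column == 1])

  expect_error(score_query("ACG", sites), "length")
})

test_that("scoring is invariant to panel sequence order", {
  sim <- simulate_lineages(sim_config(seed = 29, loci = c("16S" = 200L)))
  pan <- sim$panel
  query <- pan$seq[2]
  s1 <- score_query(query, find_diagnostic_sites(pan, "16S", "lineage"))
  shuffled <- pan[sample(nrow(pan)), ]
  s2 <- score_query(query, find_diagnostic_sites(shuffled, "16S", "lineage"))
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$verdict, s2$verdict)
})

test_that("phylogroup-level scoring uses the same machinery", {
  sim <- simulate_lineages(sim_config(seed = 37, loci = c("16S" = 400L),
                                      within_diversity = 0.02))
  pan <- sim$panel
  groups <- unique(pan$phylogroup[pan$lineage == "L1"])
  sites <- find_diagnostic_sites(pan, "16S", level = "phylogroup",
                                 focal_groups = groups)
  if (nrow(sites) > 0) {
    member <- pan[pan$phylogroup == groups[1], ][1, ]
    rep <- score_query(member$seq, sites)
    expect_equal(rep$verdict, groups[1])
  } else {
    succeed("no phylogroup-diagnostic columns at this diversity")
  }
})

test_that("p-distance follows pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACNT", "ACGA"), 1 / 3)
  expect_error(p_distance("ACG", "ACGT"), "length")
  expect_error(p_distance("NNNN", "ACGT"), "comparable")
  # symmetry and range on random pairs
  set.seed(301)
  for (k in 1:20) {
    a <- random_dna(50); b <- random_dna(50)
    expect_equal(p_distance(a, b), p_distance(b, a))
    expect_gte(p_distance(a, b), 0)
    expect_lte(p_distance(a, b), 1)
  }
})

test_that("group distance ranges match brute-force pair enumeration", {
  pan <- dplyr::bind_rows(
    toy_panel(c("AAAA", "AAAT"), c("L1", "L1"), ids = c("a1", "a2")),
    toy_panel(c("TTAA", "TTTT"), c("L2", "L2"), ids = c("b1", "b2"))
  )
  got <- group_distance_range(pan, "16S", "L1", "L2")
  # hand-enumerated: a1-b1 .5, a1-b2 1, a2-b1 .75, a2-b2 .75
  expect_equal(got$min, 0.5)
  expect_equal(got$max, 1)
  expect_equal(got$n_pairs, 4)

  one <- dplyr::bind_rows(toy_panel("ACGT", "L1", ids = "x"),
                          toy_panel("ACGT", "L2", ids = "y"))
  expect_equal(group_distance_range(one, "16S", "L1", "L2")$min, 0)
  expect_error(group_distance_range(one, "16S", "L1", "LZ"), "empty")
})

test_that("simulated 6% lineages yield distances bracketing the target", {
  dists <- purrr::map(1:8, function(k) {
    sim <- simulate_lineages(sim_config(seed = 400 + k,
                                        loci = c("16S" = 500L)))
    group_distance_range(sim$panel, "16S", "L1", "L2")
  }) |> dplyr::bind_rows()
  # founders sit ~2 * 0.03 apart in expectation, within-lineage noise on top
  expected <- oracle_expected_pdist(0.03)
  expect_lt(abs(mean((dists$min + dists$max) / 2) - expected), 0.02)
})
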
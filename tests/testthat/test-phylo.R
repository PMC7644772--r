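# TN93 distances, neighbor-joining and bootstrap supports

test_that("TN93 handles identity, saturation and missing data", {
  a <- random_dna(100)
  expect_equal(tn93_distance(a, a), 0)
  # all-transversion pair saturates the formula
  expect_true(is.nan(tn93_distance(strrep("A", 50), strrep("C", 50))))
  expect_error(tn93_distance("ACG", "ACGT"), "length")
  expect_error(tn93_distance("NNNN", "ACGT"), "comparable")
  # pairwise deletion: N columns are excluded
  expect_equal(tn93_distance("ACGTN", "ACGTA"), 0)
})

test_that("TN93 equals an independent closed-form evaluation to 1e-10", {
  set.seed(501)
  for (k in 1:12) {
    a <- random_dna(500)
    bch <- strsplit(a, "")[[1]]
    for (i in sample(500, 35)) bch[i] <- sample(c("A", "C", "G", "T"), 1)
    b <- paste(bch, collapse = "")
    pr <- oracle_pair_props(a, b)
    expect_equal(tn93_distance(a, b),
                 oracle_tn93(pr$P1, pr$P2, pr$Q, pr$freqs),
                 tolerance = 1e-10)
    # gamma-corrected variant against the same oracle
    expect_equal(tn93_distance(a, b, gamma_shape = 0.5),
                 oracle_tn93(pr$P1, pr$P2, pr$Q, pr$freqs, gamma_shape = 0.5),
                 tolerance = 1e-10)
    # and against ape's implementation as an external cross-check
    m <- matrix(c(strsplit(tolower(a), "")[[1]],
                  strsplit(tolower(b), "")[[1]]), nrow = 2, byrow = TRUE)
    ape_d <- ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                           pairwise.deletion = TRUE)
    expect_equal(tn93_distance(a, b), as.numeric(ape_d), tolerance = 1e-8)
  }
})

test_that("TN93 is never below the p-distance where defined", {
  set.seed(502)
  for (k in 1:25) {
    a <- random_dna(300)
    bch <- strsplit(a, "")[[1]]
    for (i in sample(300, sample(5:60, 1)))
      bch[i] <- sample(c("A", "C", "G", "T"), 1)
    b <- paste(bch, collapse = "")
    d <- tn93_distance(a, b)
    if (!is.nan(d)) expect_gte(d, p_distance(a, b) - 1e-12)
  }
})

test_that("TN93 degenerates continuously as the transition classes equalise", {
  # two pairs whose purine/pyrimidine transition counts differ by one
  # column should give nearly identical distances
  set.seed(503)
  base <- strsplit(random_dna(400), "")[[1]]
  mk_pair <- function(n_ag, n_ct) {
    b <- base
    a_pos <- which(base == "A")[seq_len(n_ag)]
    c_pos <- which(base == "C")[seq_len(n_ct)]
    b[a_pos] <- "G"; b[c_pos] <- "T"
    paste(b, collapse = "")
  }
  d1 <- tn93_distance(paste(base, collapse = ""), mk_pair(10, 9))
  d2 <- tn93_distance(paste(base, collapse = ""), mk_pair(9, 10))
  expect_lt(abs(d1 - d2), 0.002)
})

test_that("NJ recovers simple and additive matrices exactly", {
  # two taxa: single edge split evenly
  D2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- nj_tree(D2)
  expect_equal(sum(t2$edge.length), 0.3)

  # four taxa with additive distances from a known tree
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.05);")
  D4 <- cophenetic(tr)
  rec <- nj_tree(D4)
  expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
               ignore_attr = TRUE)
  expect_equal(max(abs(cophenetic(rec)[rownames(D4), colnames(D4)] - D4)),
               0, tolerance = 1e-10)

  # equidistant taxa: all internal branch lengths 0
  De <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  te <- nj_tree(De)
  internal <- te$edge[, 2] > length(te$tip.label)
  expect_true(all(abs(te$edge.length[internal]) < 1e-12))

  # undefined entries are refused with the pair named
  Dn <- D4; Dn["A", "C"] <- Dn["C", "A"] <- NaN
  expect_error(nj_tree(Dn), "A.*C|C.*A")
})

test_that("NJ recovers random 5-8 leaf trees from their additive matrices", {
  set.seed(504)
  for (k in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = function(x) runif(x, 0.05, 0.4))
    tr <- ape::unroot(tr)
    D <- cophenetic(tr)
    rec <- nj_tree(D)
    expect_equal(ape::dist.topo(tr, rec), 0, ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(rec)[rownames(D), colnames(D)] - D)), 1e-8)
  }
})

test_that("bootstrap gives 100% support when every column agrees", {
  set.seed(505)
  # constant columns plus columns that all split {a1,a2} vs {b1,b2}:
  # every informative column supports the same bipartition
  n_const <- 180; n_split <- 20
  const_part <- random_dna(n_const)
  a_seq <- paste0(const_part, strrep("A", n_split))
  b_seq <- paste0(const_part, strrep("G", n_split))
  seqs <- c(a1 = a_seq, a2 = a_seq, b1 = b_seq, b2 = b_seq)
  tr <- bootstrap_tree(seqs, replicates = 100, seed = 8)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 100))
  expect_error(bootstrap_tree(seqs, replicates = 0), "replicates")
})

test_that("bootstrap supports are deterministic and order-invariant", {
  sim <- simulate_lineages(sim_config(seed = 41, loci = c("16S" = 300L),
                                      within_diversity = 0.02))
  seqs <- setNames(sim$panel$seq, sim$panel$id)
  t1 <- bootstrap_tree(seqs, replicates = 60, seed = 5)
  t2 <- bootstrap_tree(seqs, replicates = 60, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  perm <- sample(length(seqs))
  t3 <- bootstrap_tree(seqs[perm], replicates = 60, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t3))

  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("the true lineage split earns high support on simulated panels", {
  sim <- simulate_lineages(sim_config(seed = 43, loci = c("16S" = 500L)))
  seqs <- setNames(sim$panel$seq, sim$panel$id)
  tr <- bootstrap_tree(seqs, replicates = 100, seed = 3)
  # find the edge splitting L1 from L2 members
  l1 <- sort(sim$panel$id[sim$panel$lineage == "L1"])
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(p) paste(sort(labs[p]), collapse = "|"),
                 character(1))
  l2 <- sort(setdiff(labs, l1))
  idx <- which(keys == paste(l1, collapse = "|") |
                 keys == paste(l2, collapse = "|"))
  expect_gt(length(idx), 0)
  sup <- suppressWarnings(as.numeric(tr$node.label[idx]))
  expect_true(any(sup >= 90, na.rm = TRUE))
})
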
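# Read placement and majority consensus calling

test_that("exact substrings are placed at their true coordinates", {
  set.seed(101)
  ref <- random_dna(200)
  read <- make_read(substr(ref, 11, 60))  # 0-based start 10, length 50
  pl <- place_reads(read, ref)
  expect_equal(pl$start, 10L)
  expect_equal(pl$end, 60L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$states, substr(ref, 11, 60))

  rc <- make_read(revcomp(substr(ref, 11, 60)), id = "r2")
  pl2 <- place_reads(rc, ref)
  expect_equal(pl2$start, 10L)
  expect_equal(pl2$end, 60L)
  expect_equal(pl2$strand, "-")
  expect_equal(pl2$states, pl$states)
})

test_that("an internal deletion appears as deletion states at the right columns", {
  set.seed(102)
  ref <- random_dna(160)
  # pin distinct bases around the deletion so the optimal gap placement
  # is unique (no co-optimal slide)
  substr(ref, 40, 43) <- "ACGT"
  # remove reference columns 41..42 (1-based) from an exact 60-nt read
  full <- substr(ref, 21, 80)
  delread <- paste0(substr(full, 1, 20), substr(full, 23, 60))
  pl <- place_reads(make_read(delread), ref)
  expect_equal(pl$start, 20L)
  expect_equal(pl$end, 80L)
  st <- strsplit(pl$states, "")[[1]]
  expect_equal(which(st == "-"), c(21L, 22L))
  expect_equal(paste(st[st != "-"], collapse = ""), delread)
})

test_that("read insertions are dropped so the consensus stays in reference frame", {
  set.seed(103)
  ref <- random_dna(160)
  full <- substr(ref, 21, 80)
  insread <- paste0(substr(full, 1, 30), "ACGT", substr(full, 31, 60))
  pl <- place_reads(make_read(insread), ref)
  expect_equal(pl$end - pl$start, nchar(pl$states))
  expect_equal(nchar(pl$states), 60L)
})

test_that("majority calling follows the strict-majority and tie rules", {
  ref <- "ACGTACGTAC"
  mk_pl <- function(states, start = 0L) {
    tibble::tibble(read_id = sprintf("p%d", seq_along(states)),
                   start = start, end = start + nchar(states[1]),
                   strand = "+", states = states)
  }
  # {A,A,T} at depth 3 -> A
  cons <- build_consensus(mk_pl(c("A", "A", "T")), ref, min_depth = 3)
  expect_equal(substr(cons$called, 1, 1), "A")
  # {A,T} tie at depth 2 -> N
  cons2 <- build_consensus(mk_pl(c("A", "T")), ref, min_depth = 2)
  expect_equal(substr(cons2$called, 1, 1), "N")
  # coverage below min_depth -> N even if unanimous
  cons3 <- build_consensus(mk_pl(c("A", "A")), ref, min_depth = 3)
  expect_equal(substr(cons3$called, 1, 1), "N")
  # a deletion can win the majority and counts as recovered
  cons4 <- build_consensus(mk_pl(c("-", "-", "A")), ref, min_depth = 3)
  expect_equal(substr(cons4$called, 1, 1), "-")
  expect_equal(cons4$recovered_nt, 1L)
  # IUPAC mode turns a two-base tie into the ambiguity code
  cons5 <- build_consensus(mk_pl(c("A", "A", "G", "G")), ref,
                           min_depth = 2, iupac = TRUE)
  expect_equal(substr(cons5$called, 1, 1), "R")
})

test_that("identical full-length reads reproduce their sequence exactly", {
  set.seed(104)
  ref <- random_dna(120)
  span <- substr(ref, 31, 90)
  reads <- dplyr::bind_rows(purrr::map(1:10, function(i)
    make_read(span, id = sprintf("r%d", i))))
  pl <- place_reads(reads, ref)
  cons <- build_consensus(pl, ref)
  expect_equal(substr(cons$called, 31, 90), span)
  expect_equal(cons$recovered_nt, 60L)
  expect_equal(cons$missing_runs$length, c(30L, 30L))
  expect_equal(cons$max_coverage, 10L)
})

test_that("per-column tallies equal a brute-force recount (simulated reads)", {
  cfg <- sim_config(seed = 17, n_reads = 50, error_rate = 0.01,
                    deam_rate = 0.3, contam_fraction = 0,
                    loci = c("16S" = 300L))
  sim <- simulate_lineages(cfg)
  src <- sim$panel[1, ]
  out <- degrade_and_read(src, cfg)
  pl <- place_reads(out$reads, src)
  cons <- build_consensus(pl, src)
  states <- c("A", "C", "G", "T", "-")
  for (col in seq(0, 299, by = 13)) {
    tal <- oracle_column_tally(pl, col)
    expect_equal(cons$coverage[col + 1], sum(tal),
                 info = sprintf("column %d", col))
  }
  # full coverage profile also matches the brute-force recount
  brute_cov <- vapply(0:299, function(col) sum(oracle_column_tally(pl, col)),
                      numeric(1))
  expect_equal(cons$coverage, as.integer(brute_cov))
})

test_that("adding a read never decreases any column's coverage", {
  set.seed(105)
  ref <- random_dna(150)
  reads <- substring_reads(ref, 12, len = 40)
  pl <- place_reads(reads, ref)
  cov_prev <- rep(0L, 150)
  for (k in seq_len(nrow(pl))) {
    cons <- build_consensus(pl[1:k, ], ref, min_depth = 1)
    expect_true(all(cons$coverage >= cov_prev))
    cov_prev <- cons$coverage
  }
})

test_that("error-free reads at sufficient depth reconstruct the source exactly", {
  cfg <- sim_config(seed = 23, n_reads = 120, error_rate = 0, deam_rate = 0,
                    contam_fraction = 0, loci = c("16S" = 250L))
  sim <- simulate_lineages(cfg)
  src <- sim$panel[1, ]
  out <- degrade_and_read(src, cfg)
  pl <- place_reads(out$reads, src)
  cons <- build_consensus(pl, src, min_depth = 3)
  called <- strsplit(cons$called, "")[[1]]
  truth <- strsplit(src$seq, "")[[1]]
  covered <- which(called != "N")
  expect_gt(length(covered), 0)
  expect_equal(called[covered], truth[covered])
})

test_that("consensus stats report missing runs in order with their lengths", {
  set.seed(106)
  ref <- random_dna(442)
  # covered stretches mirror a partly recovered barcode: N at [0,89),
  # [200,326) and [432,442)
  mk <- function(a, b) make_read(substr(ref, a + 1, b),
                                 id = sprintf("s%d", a))
  reads <- dplyr::bind_rows(
    purrr::map(1:4, function(i) { r <- mk(89, 200); r$id <- paste0(r$id, i); r }),
    purrr::map(1:4, function(i) { r <- mk(326, 432); r$id <- paste0(r$id, i); r })
  )
  pl <- place_reads(reads, ref)
  cons <- build_consensus(pl, ref, min_depth = 3)
  stats <- consensus_stats(cons)
  expect_equal(cons$missing_runs$length, c(89L, 126L, 10L))
  expect_equal(cons$missing_runs$start, c(0L, 200L, 432L))
  expect_equal(stats$recovered_nt, 442L - 89L - 126L - 10L)
  expect_equal(stats$recovered_nt + sum(cons$missing_runs$length),
               stats$alignment_length)

  # degenerate cases
  all_n <- build_consensus(pl[0, ], ref)
  expect_equal(all_n$recovered_nt, 0L)
  expect_equal(nrow(all_n$missing_runs), 1)
  expect_equal(all_n$missing_runs$length, 442L)
  full <- build_consensus(place_reads(dplyr::bind_rows(
    purrr::map(1:3, function(i) make_read(ref, id = paste0("f", i)))), ref), ref)
  expect_equal(nrow(full$missing_runs), 0)
})
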
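# Synthetic archival-read generator. Emulates the situation the pipeline is
# built for: a degraded museum extract sequenced as short single-end reads
# (75 cycles), with fragments much shorter than the locus, terminal
# C->T / G->A deamination damage, uniform sequencing error, off-target
# contamination and reference stretches with no coverage at all.

#' Configuration for the archival-read simulator
#'
#' Defaults describe the scenario the package targets: a single ~500 nt
#' mitochondrial barcode locus, two candidate lineages diverged ~6%
#' (each founder 3% from their common ancestor), five reference individuals
#' per lineage, 75 nt single-end reads from short fragments, mild sequencing
#' error, strong terminal deamination and 10% contamination.
#'
#' @param seed integer seed; every stochastic step is deterministic given it.
#' @param loci named integer vector: ancestor length (nt) per locus.
#' @param n_lineages number of candidate lineages (>= 1).
#' @param between_divergence expected substitutions/site on each
#'   ancestor-to-founder branch; two founders are therefore expected to
#'   differ at about twice this rate (~6% with the default 0.03).
#' @param within_diversity expected substitutions/site between a lineage
#'   founder and each of its members.
#' @param members_per_lineage reference individuals simulated per lineage.
#' @param fragment_mean,fragment_sd normal fragment-length parameters (nt);
#'   draws are truncated to \[20, source length\].
#' @param read_length sequencing read length (nt); the read is the first
#'   `read_length` bases of the fragment.
#' @param n_reads number of reads to emit per call to [degrade_and_read()].
#' @param error_rate per-base probability of a uniform sequencing error.
#' @param deam_rate probability of C->T at the fragment 5' terminus (and
#'   G->A at the 3' terminus).
#' @param deam_decay exponential decay length (positions) of the
#'   deamination probability away from the fragment end.
#' @param contam_fraction proportion of reads drawn from contaminant
#'   sequences instead of the target.
#' @param coverage_dropout list of 0-based half-open reference intervals
#'   (`c(start, end)`) from which no target fragment is sampled.
#' @param revcomp_fraction proportion of reads emitted as the reverse
#'   complement of their fragment (default 0: forward strand only).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       loci = c("16S" = 501L),
                       n_lineages = 2L,
                       between_divergence = 0.03,
                       within_diversity = 0.005,
                       members_per_lineage = 5L,
                       fragment_mean = 60,
                       fragment_sd = 15,
                       read_length = 75L,
                       n_reads = 170L,
                       error_rate = 0.002,
                       deam_rate = 0.2,
                       deam_decay = 3,
                       contam_fraction = 0.10,
                       coverage_dropout = list(),
                       revcomp_fraction = 0) {
  cfg <- list(
    seed = as.integer(seed), loci = loci, n_lineages = as.integer(n_lineages),
    between_divergence = between_divergence, within_diversity = within_diversity,
    members_per_lineage = as.integer(members_per_lineage),
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    read_length = as.integer(read_length), n_reads = as.integer(n_reads),
    error_rate = error_rate, deam_rate = deam_rate, deam_decay = deam_decay,
    contam_fraction = contam_fraction, coverage_dropout = coverage_dropout,
    revcomp_fraction = revcomp_fraction
  )
  probs <- c(cfg$error_rate, cfg$deam_rate, cfg$contam_fraction,
             cfg$revcomp_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (cfg$fragment_mean <= 0) abort("fragment_mean must be > 0")
  if (cfg$n_lineages < 1) abort("n_lineages must be >= 1")
  if (is.null(names(cfg$loci)) || any(names(cfg$loci) == "")) {
    abort("loci must be a named vector of ancestor lengths")
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# substitute each site with probability `rate`, uniformly to one of the
# other three bases (Jukes-Cantor-style process)
mutate_seq <- function(seq, rate) {
  ch <- str_split(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a labelled reference panel of diverged lineages
#'
#' Per locus, a random ancestor is drawn; each lineage founder is mutated
#' from the ancestor at `between_divergence` substitutions/site (uniform
#' substitution process), and each member from its founder at
#' `within_diversity`. Members of each lineage are split into two
#' phylogroups (labelled e.g. `L1.1`, `L1.2`) so phylogroup-level scoring
#' can be exercised.
#'
#' @param cfg a [sim_config()].
#' @return A list with `panel` (labelled sequence tibble, see
#'   [attach_labels()]) and `tree` (the true [ape::phylo] genealogy:
#'   lineage founders radiating from the ancestor, members from founders).
#' @export
simulate_lineages <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    panel <- purrr::imap(cfg$loci, function(len, locus) {
      ancestor <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      purrr::map(seq_len(cfg$n_lineages), function(l) {
        founder <- mutate_seq(ancestor, cfg$between_divergence)
        lineage <- paste0("L", l)
        half <- ceiling(cfg$members_per_lineage / 2)
        purrr::map(seq_len(cfg$members_per_lineage), function(m) {
          tibble(
            id = sprintf("%s_%s_m%d", locus, lineage, m),
            seq = mutate_seq(founder, cfg$within_diversity),
            locus = locus,
            species = paste0("sp_", lineage),
            lineage = lineage,
            phylogroup = paste0(lineage, ".", ((m - 1) %/% half) + 1)
          )
        }) |> bind_rows()
      }) |> bind_rows()
    }) |> bind_rows()
    validate_panel(panel)
    tree <- true_tree(panel, cfg)
    list(panel = panel, tree = tree)
  })
}

# genealogy used by the simulator: members radiate from founders, founders
# from the ancestor; branch lengths are the expected substitution rates
true_tree <- function(panel, cfg) {
  locus1 <- names(cfg$loci)[1]
  sub <- panel[panel$locus == locus1, ]
  clades <- vapply(unique(sub$lineage), function(l) {
    tips <- sub$id[sub$lineage == l]
    sprintf("(%s):%g",
            paste(sprintf("%s:%g", tips, cfg$within_diversity), collapse = ","),
            cfg$between_divergence)
  }, character(1))
  if (length(clades) == 1) {
    nwk <- sprintf("%s;", clades[[1]])
  } else {
    nwk <- sprintf("(%s);", paste(clades, collapse = ","))
  }
  ape::read.tree(text = nwk)
}

#' Fragment, damage and sequence a source into synthetic archival reads
#'
#' Fragments are sampled uniformly along the source (outside
#' `coverage_dropout` intervals for target reads), with normal lengths
#' truncated to \[20, source length\]. Deamination is applied to the
#' fragment with per-position probability `deam_rate * exp(-i/deam_decay)`:
#' C->T at distance `i` from the 5' end, G->A at distance `i` from the 3'
#' end. The read is the first `read_length` bases of the (possibly
#' reverse-complemented) damaged fragment, then uniform sequencing errors
#' are applied at `error_rate`. A `contam_fraction` of reads is drawn from
#' `contaminants` instead of `source`. Base qualities are constant Q37.
#'
#' @param source a single-row sequence tibble (or list with `id`, `seq`)
#'   to sequence from.
#' @param cfg a [sim_config()].
#' @param contaminants optional sequence tibble of contaminant sources;
#'   required if `contam_fraction > 0`.
#' @param seed overrides `cfg$seed` (useful for replicate runs).
#' @return A list with `reads` (tibble: `id`, `bases`, `quals`) and `truth`
#'   (tibble: `id`, `source` ("target"/"contaminant"), `source_id`,
#'   `frag_start`, `frag_end` (0-based half-open on the source), `strand`,
#'   `deam_positions` (list col, 1-based positions in the emitted read),
#'   `error_positions` (list col)).
#' @export
degrade_and_read <- function(source, cfg, contaminants = NULL,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  src_seq <- source$seq[[1]]
  src_id <- source$id[[1]]
  if (str_length(src_seq) < cfg$fragment_mean) {
    abort("source shorter than fragment_mean")
  }
  if (cfg$contam_fraction > 0 &&
      (is.null(contaminants) || nrow(contaminants) == 0)) {
    abort("contam_fraction > 0 but no contaminants supplied")
  }
  with_seed(seed, {
    out <- purrr::map(seq_len(cfg$n_reads), function(k) {
      is_contam <- runif(1) < cfg$contam_fraction
      if (is_contam) {
        j <- sample.int(nrow(contaminants), 1)
        s_seq <- contaminants$seq[[j]]
        s_id <- contaminants$id[[j]]
      } else {
        s_seq <- src_seq
        s_id <- src_id
      }
      slen <- str_length(s_seq)
      flen <- max(20L, min(slen, round(rnorm(1, cfg$fragment_mean,
                                             cfg$fragment_sd))))
      start <- sample_fragment_start(
        slen, flen,
        dropout = if (is_contam) list() else cfg$coverage_dropout
      )
      frag <- str_sub(s_seq, start + 1, start + flen)
      ch <- str_split(frag, "")[[1]]
      # terminal deamination: C->T from the 5' end, G->A from the 3' end
      i5 <- seq_along(ch) - 1L
      i3 <- rev(i5)
      p5 <- cfg$deam_rate * exp(-i5 / cfg$deam_decay)
      p3 <- cfg$deam_rate * exp(-i3 / cfg$deam_decay)
      u <- runif(length(ch))
      hit5 <- ch == "C" & u < p5
      hit3 <- ch == "G" & u < p3
      ch[hit5] <- "T"
      ch[hit3] <- "A"
      deam_frag <- which(hit5 | hit3)
      strand <- if (runif(1) < cfg$revcomp_fraction) "-" else "+"
      emitted <- paste(ch, collapse = "")
      if (strand == "-") {
        emitted <- revcomp(emitted)
        deam_frag <- length(ch) + 1L - deam_frag
      }
      rl <- min(cfg$read_length, flen)
      bases <- str_sub(emitted, 1, rl)
      deam_read <- sort(deam_frag[deam_frag <= rl])
      bch <- str_split(bases, "")[[1]]
      err <- which(runif(rl) < cfg$error_rate)
      for (i in err) bch[i] <- sample(setdiff(BASES, bch[i]), 1)
      tibble(
        id = sprintf("read%05d", k),
        bases = paste(bch, collapse = ""),
        quals = strrep(rawToChar(as.raw(37L + 33L)), rl),
        source = if (is_contam) "contaminant" else "target",
        source_id = s_id,
        frag_start = start, frag_end = start + flen,
        strand = strand,
        deam_positions = list(as.integer(deam_read)),
        error_positions = list(as.integer(err))
      )
    }) |> bind_rows()
    list(
      reads = out[, c("id", "bases", "quals")],
      truth = out[, c("id", "source", "source_id", "frag_start", "frag_end",
                      "strand", "deam_positions", "error_positions")]
    )
  })
}

# uniform fragment start avoiding dropout intervals (0-based half-open);
# falls back to any position if no valid start exists
sample_fragment_start <- function(slen, flen, dropout = list()) {
  starts <- 0:(slen - flen)
  if (length(dropout)) {
    ok <- rep(TRUE, length(starts))
    for (iv in dropout) {
      ok <- ok & (starts + flen <= iv[1] | starts >= iv[2])
    }
    if (any(ok)) starts <- starts[ok]
  }
  starts[sample.int(length(starts), 1)]
}

#' Write a simulated read set and its truth to disk
#'
#' @param sim result of [degrade_and_read()].
#' @param fastq,json output paths for the reads (FASTQ) and truth (JSON).
#' @param cfg optional [sim_config()] echoed into the truth JSON.
#' @return invisibly, a list of the two paths.
#' @export
write_simulation <- function(sim, fastq, json, cfg = NULL) {
  write_fastq(sim$reads, fastq)
  truth <- sim$truth
  payload <- list(truth = truth)
  if (!is.null(cfg)) payload$config <- unclass(cfg)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  invisible(list(fastq = fastq, json = json))
}
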
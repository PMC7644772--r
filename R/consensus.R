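# Reference-guided majority consensus. Reads are placed with a semi-global
# alignment (read fully aligned, reference locally), read insertions are
# dropped so the consensus lives in reference coordinates, and each column
# is called by strict majority over a minimum depth.

#' Place reads on a reference (semi-global alignment)
#'
#' Each read (or its reverse complement, whichever scores better) is
#' aligned end-to-end against a local stretch of the reference under the
#' fishing scoring scheme. Read insertions relative to the reference are
#' dropped; reference positions deleted in the read are recorded as
#' deletion states (`-`).
#'
#' @param reads read tibble (`id`, `bases`, ...), e.g. the `hits` of a
#'   [fish_reads()] result filtered to one locus.
#' @param reference a single reference sequence (character scalar) or a
#'   one-row panel tibble.
#' @param score_floor placements with alignment score below this are
#'   rejected (returned in the `rejected` attribute). Default 0.
#' @return placement tibble: `read_id`, `start`, `end` (0-based half-open,
#'   reference frame), `strand`, `states` (string over A/C/G/T/N/`-`, one
#'   character per reference column covered).
#' @export
place_reads <- function(reads, reference, score_floor = 0) {
  if (is.data.frame(reference)) reference <- reference$seq[[1]]
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  states = character(0)))
  }
  place_one_strand <- function(seqs) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(seqs),
      subject = Biostrings::DNAString(reference),
      type = "global-local", substitutionMatrix = sub_matrix(),
      gapOpening = 2, gapExtension = 1
    )
  }
  fw <- place_one_strand(reads$bases)
  rv <- place_one_strand(revcomp(reads$bases))
  use_rv <- Biostrings::score(rv) > Biostrings::score(fw)
  score_best <- ifelse(use_rv, Biostrings::score(rv), Biostrings::score(fw))

  # aligned() projects the pattern into subject coordinates: insertions
  # relative to the reference are already dropped, deleted reference
  # positions appear as '-'
  states_of <- function(aln) {
    a <- as.character(Biostrings::aligned(aln))
    substr(a, IRanges::start(Biostrings::subject(aln)),
           IRanges::end(Biostrings::subject(aln)))
  }
  st_fw <- states_of(fw)
  st_rv <- states_of(rv)
  start_fw <- IRanges::start(Biostrings::subject(fw)) - 1L
  start_rv <- IRanges::start(Biostrings::subject(rv)) - 1L
  states <- ifelse(use_rv, st_rv, st_fw)
  start <- ifelse(use_rv, start_rv, start_fw)
  keep <- score_best >= score_floor
  out <- tibble(
    read_id = reads$id[keep],
    start = as.integer(start[keep]),
    end = as.integer(start[keep] + nchar(states[keep])),
    strand = ifelse(use_rv[keep], "-", "+"),
    states = states[keep]
  )
  attr(out, "rejected") <- reads$id[!keep]
  out
}

#' Build a majority consensus from read placements
#'
#' Per reference column, non-N states are tallied; coverage is the tally
#' total. The state with the strictly greatest count is called iff its
#' count exceeds `majority_fraction` of the coverage and coverage reaches
#' `min_depth`; otherwise the column is `N` (exact ties are never called,
#' unless `iupac = TRUE`, when a two-base tie becomes the IUPAC code).
#' A called deletion (`-`) counts as a recovered position.
#'
#' @param placements placement tibble from [place_reads()].
#' @param reference the reference sequence (character scalar or one-row
#'   panel tibble) the placements refer to.
#' @param min_depth minimum coverage for a call (default 3).
#' @param majority_fraction required majority, strict (default 0.5).
#' @param iupac emit IUPAC codes for two-base exact ties? Default FALSE.
#' @param locus optional locus name carried into the result.
#' @return An object of class `consensus_result`: list with `locus`,
#'   `called` (string of reference length over A/C/G/T/IUPAC/N/`-`),
#'   `coverage` (integer vector), `recovered_nt`, `alignment_length`,
#'   `missing_runs` (tibble `start`, `end`, `length`; 0-based half-open),
#'   `max_coverage`, `n_placements`.
#' @export
build_consensus <- function(placements, reference, min_depth = 3L,
                            majority_fraction = 0.5, iupac = FALSE,
                            locus = NA_character_) {
  if (is.data.frame(reference)) {
    if (is.na(locus) && "locus" %in% names(reference)) {
      locus <- reference$locus[[1]]
    }
    reference <- reference$seq[[1]]
  }
  L <- str_length(reference)
  states <- c("A", "C", "G", "T", "-")
  tallies <- matrix(0L, nrow = length(states), ncol = L,
                    dimnames = list(states, NULL))
  for (i in seq_len(nrow(placements))) {
    st <- str_split(placements$states[i], "")[[1]]
    cols <- (placements$start[i] + 1L):(placements$end[i])
    if (length(st) != length(cols) || any(cols > L) || any(cols < 1)) {
      abort(sprintf("placement '%s' inconsistent with reference length",
                    placements$read_id[i]))
    }
    for (s in states) {
      w <- cols[st == s]
      if (length(w)) tallies[s, w] <- tallies[s, w] + 1L
    }
  }
  coverage <- as.integer(colSums(tallies))
  called <- rep("N", L)
  for (j in seq_len(L)) {
    tot <- coverage[j]
    if (tot < min_depth || tot == 0L) next
    mx <- max(tallies[, j])
    top <- states[tallies[, j] == mx]
    if (length(top) == 1 && mx / tot > majority_fraction) {
      called[j] <- top
    } else if (iupac && length(top) == 2 && !"-" %in% top) {
      code <- names(IUPAC_CODES)[match(
        paste(sort(top), collapse = ""),
        vapply(IUPAC_CODES, function(x)
          paste(sort(str_split(x, "")[[1]]), collapse = ""), character(1))
      )]
      if (!is.na(code)) called[j] <- code
    }
  }
  called_str <- paste(called, collapse = "")
  runs <- missing_runs(called)
  structure(list(
    locus = locus,
    called = called_str,
    coverage = coverage,
    recovered_nt = sum(called != "N"),
    alignment_length = L,
    missing_runs = runs,
    max_coverage = if (L) max(coverage) else 0L,
    n_placements = nrow(placements),
    reference = reference
  ), class = "consensus_result")
}

# runs of N in a called character vector, as 0-based half-open intervals
missing_runs <- function(called) {
  r <- rle(called == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(start = starts[r$values], end = ends[r$values],
         length = r$lengths[r$values])
}

#' Recovery and coverage statistics of a consensus
#'
#' @param result a [build_consensus()] result.
#' @return a list (JSON-ready): `locus`, `recovered_nt`,
#'   `alignment_length`, `recovery_fraction`, `missing_runs` (start, end,
#'   length of each N run, in order), `max_coverage`, and per covered
#'   segment the min/mean/max depth.
#' @export
consensus_stats <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  called <- str_split(result$called, "")[[1]]
  segs <- {
    r <- rle(called != "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    tibble(start = starts[r$values], end = ends[r$values])
  }
  seg_stats <- purrr::pmap(segs, function(start, end) {
    d <- result$coverage[(start + 1):end]
    list(start = start, end = end, min_depth = min(d),
         mean_depth = mean(d), max_depth = max(d))
  })
  list(
    locus = result$locus,
    recovered_nt = result$recovered_nt,
    alignment_length = result$alignment_length,
    recovery_fraction = result$recovered_nt / result$alignment_length,
    n_placements = result$n_placements,
    missing_runs = purrr::pmap(result$missing_runs, function(start, end, length) {
      list(start = start, end = end, length = length)
    }),
    max_coverage = result$max_coverage,
    covered_segments = seg_stats
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result%s> %d/%d nt recovered, %d missing run(s), max coverage %d\n",
    if (is.na(x$locus)) "" else paste0(" ", x$locus),
    x$recovered_nt, x$alignment_length, nrow(x$missing_runs), x$max_coverage
  ))
  invisible(x)
}
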
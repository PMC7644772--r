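# "Barcode fishing": quality/adapter trimming followed by retention of the
# reads whose best local-alignment identity against any panel reference
# reaches a similarity threshold (default 90%), each retained read being
# assigned to the locus of its best reference.

#' Configuration for read trimming and fishing
#'
#' @param similarity_threshold minimum best-hit identity (matches /
#'   alignment columns) for a read to be retained. Default 0.90.
#' @param min_aligned_length minimum alignment columns for an alignment to
#'   count at all (shorter alignments score identity 0). Default 30.
#' @param min_read_length_after_trim reads shorter than this after trimming
#'   are discarded. Default 25.
#' @param quality_window,quality_threshold sliding-window 3' quality trim:
#'   at the first window (length `quality_window`) whose mean phred falls
#'   below `quality_threshold`, the read is cut at the first sub-threshold
#'   base within that window.
#' @param adapter optional 3' adapter sequence to remove.
#' @param dedupe collapse reads with identical (bases, strand, start)?
#'   Default `FALSE`: clonal reads are kept, as appropriate for a
#'   majority-based assembly.
#' @return a list of class `fishing_config`.
#' @export
fishing_config <- function(similarity_threshold = 0.90,
                           min_aligned_length = 30L,
                           min_read_length_after_trim = 25L,
                           quality_window = 5L,
                           quality_threshold = 20,
                           adapter = NULL,
                           dedupe = FALSE) {
  if (similarity_threshold < 0 || similarity_threshold > 1) {
    abort("similarity_threshold must lie in [0,1]")
  }
  structure(list(
    similarity_threshold = similarity_threshold,
    min_aligned_length = as.integer(min_aligned_length),
    min_read_length_after_trim = as.integer(min_read_length_after_trim),
    quality_window = as.integer(quality_window),
    quality_threshold = quality_threshold,
    adapter = if (is.null(adapter)) NULL else str_to_upper(adapter),
    dedupe = isTRUE(dedupe)
  ), class = "fishing_config")
}

# scoring scheme shared by fishing and placement:
# match +1, mismatch -1, gap open -2, gap extend -1
# (a gap of length k costs 2 + k)
SUB_MATRIX <- NULL

sub_matrix <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = FALSE)
  m
}

#' Trim reads: 3' adapter removal then sliding-window quality trim
#'
#' An adapter suffix is removed when a read suffix matches a prefix of the
#' adapter over >= 8 nt with at most one mismatch per 10 nt of overlap
#' (longest qualifying overlap wins). Then the 3' end is cut at the first
#' sliding window of `quality_window` bases whose mean phred is below
#' `quality_threshold` (the cut lands on the first sub-threshold base in
#' that window). Reads shorter than `min_read_length_after_trim` are
#' discarded.
#'
#' @param reads read tibble (`id`, `bases`, `quals`).
#' @param cfg a [fishing_config()].
#' @return the trimmed read tibble (possibly fewer rows).
#' @export
trim_reads <- function(reads, cfg = fishing_config()) {
  if (nrow(reads) == 0) return(reads)
  trimmed <- purrr::pmap(reads[, c("id", "bases", "quals")], function(id, bases, quals) {
    n <- nchar(bases)
    # adapter removal
    if (!is.null(cfg$adapter)) {
      ad <- cfg$adapter
      best <- 0L
      for (ov in seq(min(n, nchar(ad)), 8L)) {
        if (ov < 8L) break
        rs <- str_sub(bases, n - ov + 1, n)
        ap <- str_sub(ad, 1, ov)
        mm <- sum(str_split(rs, "")[[1]] != str_split(ap, "")[[1]])
        if (mm <= ov %/% 10) { best <- ov; break }
      }
      if (best > 0L) {
        n <- n - best
        bases <- str_sub(bases, 1, n)
        quals <- str_sub(quals, 1, n)
      }
    }
    # sliding-window quality trim
    q <- phred_decode(quals)[[1]]
    w <- cfg$quality_window
    if (n >= w) {
      means <- vapply(seq_len(n - w + 1),
                      function(s) mean(q[s:(s + w - 1)]), numeric(1))
      low <- which(means < cfg$quality_threshold)
      if (length(low)) {
        s <- low[1]
        firstbad <- s + which(q[s:n] < cfg$quality_threshold)[1] - 1L
        cut <- if (is.na(firstbad)) s else firstbad
        n <- cut - 1L
        bases <- str_sub(bases, 1, n)
        quals <- str_sub(quals, 1, n)
      }
    }
    if (n < cfg$min_read_length_after_trim) return(NULL)
    tibble(id = id, bases = bases, quals = quals)
  })
  bind_rows(trimmed)
}

# best local alignments of many patterns against one subject; returns
# identity (matches / alignment columns), aligned columns and subject start
align_local_many <- function(patterns, subject) {
  if (length(patterns) == 0) {
    return(tibble(score = numeric(0), identity = numeric(0),
                  aligned_length = integer(0), sub_start = integer(0)))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = sub_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  # identity = exact matches / alignment columns (gaps and mismatches count
  # in the denominator; N never counts as a match)
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  tibble(
    score = Biostrings::score(aln),
    identity = ifelse(cols > 0, matches / cols, 0),
    aligned_length = as.integer(cols),
    sub_start = as.integer(IRanges::start(Biostrings::subject(aln)))
  )
}

#' Similarity of one read to one reference (both strands)
#'
#' Best local alignment of the read and of its reverse complement against
#' the reference under the fishing scoring scheme (match +1, mismatch -1,
#' gap open -2, gap extend -1). Identity is matches / alignment columns,
#' counting mismatch and gap columns in the denominator. Alignments shorter
#' than `min_aligned_length` columns get identity 0.
#'
#' @param bases read sequence (character scalar).
#' @param reference reference sequence (character scalar).
#' @param cfg a [fishing_config()].
#' @return one-row tibble: `identity`, `strand` ("+"/"-"), `aligned_length`.
#' @export
similarity <- function(bases, reference, cfg = fishing_config()) {
  stopifnot(nchar(bases) > 0)
  fw <- align_local_many(bases, reference)
  rv <- align_local_many(revcomp(bases), reference)
  hit <- if (rv$score[1] > fw$score[1]) mutate(rv, strand = "-") else
    mutate(fw, strand = "+")
  hit$identity[hit$aligned_length < cfg$min_aligned_length] <- 0
  hit[, c("identity", "strand", "aligned_length")]
}

#' Fish reads against a reference panel
#'
#' Trims each read, scores it against every reference of every locus on
#' both strands, and retains it iff its best identity reaches
#' `similarity_threshold`. Each retained read is assigned to the locus of
#' its best-scoring reference (ties broken by panel locus order).
#'
#' @param reads read tibble (`id`, `bases`, `quals`).
#' @param panel labelled reference panel (see [attach_labels()]).
#' @param cfg a [fishing_config()].
#' @param trim apply [trim_reads()] first? Default `TRUE`.
#' @return An object of class `fishing_result`: list with
#'   * `hits`: tibble of retained reads (`id`, `bases`, `quals`, `locus`,
#'     `ref_id`, `identity`, `strand`, `aligned_length`, `sub_start`),
#'   * `counts`: list with `total_input`, `removed_by_trimming`,
#'     `retained_total` and `retained_by_locus` (named integer vector).
#' @export
fish_reads <- function(reads, panel, cfg = fishing_config(), trim = TRUE) {
  validate_panel(panel)
  loci <- unique(panel$locus)
  total <- nrow(reads)
  kept <- if (trim) trim_reads(reads, cfg) else reads
  removed_trim <- total - nrow(kept)
  if (nrow(kept) == 0) {
    hits <- tibble(id = character(0), bases = character(0),
                   quals = character(0), locus = character(0),
                   ref_id = character(0), identity = numeric(0),
                   strand = character(0), aligned_length = integer(0),
                   sub_start = integer(0))
    return(structure(list(
      hits = hits,
      counts = list(total_input = total, removed_by_trimming = removed_trim,
                    retained_total = 0L,
                    retained_by_locus = setNames(integer(length(loci)), loci))
    ), class = "fishing_result"))
  }
  rc <- revcomp(kept$bases)
  best <- NULL
  for (r in seq_len(nrow(panel))) {
    fw <- align_local_many(kept$bases, panel$seq[r])
    rv <- align_local_many(rc, panel$seq[r])
    use_rv <- rv$score > fw$score
    cand <- fw
    cand[use_rv, ] <- rv[use_rv, ]
    cand$strand <- ifelse(use_rv, "-", "+")
    cand$identity[cand$aligned_length < cfg$min_aligned_length] <- 0
    cand$ref_id <- panel$id[r]
    cand$locus <- panel$locus[r]
    cand$locus_rank <- match(panel$locus[r], loci)
    if (is.null(best)) {
      best <- cand
    } else {
      # strictly better identity wins; ties keep the earlier locus
      repl <- cand$identity > best$identity
      best[repl, ] <- cand[repl, ]
    }
  }
  keep_idx <- which(best$identity >= cfg$similarity_threshold &
                      best$identity > 0)
  hits <- dplyr::bind_cols(
    kept[keep_idx, c("id", "bases", "quals")],
    best[keep_idx, c("locus", "ref_id", "identity", "strand",
                     "aligned_length", "sub_start")]
  )
  if (cfg$dedupe && nrow(hits)) {
    hits <- dplyr::distinct(hits, .data$bases, .data$strand, .data$sub_start,
                            .keep_all = TRUE)
  }
  by_locus <- setNames(integer(length(loci)), loci)
  if (nrow(hits)) {
    tb <- table(factor(hits$locus, levels = loci))
    by_locus[names(tb)] <- as.integer(tb)
  }
  structure(list(
    hits = hits,
    counts = list(
      total_input = total,
      removed_by_trimming = removed_trim,
      retained_total = nrow(hits),
      retained_by_locus = by_locus
    )
  ), class = "fishing_result")
}

#' @export
print.fishing_result <- function(x, ...) {
  c <- x$counts
  cat(sprintf(
    "<fishing_result> %d reads in, %d removed by trimming, %d retained\n",
    c$total_input, c$removed_by_trimming, c$retained_total
  ))
  for (l in names(c$retained_by_locus)) {
    cat(sprintf("  %s: %d reads\n", l, c$retained_by_locus[[l]]))
  }
  invisible(x)
}
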
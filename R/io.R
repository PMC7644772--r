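# Readers and writers for the standard formats the pipeline touches:
# FASTA (reference panels, consensus), FASTQ phred+33 (reads), TSV label
# maps, Newick (trees). Sequence tables are plain tibbles so they pipe.

#' Read a FASTA file into a sequence tibble
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `id` (text before the first whitespace of
#'   each header) and `seq` (upper-cased residues; wrapped lines are
#'   concatenated). Label columns (`locus`, `species`, `lineage`,
#'   `phylogroup`) are left empty and filled by [attach_labels()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*$", lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(id = character(0), seq = character(0)))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) {
    abort(sprintf("malformed FASTA: line %d is not a header", keep[1]))
  }
  empty_hdr <- is_hdr & nchar(trimws(sub("^>", "", lines))) == 0
  if (any(empty_hdr)) {
    abort(sprintf("malformed FASTA: empty header at line %d",
                  keep[which(empty_hdr)[1]]))
  }
  grp <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste0, character(1), collapse = "")
  seqs <- seqs[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  no_seq <- which(seqs == "")
  if (length(no_seq)) {
    abort(sprintf("malformed FASTA: record '%s' has no sequence", ids[no_seq[1]]))
  }
  # validate with line numbers
  body_lines <- which(!is_hdr)
  for (j in body_lines) {
    ch <- str_split(str_to_upper(lines[j]), "")[[1]]
    bad <- which(!ch %in% REF_ALPHABET)
    if (length(bad)) {
      abort(sprintf("illegal character '%s' at line %d, column %d",
                    ch[bad[1]], keep[j], bad[1]))
    }
  }
  tibble(id = unname(ids), seq = normalise_seq(unname(seqs)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs tibble with columns `id` and `seq`.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(str_sub(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read single-end FASTQ (phred+33) into a read tibble
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `id`, `bases` (upper-cased, A/C/G/T/N) and
#'   `quals` (phred+33 string, same length as `bases`).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    return(tibble(id = character(0), bases = character(0), quals = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    abort("malformed FASTQ: line count not a multiple of 4")
  }
  idx <- seq(1, length(lines), by = 4)
  if (any(!startsWith(lines[idx], "@"))) {
    abort(sprintf("malformed FASTQ: record at line %d does not start with '@'",
                  idx[which(!startsWith(lines[idx], "@"))[1]]))
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  bases <- str_to_upper(lines[idx + 1])
  quals <- lines[idx + 3]
  mism <- which(nchar(bases) != nchar(quals))
  if (length(mism)) {
    abort(sprintf(
      "malformed FASTQ: sequence/quality length mismatch for read '%s' (line %d)",
      ids[mism[1]], idx[mism[1]]
    ))
  }
  bases <- normalise_seq(bases, alphabet = READ_ALPHABET, what = "read")
  ph <- phred_decode(quals)
  bad <- which(vapply(ph, function(p) any(p < 0 | p > 93), logical(1)))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ: phred score out of [0,93] in read '%s'",
                  ids[bad[1]]))
  }
  tibble(id = ids, bases = bases, quals = quals)
}

#' Write a read tibble to FASTQ (phred+33)
#'
#' @param reads tibble with columns `id`, `bases`, `quals`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads)) {
    stopifnot(all(nchar(reads$bases) == nchar(reads$quals)))
  }
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$bases
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$quals
  writeLines(out, path)
  invisible(path)
}

#' Attach lineage labels to sequences, building a reference panel
#'
#' Joins a TSV label map (columns `id`, `locus`, `species`, `lineage`,
#' `phylogroup`) onto a sequence tibble. The result is the package's
#' reference-panel representation: one row per reference sequence, grouped
#' by `locus`, with all sequences of one locus aligned to equal length.
#'
#' @param seqs tibble from [read_fasta()] (columns `id`, `seq`).
#' @param label_table path to a TSV file, or a data frame with the columns
#'   above.
#' @return A tibble with columns `id`, `seq`, `locus`, `species`, `lineage`,
#'   `phylogroup`, ordered by locus then id. Ids present in the table but
#'   absent from `seqs` are reported in the `unmatched_ids` attribute (and a
#'   warning). Sequences without a table entry are dropped with a warning.
#' @export
attach_labels <- function(seqs, label_table) {
  lab <- if (is.character(label_table)) {
    readr::read_tsv(label_table, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    tibble::as_tibble(label_table)
  }
  need <- c("id", "locus", "species", "lineage", "phylogroup")
  miss <- setdiff(need, names(lab))
  if (length(miss)) {
    abort(sprintf("label table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(lab$id)) {
    abort(sprintf("duplicate id in label table: %s",
                  lab$id[duplicated(lab$id)][1]))
  }
  unmatched <- setdiff(lab$id, seqs$id)
  if (length(unmatched)) {
    warn(sprintf("%d label-table id(s) not found among sequences: %s",
                 length(unmatched), paste(unmatched, collapse = ", ")))
  }
  unlabelled <- setdiff(seqs$id, lab$id)
  if (length(unlabelled)) {
    warn(sprintf("%d sequence(s) without label entry dropped: %s",
                 length(unlabelled), paste(unlabelled, collapse = ", ")))
  }
  panel <- seqs |>
    dplyr::select("id", "seq") |>
    dplyr::inner_join(lab[, need], by = "id") |>
    dplyr::arrange(.data$locus, .data$id)
  validate_panel(panel)
  attr(panel, "unmatched_ids") <- unmatched
  panel
}

#' Validate a reference-panel tibble
#'
#' Checks the alignment-length invariant: within each locus all sequences
#' have equal length, and at least one locus is present.
#' @param panel a panel tibble (see [attach_labels()]).
#' @return `panel`, invisibly; aborts on violation.
#' @export
validate_panel <- function(panel) {
  stopifnot(all(c("id", "seq", "locus") %in% names(panel)))
  if (nrow(panel) == 0) abort("panel has no sequences")
  bad <- panel |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(nlen = dplyr::n_distinct(str_length(.data$seq))) |>
    dplyr::filter(.data$nlen > 1)
  if (nrow(bad)) {
    abort(sprintf("unequal alignment lengths within locus '%s'", bad$locus[1]))
  }
  invisible(panel)
}

#' Write a tree to Newick, with bootstrap supports as internal-node labels
#'
#' Branch lengths are rounded to 6 decimals; integer supports (if present in
#' `tree$node.label`) are written as internal-node labels.
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    stopifnot(all(is.finite(tree$edge.length)), all(tree$edge.length >= 0))
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
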
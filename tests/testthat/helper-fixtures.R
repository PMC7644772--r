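# Programmatic fixtures shared across test files.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# a tiny two-lineage, one-locus labelled panel built by hand
toy_panel <- function(seqs, lineage, locus = "16S",
                      phylogroup = lineage, ids = NULL) {
  ids <- ids %||% sprintf("ref%02d", seq_along(seqs))
  tibble::tibble(
    id = ids, seq = seqs, locus = locus,
    species = paste0("sp_", lineage), lineage = lineage,
    phylogroup = phylogroup
  )
}

# reads that are exact substrings of `source`, tiled at fixed offsets
substring_reads <- function(source, n, len = 40, q = 37, prefix = "r") {
  L <- nchar(source)
  starts <- ((seq_len(n) - 1) * 7) %% (L - len) + 1
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_len(n)),
    bases = substr(rep(source, n), starts, starts + len - 1),
    quals = strrep(rawToChar(as.raw(q + 33L)), len)
  )
}

make_read <- function(bases, q = 37, id = "r1") {
  tibble::tibble(id = id, bases = bases,
                 quals = strrep(rawToChar(as.raw(q + 33L)), nchar(bases)))
}

# read with explicit per-base qualities
make_read_q <- function(bases, quals, id = "r1") {
  tibble::tibble(id = id, bases = bases,
                 quals = rawToChar(as.raw(quals + 33L)))
}

measurements_path <- function() {
  system.file("extdata", "mantidactylus_measurements.tsv",
              package = "barcodefish")
}

localities_path <- function() {
  system.file("extdata", "mantidactylus_localities.tsv",
              package = "barcodefish")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
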
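# End-to-end orchestration: fish -> place -> consensus -> diagnostic-site
# scoring -> distance trees, producing a machine-readable run report whose
# structure mirrors how such analyses are reported (per-stage read counts,
# per-locus recovery, per-lineage agreement counts, tree supports).

#' Run the whole barcode-fishing pipeline
#'
#' @param reads read tibble (`id`, `bases`, `quals`) or a FASTQ path.
#' @param panel labelled panel tibble (see [attach_labels()]) or a list
#'   `list(fasta = , labels = )` of paths.
#' @param fishing a [fishing_config()].
#' @param min_depth,majority_fraction consensus parameters
#'   (see [build_consensus()]).
#' @param level label level for diagnostic-site scoring (default
#'   `"lineage"`).
#' @param focal_groups groups to compare; default: all groups at `level`.
#' @param consensus_ref named character vector locus -> reference id to
#'   guide placement; default: the first panel sequence of each locus.
#' @param bootstrap_replicates bootstrap replicates for the placement tree
#'   (default 1000; 0 skips tree building).
#' @param gamma_shape optional gamma shape for TN93+G distances.
#' @param seed integer seed for the bootstrap.
#' @param output_dir if non-NULL, intermediates (per-locus FASTQ, consensus
#'   FASTA, coverage TSV, Newick, report JSON) are written there.
#' @return An object of class `run_report`: list with `config`, `counts`,
#'   per-locus `consensus` stats, `assignment` reports, `distance_range`,
#'   `trees` (Newick strings), `verdict` (per locus and `combined`),
#'   `version` and `wall_clock_s`. The combined verdict is the shared
#'   per-locus verdict, `"conflicting"` if informative loci disagree and
#'   `"ambiguous"` if none is informative.
#' @export
run_pipeline <- function(reads, panel,
                         fishing = fishing_config(),
                         min_depth = 3L, majority_fraction = 0.5,
                         level = "lineage", focal_groups = NULL,
                         consensus_ref = NULL,
                         bootstrap_replicates = 1000L,
                         gamma_shape = NULL,
                         seed = 1L,
                         output_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.list(panel) && !is.data.frame(panel)) {
    panel <- attach_labels(read_fasta(panel$fasta), panel$labels)
  }
  validate_panel(panel)
  loci <- unique(panel$locus)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }

  fished <- fish_reads(reads, panel, fishing)

  per_locus <- purrr::map(loci, function(lc) {
    sub_panel <- panel[panel$locus == lc, ]
    ref_id <- consensus_ref[[lc]] %||% sub_panel$id[1]
    reference <- sub_panel[sub_panel$id == ref_id, ]
    if (nrow(reference) == 0) {
      abort(sprintf("consensus reference '%s' not in locus '%s'", ref_id, lc))
    }
    locus_reads <- fished$hits[fished$hits$locus == lc, ]
    placements <- place_reads(locus_reads, reference)
    cons <- build_consensus(placements, reference,
                            min_depth = min_depth,
                            majority_fraction = majority_fraction,
                            locus = lc)
    groups <- focal_groups %||% unique(sub_panel[[level]])
    report <- if (length(groups) >= 2) {
      sites <- find_diagnostic_sites(sub_panel, lc, level = level,
                                     focal_groups = groups)
      score_query(cons, sites)
    } else NULL
    drange <- if (length(groups) == 2) {
      group_distance_range(sub_panel, lc, groups[1], groups[2], level = level)
    } else NULL
    tree <- NULL
    if (bootstrap_replicates > 0 && cons$recovered_nt > 0 &&
        nrow(sub_panel) >= 2) {
      aln <- c(setNames(sub_panel$seq, sub_panel$id),
               setNames(cons$called, paste0("query_", lc)))
      tree <- tryCatch(
        bootstrap_tree(aln, replicates = bootstrap_replicates,
                       seed = seed, gamma_shape = gamma_shape),
        error = function(e) {
          warn(sprintf("tree skipped for locus %s: %s", lc, conditionMessage(e)))
          NULL
        }
      )
    }
    if (!is.null(output_dir)) {
      write_fastq(locus_reads, file.path(output_dir, paste0(lc, ".fastq")))
      write_fasta(tibble(id = paste0("consensus_", lc), seq = cons$called),
                  file.path(output_dir, paste0(lc, "_consensus.fasta")))
      readr::write_tsv(tidy(cons),
                       file.path(output_dir, paste0(lc, "_coverage.tsv")))
      if (!is.null(tree)) {
        write_newick(tree, file.path(output_dir, paste0(lc, ".nwk")))
      }
    }
    list(locus = lc, consensus = cons, assignment = report,
         distance_range = drange, tree = tree)
  })
  names(per_locus) <- loci

  verdicts <- purrr::map_chr(per_locus, function(x) {
    if (is.null(x$assignment)) "ambiguous" else x$assignment$verdict
  })
  informative <- verdicts[verdicts != "ambiguous"]
  combined <- if (length(informative) == 0) {
    "ambiguous"
  } else if (length(unique(informative)) == 1) {
    unique(informative)
  } else {
    "conflicting"
  }

  report <- structure(list(
    config = list(
      fishing = unclass(fishing), min_depth = min_depth,
      majority_fraction = majority_fraction, level = level,
      focal_groups = focal_groups,
      bootstrap_replicates = bootstrap_replicates,
      gamma_shape = gamma_shape, seed = seed
    ),
    counts = fished$counts,
    consensus = purrr::map(per_locus, ~consensus_stats(.x$consensus)),
    assignment = purrr::map(per_locus, function(x) {
      if (is.null(x$assignment)) return(NULL)
      a <- x$assignment
      list(locus = a$locus, level = a$level,
           counts = as.list(a$counts),
           n_sites_total = a$n_sites_total,
           n_sites_query_informative = a$n_sites_query_informative,
           n_off_pattern = a$n_off_pattern,
           verdict = a$verdict)
    }),
    distance_range = purrr::map(per_locus, function(x) {
      if (is.null(x$distance_range)) NULL else as.list(x$distance_range)
    }),
    trees = purrr::map(per_locus, function(x) {
      if (is.null(x$tree)) NULL else ape::write.tree(x$tree)
    }),
    verdict = c(as.list(verdicts), combined = combined),
    objects = per_locus,
    version = as.character(packageVersion("barcodefish")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "run_report")

  if (!is.null(output_dir)) {
    write_report_json(report, file.path(output_dir, "report.json"))
  }
  report
}

#' Serialise a run report to JSON
#'
#' Everything except the in-memory `objects` (re-derivable from the
#' written intermediates) is serialised; byte-identical for identical
#' config and seed apart from `wall_clock_s`.
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- unclass(report)
  out$objects <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Render a run report as human-readable Markdown
#'
#' @param report a [run_pipeline()] result, or the path to a report JSON.
#' @return a single Markdown string.
#' @export
render_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  out <- c("# Barcode-fishing run report", "")
  c0 <- report$counts
  out <- c(out, "## Read accounting", "",
           sprintf("- total input reads: %s", c0$total_input),
           sprintf("- removed by trimming: %s", c0$removed_by_trimming),
           sprintf("- retained at similarity threshold: %s", c0$retained_total))
  for (l in names(c0$retained_by_locus)) {
    out <- c(out, sprintf("  - %s: %s", l, c0$retained_by_locus[[l]]))
  }
  out <- c(out, "", "## Consensus recovery", "")
  for (cs in report$consensus) {
    out <- c(out, sprintf(
      "- %s: %s of %s nt recovered (%d missing run(s), max coverage %s)",
      cs$locus, cs$recovered_nt, cs$alignment_length,
      length(cs$missing_runs), cs$max_coverage))
  }
  out <- c(out, "", "## Diagnostic-site assignment", "")
  for (a in report$assignment) {
    if (is.null(a)) next
    counts <- paste(sprintf("%s: %s", names(a$counts), unlist(a$counts)),
                    collapse = ", ")
    out <- c(out, sprintf(
      "- %s (%s level): %s informative of %s sites (%s off-pattern); agreements %s; verdict **%s**",
      a$locus, a$level, a$n_sites_query_informative, a$n_sites_total,
      a$n_off_pattern, counts, a$verdict))
  }
  v <- report$verdict
  comb <- v$combined
  flag <- if (identical(comb, "conflicting")) " **** LOCI CONFLICT ****" else ""
  out <- c(out, "", sprintf("## Combined verdict: **%s**%s", comb, flag), "")
  for (d in report$distance_range) {
    if (is.null(d)) next
    out <- c(out, sprintf(
      "- between-group uncorrected distance range: %.1f%% to %.1f%% (%s pairs)",
      100 * d$min, 100 * d$max, d$n_pairs))
  }
  trees <- report$trees
  if (length(trees) && any(!vapply(trees, is.null, logical(1)))) {
    out <- c(out, "", "## Trees (Newick, bootstrap % on internal nodes)", "")
    for (l in names(trees)) {
      if (!is.null(trees[[l]])) {
        out <- c(out, sprintf("- %s: `%s`", l, trees[[l]]))
      }
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report(x), "\n")
  invisible(x)
}
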
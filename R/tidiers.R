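# broom-style tidiers and ggplot2 visualisations for the result objects.

#' Tidy a fishing result into its per-read hit table
#' @param x a [fish_reads()] result.
#' @param ... unused.
#' @return tibble: one row per retained read with `id`, `locus`, `ref_id`,
#'   `identity`, `strand`, `aligned_length`.
#' @method tidy fishing_result
#' @export
tidy.fishing_result <- function(x, ...) {
  x$hits[, c("id", "locus", "ref_id", "identity", "strand", "aligned_length")]
}

#' One-row summary of a fishing result
#' @param x a [fish_reads()] result.
#' @param ... unused.
#' @return tibble: `total_input`, `removed_by_trimming`, `retained_total`,
#'   `n_loci`.
#' @method glance fishing_result
#' @export
glance.fishing_result <- function(x, ...) {
  tibble(
    total_input = x$counts$total_input,
    removed_by_trimming = x$counts$removed_by_trimming,
    retained_total = x$counts$retained_total,
    n_loci = sum(x$counts$retained_by_locus > 0)
  )
}

#' Tidy a consensus into a per-position table
#' @param x a [build_consensus()] result.
#' @param ... unused.
#' @return tibble: `position` (0-based), `ref_base`, `call`, `depth`.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(
    position = seq_len(x$alignment_length) - 1L,
    ref_base = str_split(x$reference, "")[[1]],
    call = str_split(x$called, "")[[1]],
    depth = x$coverage
  )
}

#' One-row summary of a consensus
#' @param x a [build_consensus()] result.
#' @param ... unused.
#' @return tibble: `locus`, `recovered_nt`, `alignment_length`,
#'   `recovery_fraction`, `n_missing_runs`, `max_coverage`, `n_placements`.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    locus = x$locus,
    recovered_nt = x$recovered_nt,
    alignment_length = x$alignment_length,
    recovery_fraction = x$recovered_nt / x$alignment_length,
    n_missing_runs = nrow(x$missing_runs),
    max_coverage = x$max_coverage,
    n_placements = x$n_placements
  )
}

#' Tidy an assignment report into its site table
#' @param x a [score_query()] result.
#' @param ... unused.
#' @return tibble: one row per diagnostic site with the group states, the
#'   query call and which group (if any) it matched.
#' @method tidy assignment_report
#' @export
tidy.assignment_report <- function(x, ...) {
  x$site_table
}

#' One-row summary of an assignment report
#' @param x a [score_query()] result.
#' @param ... unused.
#' @return tibble with the per-group agreement counts (`agree_<group>`),
#'   site totals and `verdict`.
#' @method glance assignment_report
#' @export
glance.assignment_report <- function(x, ...) {
  counts <- setNames(as.list(x$counts), paste0("agree_", names(x$counts)))
  tibble(
    locus = x$locus, level = x$level, !!!counts,
    n_sites_total = x$n_sites_total,
    n_sites_query_informative = x$n_sites_query_informative,
    n_off_pattern = x$n_off_pattern,
    verdict = x$verdict
  )
}

#' Coverage-and-calls plot for a consensus
#'
#' Per-position read depth along the reference, with missing (N) stretches
#' shaded.
#' @param object a [build_consensus()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- tidy(object)
  runs <- object$missing_runs
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_col(width = 1, fill = "grey35")
  if (nrow(runs)) {
    p <- p + ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end - 0.5),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p + ggplot2::labs(
    x = "reference position (0-based)", y = "read depth",
    title = if (is.na(object$locus)) "consensus coverage" else
      sprintf("%s: %d/%d nt recovered", object$locus,
              object$recovered_nt, object$alignment_length)
  ) + ggplot2::theme_minimal()
}

#' Diagnostic-site agreement plot
#'
#' One tile per diagnostic column showing each group's fixed state and the
#' query call, coloured by which group the query agrees with.
#' @param object a [score_query()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot assignment_report
#' @export
autoplot.assignment_report <- function(object, ...) {
  st <- object$site_table
  if (nrow(st) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "no diagnostic sites") +
             ggplot2::theme_void())
  }
  groups <- names(object$counts)
  long <- tidyr::pivot_longer(
    st[, c("column", groups, "query_state", "matched_group")],
    cols = dplyr::all_of(c(groups, "query_state")),
    names_to = "row", values_to = "state"
  ) |>
    mutate(row = factor(.data$row, levels = c(rev(groups), "query_state"),
                        labels = c(rev(groups), "query")))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$column), y = .data$row, label = .data$state,
    fill = ifelse(.data$row == "query",
                  ifelse(is.na(.data$matched_group), "none",
                         .data$matched_group), "panel")
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(size = 3) +
    ggplot2::scale_fill_brewer(palette = "Pastel1", name = "query agrees with") +
    ggplot2::labs(x = "alignment column (0-based)", y = NULL,
                  title = sprintf("verdict: %s", object$verdict)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
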
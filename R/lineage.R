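# Lineage-diagnostic positions and assignment scoring: find alignment
# columns fixed-and-different between candidate groups, score a partial
# query consensus at those columns, and compute uncorrected group
# distances.

#' Find lineage-diagnostic alignment columns in a labelled panel
#'
#' A column is diagnostic iff, ignoring missing characters (N/?/-), every
#' focal group is monomorphic at it and the group states are pairwise
#' distinct. Columns where any focal group has no non-missing member are
#' skipped.
#'
#' @param panel labelled panel tibble (see [attach_labels()]).
#' @param locus locus to analyse.
#' @param level label level to partition by: `"lineage"`, `"phylogroup"`
#'   or `"species"`.
#' @param focal_groups character vector of two or more group labels at
#'   that level.
#' @return A tibble of class `diagnostic_sites`: one row per site with
#'   `column` (0-based) and `group`/`state` in long form is available via
#'   [tidy()]; the returned wide form has `column` plus one column per
#'   focal group holding that group's fixed state. Attributes `locus`,
#'   `level`, `groups` and `alignment_length` are set.
#' @export
find_diagnostic_sites <- function(panel, locus, level = "lineage",
                                  focal_groups = NULL) {
  validate_panel(panel)
  stopifnot(level %in% c("species", "lineage", "phylogroup"))
  sub <- panel[panel$locus == locus, ]
  if (nrow(sub) == 0) abort(sprintf("no sequences for locus '%s'", locus))
  labels <- sub[[level]]
  if (is.null(focal_groups)) focal_groups <- unique(labels)
  unknown <- setdiff(focal_groups, labels)
  if (length(unknown)) {
    abort(sprintf("unknown %s label(s): %s", level,
                  paste(unknown, collapse = ", ")))
  }
  if (length(focal_groups) < 2) abort("need at least two focal groups")
  m <- seq_matrix(sub$seq, sub$id)
  L <- ncol(m)
  group_rows <- lapply(focal_groups, function(g) which(labels == g))
  sites <- list()
  for (j in seq_len(L)) {
    states <- character(length(focal_groups))
    ok <- TRUE
    for (k in seq_along(focal_groups)) {
      vals <- m[group_rows[[k]], j]
      vals <- vals[!vals %in% MISSING_CHARS]
      u <- unique(vals)
      if (length(u) != 1) { ok <- FALSE; break }
      states[k] <- u
    }
    if (ok && anyDuplicated(states) == 0) {
      sites[[length(sites) + 1]] <-
        c(list(column = j - 1L), setNames(as.list(states), focal_groups))
    }
  }
  out <- if (length(sites)) bind_rows(lapply(sites, tibble::as_tibble)) else
    tibble(column = integer(0))
  for (g in focal_groups) if (!g %in% names(out)) out[[g]] <- character(0)
  attr(out, "locus") <- locus
  attr(out, "level") <- level
  attr(out, "groups") <- focal_groups
  attr(out, "alignment_length") <- L
  class(out) <- c("diagnostic_sites", class(out))
  out
}

#' Score a partial query against diagnostic sites
#'
#' For each site where the query has a call, the group whose fixed state
#' the query matches is credited; query states matching none of the focal
#' groups' states are counted off-pattern. IUPAC ambiguity in the query
#' matches a group iff the group's state lies in the ambiguity set; such
#' matches are flagged weak. The verdict is the group with a strict
#' majority of agreements, else `"ambiguous"`.
#'
#' @param query a [build_consensus()] result, or a character sequence in
#'   the same alignment frame as the panel locus.
#' @param sites a [find_diagnostic_sites()] result.
#' @return An object of class `assignment_report`: list with `counts`
#'   (named integer vector per group), `site_table` (tibble: `column`,
#'   group states, `query_state`, `matched_group`, `weak`),
#'   `n_sites_total`, `n_sites_query_informative`, `n_off_pattern`,
#'   `verdict`, `level`, `locus`.
#' @export
score_query <- function(query, sites) {
  stopifnot(inherits(sites, "diagnostic_sites"))
  qseq <- if (inherits(query, "consensus_result")) query$called else query
  L <- attr(sites, "alignment_length")
  if (str_length(qseq) != L) {
    abort(sprintf("query length %d does not match alignment length %d",
                  str_length(qseq), L))
  }
  groups <- attr(sites, "groups")
  qch <- str_split(str_to_upper(qseq), "")[[1]]
  counts <- setNames(integer(length(groups)), groups)
  rows <- purrr::pmap(sites, function(column, ...) {
    states <- unlist(list(...))[groups]
    q <- qch[column + 1]
    informative <- !q %in% MISSING_CHARS
    matched <- NA_character_
    weak <- FALSE
    if (informative) {
      exact <- groups[states == q]
      if (length(exact) == 1) {
        matched <- exact
      } else if (q %in% names(IUPAC_CODES) && nchar(IUPAC_CODES[[q]]) > 1) {
        amb <- str_split(IUPAC_CODES[[q]], "")[[1]]
        hit <- groups[states %in% amb]
        if (length(hit) == 1) { matched <- hit; weak <- TRUE }
      }
    }
    tibble(column = column, !!!setNames(as.list(states), groups),
           query_state = q, informative = informative,
           matched_group = matched, weak = weak)
  })
  site_table <- bind_rows(rows)
  if (nrow(site_table)) {
    tb <- table(factor(site_table$matched_group, levels = groups))
    counts[names(tb)] <- as.integer(tb)
  }
  n_inf <- if (nrow(site_table)) sum(site_table$informative) else 0L
  off <- n_inf - sum(counts)
  verdict <- "ambiguous"
  if (any(counts > 0)) {
    mx <- max(counts)
    top <- groups[counts == mx]
    if (length(top) == 1) verdict <- top
  }
  structure(list(
    counts = counts,
    site_table = site_table,
    n_sites_total = nrow(sites),
    n_sites_query_informative = n_inf,
    n_off_pattern = off,
    verdict = verdict,
    level = attr(sites, "level"),
    locus = attr(sites, "locus")
  ), class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("<assignment_report%s, level %s> verdict: %s\n",
              if (is.na(x$locus %||% NA)) "" else paste0(" ", x$locus),
              x$level, x$verdict))
  cat(sprintf("  %d diagnostic site(s), %d informative in query, %d off-pattern\n",
              x$n_sites_total, x$n_sites_query_informative, x$n_off_pattern))
  for (g in names(x$counts)) {
    cat(sprintf("  agrees with %s at %d site(s)\n", g, x$counts[[g]]))
  }
  invisible(x)
}

#' Uncorrected pairwise distance (pairwise deletion)
#'
#' Proportion of differing columns among columns where neither sequence
#' has a missing character (N/?/-).
#'
#' @param a,b aligned sequences of equal length (character scalars).
#' @return the p-distance, a fraction in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  if (str_length(a) != str_length(b)) abort("sequences differ in length")
  ca <- str_split(str_to_upper(a), "")[[1]]
  cb <- str_split(str_to_upper(b), "")[[1]]
  ok <- !(ca %in% MISSING_CHARS) & !(cb %in% MISSING_CHARS)
  if (!any(ok)) abort("no comparable columns (all missing)")
  sum(ca[ok] != cb[ok]) / sum(ok)
}

#' Range of uncorrected distances between two groups
#'
#' Minimum and maximum p-distance over all cross-group sequence pairs of a
#' locus.
#'
#' @param panel labelled panel tibble.
#' @param locus locus to analyse.
#' @param group_a,group_b group labels at `level`.
#' @param level label level (default `"lineage"`).
#' @return one-row tibble: `min`, `max`, `n_pairs`.
#' @export
group_distance_range <- function(panel, locus, group_a, group_b,
                                 level = "lineage") {
  sub <- panel[panel$locus == locus, ]
  sa <- sub$seq[sub[[level]] == group_a]
  sb <- sub$seq[sub[[level]] == group_b]
  if (length(sa) == 0 || length(sb) == 0) {
    abort(sprintf("empty group at level %s", level))
  }
  d <- as.vector(outer(sa, sb, Vectorize(p_distance)))
  tibble(min = min(d), max = max(d), n_pairs = length(d))
}
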
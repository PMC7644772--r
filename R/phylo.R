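# Distance-based placement: Tamura-Nei (1993) distances with optional
# gamma rate variation, neighbor-joining trees, and nonparametric bootstrap
# support from column resampling.

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Columns where either sequence has a missing character (N/?/-) or a
#' non-ACGT code are excluded (pairwise deletion). Base frequencies are
#' estimated from the pooled pair. With `gamma_shape`, the gamma-corrected
#' variant is returned. If any logarithm (or power) argument is
#' non-positive — saturation — the distance is undefined and `NaN` is
#' returned.
#'
#' @param a,b aligned sequences of equal length (character scalars).
#' @param gamma_shape optional positive gamma shape parameter.
#' @return the TN93 distance in substitutions/site, or `NaN` if undefined.
#' @export
tn93_distance <- function(a, b, gamma_shape = NULL) {
  if (str_length(a) != str_length(b)) abort("sequences differ in length")
  ca <- str_split(str_to_upper(a), "")[[1]]
  cb <- str_split(str_to_upper(b), "")[[1]]
  ok <- ca %in% BASES & cb %in% BASES
  if (!any(ok)) abort("no comparable columns (all missing)")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  # pooled base frequencies
  f <- table(factor(c(ca, cb), levels = BASES)) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  pur <- diff & (ca %in% c("A", "G")) & (cb %in% c("A", "G"))
  pyr <- diff & (ca %in% c("C", "T")) & (cb %in% c("C", "T"))
  P1 <- sum(pur) / n   # purine transitions (A<->G)
  P2 <- sum(pyr) / n   # pyrimidine transitions (C<->T)
  Q <- sum(diff & !pur & !pyr) / n  # transversions
  if (P1 + P2 + Q == 0) return(0)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  # degenerate frequency classes with observed changes cannot be corrected
  if ((k1 == 0 && P1 > 0) || (k2 == 0 && P2 > 0) ||
      (gR == 0 || gY == 0)) {
    return(NaN)
  }
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NaN)
  if (is.null(gamma_shape)) {
    d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  } else {
    stopifnot(gamma_shape > 0)
    a_ <- gamma_shape
    d <- a_ * (k1 * (w1^(-1 / a_) - 1) + k2 * (w2^(-1 / a_) - 1) +
                 k3 * (w3^(-1 / a_) - 1))
  }
  unname(d)
}

#' Pairwise distance matrix for a set of aligned sequences
#'
#' @param seqs named character vector, or a tibble with `id` and `seq`.
#' @param model `"TN93"` (default) or `"p"` (uncorrected).
#' @param gamma_shape optional gamma shape (TN93 only).
#' @return symmetric numeric matrix with sequence ids as dimnames;
#'   undefined TN93 entries are `NaN`. Attributes `model` and
#'   `gamma_shape` record the settings.
#' @export
distance_matrix <- function(seqs, model = c("TN93", "p"),
                            gamma_shape = NULL) {
  model <- match.arg(model)
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  fun <- if (model == "p") p_distance else
    function(a, b) tn93_distance(a, b, gamma_shape)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- fun(seqs[[i]], seqs[[j]])
    }
  }
  attr(D, "model") <- if (!is.null(gamma_shape) && model == "TN93")
    "TN93+G" else model
  attr(D, "gamma_shape") <- gamma_shape
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor-joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the total deficit reported as a message.
#'
#' @param D symmetric distance matrix with dimnames (see
#'   [distance_matrix()]).
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 2) abort("need at least 2 taxa")
  bad <- which(!is.finite(D), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("undefined distance between '%s' and '%s'",
                  rownames(D)[bad[1, 1]], colnames(D)[bad[1, 2]]))
  }
  if (nrow(D) == 2) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         rownames(D)[1], D[1, 2] / 2,
                                         rownames(D)[2], D[1, 2] / 2)))
  }
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s), total deficit %.6g",
                    sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

# canonical keys of the non-trivial bipartitions of an unrooted tree:
# each split is represented by the side not containing `ref_tip`
tree_splits <- function(tr, ref_tip) {
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  n <- length(labs)
  keys <- vapply(pp, function(part) {
    tips <- labs[part]
    if (ref_tip %in% tips) tips <- setdiff(labs, tips)
    if (length(tips) < 2 || length(tips) > n - 2) return(NA_character_)
    paste(sort(tips), collapse = "|")
  }, character(1))
  keys
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times, rebuilding the distance
#' matrix and NJ tree each time. The support of an internal edge is the
#' percentage of replicate trees containing the same leaf bipartition.
#' Replicates with any undefined distance are skipped (with a warning if
#' more than 10% are).
#'
#' @param seqs named character vector of aligned sequences, or a tibble
#'   with `id` and `seq`.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; supports are deterministic given it.
#' @param model,gamma_shape distance settings (see [distance_matrix()]).
#' @return an unrooted [ape::phylo] tree whose `node.label` holds integer
#'   bootstrap percentages (empty for trivial splits); attribute
#'   `n_replicates_used` records how many replicates contributed.
#' @export
bootstrap_tree <- function(seqs, replicates = 1000L, seed = 1L,
                           model = "TN93", gamma_shape = NULL) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (replicates < 1) abort("replicates must be >= 1")
  seqs <- seqs[order(names(seqs))]  # leaf input order must not matter
  D <- distance_matrix(seqs, model = model, gamma_shape = gamma_shape)
  main <- nj_tree(D)
  ref_tip <- sort(names(seqs))[1]
  L <- str_length(seqs[[1]])
  mat <- seq_matrix(seqs)
  counts <- new.env(parent = emptyenv())
  used <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      boot_seqs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      Db <- tryCatch(
        distance_matrix(boot_seqs, model = model, gamma_shape = gamma_shape),
        error = function(e) NULL
      )
      if (is.null(Db) || any(!is.finite(Db))) next
      trb <- suppressMessages(nj_tree(Db))
      used <- used + 1L
      for (k in tree_splits(trb, ref_tip)) {
        if (is.na(k)) next
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      }
    }
  })
  skipped <- replicates - used
  if (skipped > 0.10 * replicates) {
    warn(sprintf("%d of %d bootstrap replicates skipped (undefined distances)",
                 skipped, replicates))
  }
  if (used == 0L) abort("all bootstrap replicates had undefined distances")
  main_keys <- tree_splits(main, ref_tip)
  main$node.label <- vapply(main_keys, function(k) {
    if (is.na(k)) "" else
      as.character(round(100 * (counts[[k]] %||% 0L) / used))
  }, character(1))
  attr(main, "n_replicates_used") <- used
  main
}
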
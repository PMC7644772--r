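# Independent oracles used by the tests. These deliberately re-derive
# quantities by a different route than the package code: a from-scratch
# dynamic-programming aligner, a separately coded Tamura-Nei closed form,
# closed-form expectations for the simulator, and brute-force recounts.

# ---- exhaustive affine-gap local alignment (Smith-Waterman) -------------
# match +1, mismatch -1, gap of length k costs 2 + k (open 2, extend 1),
# the same convention as the package's aligner. Returns best score and the
# identity (matches / alignment columns) of one optimal alignment.
oracle_local_align <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in pattern (consumes subject)
  F_ <- matrix(NEG, m + 1, n + 1) # gap in subject (consumes pattern)
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 2:(m + 1)) {
    sub <- ifelse(p[i - 1] == s, 1, -1)
    prev <- pmax(0, M[i - 1, 1:n], E[i - 1, 1:n], F_[i - 1, 1:n])
    M[i, 2:(n + 1)] <- prev + sub
    F_[i, 2:(n + 1)] <- pmax(M[i - 1, 2:(n + 1)] - 3, F_[i - 1, 2:(n + 1)] - 1)
    # E[i,j] = max over k<j of M[i,k] - 3 - (j-k-1), via a running max
    cm <- cummax(M[i, 1:n] + (1:n))
    E[i, 2:(n + 1)] <- cm - (2:(n + 1)) - 2
  }
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  score <- max(M)
  # traceback one optimal alignment, counting columns and matches
  i <- best[1]; j <- best[2]; state <- "M"
  cols <- 0L; matches <- 0L
  repeat {
    if (state == "M") {
      if (i == 1 || j == 1) break
      cols <- cols + 1L
      if (p[i - 1] == s[j - 1]) matches <- matches + 1L
      prev <- c(0, M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      k <- which.max(prev)
      i <- i - 1; j <- j - 1
      if (k == 1) break
      state <- c("M", "M", "E", "F")[k]
    } else if (state == "E") {
      # E[i,j] == max(M[i,j-1] - 3, E[i,j-1] - 1); prefer M on ties
      cols <- cols + 1L
      choose_m <- M[i, j - 1] - 3 >= E[i, j - 1] - 1
      j <- j - 1
      state <- if (choose_m) "M" else "E"
    } else { # F
      cols <- cols + 1L
      choose_m <- M[i - 1, j] - 3 >= F_[i - 1, j] - 1
      i <- i - 1
      state <- if (choose_m) "M" else "F"
    }
  }
  list(score = score, identity = if (cols > 0) matches / cols else 0,
       columns = cols, matches = matches)
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# mirror of the fishing decision rule, entirely on the oracle aligner:
# per reference take the better-scoring strand, identity 0 if the
# alignment spans fewer than min_aligned_length columns; best identity
# over references decides retention
oracle_best_identity <- function(bases, refs, min_aligned_length = 30) {
  best <- 0
  for (r in refs) {
    fw <- oracle_local_align(bases, r)
    rv <- oracle_local_align(oracle_revcomp(bases), r)
    hit <- if (rv$score > fw$score) rv else fw
    id <- if (hit$columns < min_aligned_length) 0 else hit$identity
    if (id > best) best <- id
  }
  best
}

# ---- independently coded Tamura-Nei (1993) closed form ------------------
# takes the observed proportions directly, so it shares no code with the
# package implementation
oracle_tn93 <- function(P1, P2, Q, freqs, gamma_shape = NULL) {
  gA <- freqs[["A"]]; gC <- freqs[["C"]]; gG <- freqs[["G"]]; gT <- freqs[["T"]]
  gR <- gA + gG; gY <- gC + gT
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NaN)
  c1 <- 2 * gA * gG / gR
  c2 <- 2 * gT * gC / gY
  c3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  if (is.null(gamma_shape)) {
    -c1 * log(w1) - c2 * log(w2) - c3 * log(w3)
  } else {
    a <- gamma_shape
    a * (c1 * (w1^(-1 / a) - 1) + c2 * (w2^(-1 / a) - 1) +
           c3 * (w3^(-1 / a) - 1))
  }
}

# observed TN93 ingredients of a gap-free pair
oracle_pair_props <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  diff <- ca != cb
  pur <- diff & ca %in% c("A", "G") & cb %in% c("A", "G")
  pyr <- diff & ca %in% c("C", "T") & cb %in% c("C", "T")
  freqs <- table(factor(c(ca, cb), levels = c("A", "C", "G", "T"))) / (2 * n)
  list(P1 = sum(pur) / n, P2 = sum(pyr) / n, Q = sum(diff & !pur & !pyr) / n,
       freqs = as.list(freqs))
}

# ---- closed-form expectation for the lineage simulator ------------------
# two founders independently mutated from one ancestor at per-site rate d,
# each substitution uniform over the 3 other bases: per-site probability
# that the founders differ
oracle_expected_pdist <- function(d) {
  # neither mutated: identical; exactly one: different;
  # both: identical iff they chose the same of 3 targets (prob 1/3)
  2 * d * (1 - d) + d^2 * (2 / 3)
}

# ---- spherical zone area (independent closed form) ----------------------
# area of the lat/lon rectangle [lat1,lat2] x [lon1,lon2] on a sphere:
# R^2 * dlon * (sin(lat2) - sin(lat1))
oracle_zone_area_km2 <- function(lat1, lat2, lon1, lon2, R = 6371.0088) {
  d2r <- pi / 180
  R^2 * (lon2 - lon1) * d2r * (sin(lat2 * d2r) - sin(lat1 * d2r))
}

# ---- brute-force consensus recount --------------------------------------
# per-column state tally recomputed directly from the placement table
oracle_column_tally <- function(placements, column) {
  states <- character(0)
  for (i in seq_len(nrow(placements))) {
    if (placements$start[i] <= column && column < placements$end[i]) {
      st <- substr(placements$states[i],
                   column - placements$start[i] + 1,
                   column - placements$start[i] + 1)
      states <- c(states, st)
    }
  }
  table(factor(states[states != "N"], levels = c("A", "C", "G", "T", "-")))
}

# ---- brute-force diagnostic-site check ----------------------------------
# re-verify a claimed diagnostic column by direct inspection
oracle_is_diagnostic <- function(seqs, groups, column, focal) {
  missing <- c("N", "?", "-")
  states <- character(0)
  for (g in focal) {
    vals <- substr(seqs[groups == g], column + 1, column + 1)
    vals <- vals[!vals %in% missing]
    if (length(unique(vals)) != 1) return(FALSE)
    states <- c(states, vals[1])
  }
  anyDuplicated(states) == 0
}
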
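# Feature groups 1-5 over a sliding window, and assembly of the full
# 342-column per-residue feature matrix.
#
# Window handling: averaged features (groups 2-5, and the windowed
# disorder mean of group 6) truncate the window at the termini and divide
# by the number of in-sequence positions; the positional PSSM
# concatenation of group 1 instead zero-pads missing rows so its
# dimensionality stays fixed at 20 x window.

.half <- function(window) {
  if (window %% 2 != 1 || window < 1) stop("window size must be a positive odd number")
  (window - 1L) %/% 2L
}

# truncated running mean of x over a centred window
.running_mean <- function(x, window) {
  L <- length(x)
  h <- .half(window)
  cs <- cumsum(x)
  i <- seq_len(L)
  lo <- pmax(1L, i - h); hi <- pmin(L, i + h)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

# truncated running sum with an externally supplied divisor vector
.running_sum <- function(x, window) {
  L <- length(x)
  h <- .half(window)
  cs <- cumsum(x)
  i <- seq_len(L)
  lo <- pmax(1L, i - h); hi <- pmin(L, i + h)
  cs[hi] - c(0, cs)[lo]
}

#' Fit the corpus-wide PSSM scaler
#'
#' Records, for each amino-acid column, the minimum and maximum raw PSSM
#' score observed across all residues of all training profiles. Raw
#' scores are later mapped linearly onto `[0, 1]` with these bounds
#' (see [scale_pssm()]); fitting on the training split only keeps test
#' proteins from stretching the scale.
#'
#' @param profiles list of [pssm_profile()] objects (the training set).
#' @return An object of class `pssm_scaler` with numeric vectors `min`
#'   and `max`, one entry per amino acid in [AA_ORDER].
#' @export
fit_pssm_scaler <- function(profiles) {
  if (length(profiles) == 0) stop("cannot fit a PSSM scaler on zero profiles")
  all_scores <- do.call(rbind, lapply(profiles, function(p) p$scores))
  structure(list(min = apply(all_scores, 2, min),
                 max = apply(all_scores, 2, max)),
            class = "pssm_scaler")
}

#' Scale a PSSM profile to `[0, 1]`
#'
#' Applies `(v - min) / (max - min)` per amino-acid column with the
#' fitted bounds, clamping out-of-range values to `[0, 1]`. A degenerate
#' column (min = max in training) maps every value to 0.5: a constant
#' column carries no information and the midpoint avoids either extreme.
#'
#' @param profile a [pssm_profile()].
#' @param scaler a fitted [fit_pssm_scaler()] result.
#' @return A scaled [pssm_profile()] with all scores in `[0, 1]`.
#' @export
scale_pssm <- function(profile, scaler) {
  stopifnot(inherits(scaler, "pssm_scaler"))
  rng <- scaler$max - scaler$min
  sc <- sweep(profile$scores, 2, scaler$min, `-`)
  sc <- sweep(sc, 2, ifelse(rng > 0, rng, 1), `/`)
  sc[, rng == 0] <- 0.5
  sc[sc < 0] <- 0
  sc[sc > 1] <- 1
  pssm_profile(sc, profile$info, profile$protein_id)
}

#' Group 1: windowed PSSM mutability features
#'
#' Concatenates the 20 scaled substitution scores for each window offset
#' (-h .. +h around `pos`, h = (window-1)/2) into a single vector of
#' `20 * window` values (300 at the default window of 15). Offsets
#' falling outside the sequence contribute 20 zeros each.
#'
#' @param scaled a scaled [pssm_profile()].
#' @param pos 1-based residue index.
#' @param window odd window size (default 15).
#' @return Numeric vector of length `20 * window`.
#' @export
mutability_features <- function(scaled, pos, window = 15) {
  L <- nrow(scaled$scores)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  h <- .half(window)
  out <- numeric(20L * window)
  for (k in seq_len(window)) {
    j <- pos + (k - 1L - h)
    if (j >= 1 && j <= L)
      out[((k - 1L) * 20L + 1L):(k * 20L)] <- scaled$scores[j, ]
  }
  out
}

#' Group 2: windowed conservation feature
#'
#' Mean of the per-position PSSM information value over the in-sequence
#' portion of the window.
#'
#' @inheritParams mutability_features
#' @param profile a [pssm_profile()] (scaling does not apply to the
#'   information column).
#' @return A single numeric value.
#' @export
conservation_feature <- function(profile, pos, window = 15) {
  L <- length(profile$info)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  .running_mean(profile$info, window)[pos]
}

# indicator matrix L x 20 of standard amino acids; ambiguity codes give
# an all-zero row
.aa_indicator <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  ind <- matrix(0, length(res), 20, dimnames = list(NULL, AA_ORDER))
  idx <- match(res, AA_ORDER)
  ok <- !is.na(idx)
  ind[cbind(which(ok), idx[ok])] <- 1
  ind
}

#' Group 3: windowed amino-acid composition
#'
#' Fraction of each of the 20 standard amino acids in the window around
#' `pos`. The divisor is the number of in-sequence standard residues in
#' the window, so ambiguity codes count toward neither numerator nor
#' denominator.
#'
#' @param sequence protein sequence string.
#' @inheritParams mutability_features
#' @return Numeric vector of 20 fractions named by [AA_ORDER].
#' @export
composition_features <- function(sequence, pos, window = 15) {
  L <- nchar(sequence)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  .composition_block(sequence, window)[pos, ]
}

.composition_block <- function(sequence, window) {
  ind <- .aa_indicator(sequence)
  denom <- .running_sum(rowSums(ind), window)
  counts <- apply(ind, 2, .running_sum, window = window)
  if (nrow(ind) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, AA_ORDER))
  sweep(counts, 1, ifelse(denom > 0, denom, 1), `/`)
}

#' Group 4: windowed physicochemical property features
#'
#' Nine values per residue: four polarity-class fractions (non-polar,
#' polar, acidic-polar, basic-polar), three charge-class fractions
#' (positive, negative, neutral), the mean Kyte-Doolittle hydropathy and
#' the mean average residue mass (Da), all over the in-sequence standard
#' residues of the window. Hydropathy and mass stay on their natural
#' scales; tree ensembles are insensitive to feature scaling.
#'
#' @inheritParams composition_features
#' @return Named numeric vector of length 9.
#' @export
property_features <- function(sequence, pos, window = 15) {
  L <- nchar(sequence)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  .property_block(sequence, window)[pos, ]
}

.property_block <- function(sequence, window) {
  tab <- property_tables()
  comp <- .composition_block(sequence, window)   # fractions over standard residues
  pol <- vapply(POLARITY_CLASSES, function(cl)
    rowSums(comp[, tab$aa[tab$polarity == cl], drop = FALSE]), numeric(nrow(comp)))
  chg <- vapply(CHARGE_CLASSES, function(cl)
    rowSums(comp[, tab$aa[tab$charge == cl], drop = FALSE]), numeric(nrow(comp)))
  if (nrow(comp) == 1) {
    pol <- matrix(pol, nrow = 1, dimnames = list(NULL, POLARITY_CLASSES))
    chg <- matrix(chg, nrow = 1, dimnames = list(NULL, CHARGE_CLASSES))
  }
  hyd <- as.vector(comp %*% tab$hydropathy)
  mass <- as.vector(comp %*% tab$mass)
  out <- cbind(pol, chg, hydropathy = hyd, mass = mass)
  colnames(out) <- c(paste0("pol_", POLARITY_CLASSES),
                     paste0("charge_", CHARGE_CLASSES), "hydropathy", "mass")
  out
}

#' Group 5: windowed secondary-structure probabilities
#'
#' Mean of P(H), P(E) and P(C) over the in-sequence window portion.
#'
#' @param ss an [ss_profile()].
#' @inheritParams mutability_features
#' @return Numeric vector `(H, E, C)`.
#' @export
ss_features <- function(ss, pos, window = 15) {
  L <- nrow(ss$probs)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  c(H = .running_mean(ss$probs[, "H"], window)[pos],
    E = .running_mean(ss$probs[, "E"], window)[pos],
    C = .running_mean(ss$probs[, "C"], window)[pos])
}

#' Feature-group column layout
#'
#' Column ranges of the seven feature groups in the assembled matrix for
#' a given window size (at the default window of 15: group 1 spans
#' columns 1-300, group 2 column 301, group 3 columns 302-321, group 4
#' columns 322-330, group 5 columns 331-333, group 6 columns 334-340 and
#' group 7 columns 341-342).
#'
#' @param window odd window size.
#' @return Named list `group1` .. `group7` of integer column vectors.
#' @export
feature_group_index <- function(window = 15) {
  n1 <- 20L * window
  list(
    group1 = seq_len(n1),
    group2 = n1 + 1L,
    group3 = (n1 + 2L):(n1 + 21L),
    group4 = (n1 + 22L):(n1 + 30L),
    group5 = (n1 + 31L):(n1 + 33L),
    group6 = (n1 + 34L):(n1 + 40L),
    group7 = (n1 + 41L):(n1 + 42L)
  )
}

#' Assemble the full per-residue feature matrix for one protein
#'
#' Stacks all seven feature groups in their canonical column order:
#' windowed PSSM mutability (group 1), windowed conservation (2),
#' windowed composition (3), windowed physicochemical properties (4),
#' windowed secondary-structure probabilities (5), disorder-segment
#' descriptors (6) and disorder topography (7). At the default window of
#' 15 the result has exactly 342 columns.
#'
#' @param sequence protein sequence string.
#' @param scaled_pssm a [scale_pssm()]-transformed [pssm_profile()].
#' @param ss an [ss_profile()].
#' @param diso a [disorder_profile()].
#' @param window odd window size (default 15; group 1 is the only group
#'   whose width depends on it).
#' @param disorder_threshold disorder/order threshold for group 6.
#' @param delta relative score difference defining peaks/valleys (group 7).
#' @param delta_mode `"relative"` (default) or `"absolute"`, see
#'   [topography_class()].
#' @param segment_position_mode `"position"` (default) or `"distance"`,
#'   see [disorder_segment_features()].
#' @return An L x (20*window + 42) numeric matrix of class
#'   `feature_matrix` with attribute `group_index` (see
#'   [feature_group_index()]).
#' @export
assemble_features <- function(sequence, scaled_pssm, ss, diso, window = 15,
                              disorder_threshold = 0.5, delta = 0.10,
                              delta_mode = c("relative", "absolute"),
                              segment_position_mode = c("position", "distance")) {
  L <- nchar(sequence)
  if (nrow(scaled_pssm$scores) != L || nrow(ss$probs) != L ||
      length(diso$scores) != L)
    stop("track length mismatch: sequence ", L, ", pssm ",
         nrow(scaled_pssm$scores), ", ss ", nrow(ss$probs), ", diso ",
         length(diso$scores))
  h <- .half(window)

  # group 1: shifted copies of the scaled score matrix, zero-padded
  g1 <- matrix(0, L, 20L * window)
  for (k in seq_len(window)) {
    d <- k - 1L - h
    rows <- seq_len(L)
    src <- rows + d
    ok <- src >= 1 & src <= L
    g1[rows[ok], ((k - 1L) * 20L + 1L):(k * 20L)] <- scaled_pssm$scores[src[ok], ]
  }
  colnames(g1) <- paste0("g1_w", rep(seq_len(window) - 1L - h, each = 20),
                         "_", rep(AA_ORDER, window))

  g2 <- matrix(.running_mean(scaled_pssm$info, window), ncol = 1,
               dimnames = list(NULL, "g2_conservation"))
  g3 <- .composition_block(sequence, window)
  colnames(g3) <- paste0("g3_comp_", AA_ORDER)
  g4 <- .property_block(sequence, window)
  colnames(g4) <- paste0("g4_", colnames(g4))
  g5 <- vapply(c("H", "E", "C"), function(s)
    .running_mean(ss$probs[, s], window), numeric(L))
  if (L == 1) g5 <- matrix(g5, nrow = 1)
  colnames(g5) <- paste0("g5_ss", c("H", "E", "C"))
  g6 <- .disorder_segment_block(diso, window, disorder_threshold,
                                match.arg(segment_position_mode))
  g7 <- .topography_block(diso, delta, match.arg(delta_mode))

  out <- cbind(g1, g2, g3, g4, g5, g6, g7)
  structure(out, group_index = feature_group_index(window),
            class = c("feature_matrix", class(out)))
}

#' Extract features and labels for a whole corpus
#'
#' Fits nothing: the scaler must already be fitted (typically on the
#' training split only). Returns the row-bound feature matrix together
#' with per-row protein ids, positions and labels.
#'
#' @param corpus corpus list (see [validate_corpus()] for the expected
#'   per-protein fields).
#' @param scaler fitted [fit_pssm_scaler()] result.
#' @param ... passed on to [assemble_features()].
#' @return List with `features` (matrix), `protein_id`, `position`,
#'   `labels` (parallel vectors), and `group_index`.
#' @export
extract_corpus_features <- function(corpus, scaler, ...) {
  parts <- lapply(corpus, function(p) {
    assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss, p$diso, ...)
  })
  feats <- do.call(rbind, parts)
  lens <- vapply(parts, nrow, integer(1))
  list(
    features = feats,
    protein_id = rep(vapply(corpus, `[[`, "", "id"), lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    labels = unlist(lapply(corpus, function(p) p$labels$labels), use.names = FALSE),
    group_index = attr(parts[[1]], "group_index")
  )
}
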
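# Feature group 6 (disorder-segment descriptors) and group 7 (disorder
# topography) computed from a per-residue disorder probability track.

# maximal runs of the logical vector `dis`; returns per-residue start,
# stop, and length of the run containing each residue
.runs_of <- function(dis) {
  r <- rle(dis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(start = rep(starts, r$lengths),
       stop = rep(ends, r$lengths),
       length = rep(r$lengths, r$lengths))
}

#' Maximal disorder/order segment containing a residue
#'
#' If the disorder score at `pos` is at or above `threshold` the residue
#' sits in a disordered segment: the maximal contiguous run of scores
#' `>= threshold` containing it. Otherwise it sits in the complementary
#' ordered run (scores `< threshold`). Boundaries are clipped at the
#' sequence ends. Start/stop are also reported relative to the total
#' sequence length.
#'
#' @param diso a [disorder_profile()].
#' @param pos 1-based residue index.
#' @param threshold disorder threshold (default 0.5; the comparison for
#'   "disordered" is `>=`).
#' @return List with `kind` (`"disordered"` or `"ordered"`), `start`,
#'   `stop`, `length`, `start_rel`, `stop_rel`.
#' @export
segment_of <- function(diso, pos, threshold = 0.5) {
  s <- diso$scores
  L <- length(s)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  runs <- .runs_of(s >= threshold)
  list(kind = if (s[pos] >= threshold) "disordered" else "ordered",
       start = runs$start[pos], stop = runs$stop[pos],
       length = runs$length[pos],
       start_rel = runs$start[pos] / L, stop_rel = runs$stop[pos] / L)
}

#' Group 6: disorder-segment features for one residue
#'
#' Seven values: (1) the mean disorder score over the truncated window;
#' (2-4) length, relative start and relative stop of the disordered
#' segment when the residue is predicted disordered, zeros otherwise;
#' (5-7) the same triplet for the ordered segment when the residue is
#' predicted ordered, zeros otherwise. Exactly one of the two triplets is
#' therefore always zero.
#'
#' @inheritParams segment_of
#' @param window odd window size for the mean-score feature.
#' @param position_mode `"position"` reports segment boundary positions
#'   divided by L; `"distance"` reports the relative distance from the
#'   current residue to the boundary before/after it (both divided by L).
#' @return Named numeric vector of length 7.
#' @export
disorder_segment_features <- function(diso, pos, window = 15,
                                      threshold = 0.5,
                                      position_mode = c("position", "distance")) {
  L <- length(diso$scores)
  if (pos < 1 || pos > L) stop("position out of range: ", pos)
  .disorder_segment_block(diso, window, threshold,
                          match.arg(position_mode))[pos, ]
}

.disorder_segment_block <- function(diso, window, threshold, position_mode) {
  s <- diso$scores
  L <- length(s)
  dis <- s >= threshold
  runs <- .runs_of(dis)
  i <- seq_len(L)
  if (position_mode == "position") {
    a <- runs$start / L
    b <- runs$stop / L
  } else {
    a <- (i - runs$start + 1L) / L
    b <- (runs$stop - i + 1L) / L
  }
  out <- matrix(0, L, 7)
  out[, 1] <- .running_mean(s, window)
  out[dis, 2] <- runs$length[dis]
  out[dis, 3] <- a[dis]
  out[dis, 4] <- b[dis]
  out[!dis, 5] <- runs$length[!dis]
  out[!dis, 6] <- a[!dis]
  out[!dis, 7] <- b[!dis]
  colnames(out) <- c("g6_diso_mean", "g6_dis_len", "g6_dis_start",
                     "g6_dis_stop", "g6_ord_len", "g6_ord_start", "g6_ord_stop")
  out
}

#' Group 7: peak/valley/neither topography class
#'
#' A residue is part of a peak (class 1) if on both sides there is a
#' residue with a disorder score at least 10% lower, and part of a
#' valley (class -1) if there are residues at least 10% higher on both
#' sides; otherwise neither (class 0). The qualifying residue on each
#' side is the NEAREST one deviating by at least 10% in either
#' direction: walking outward from the residue, the first score to
#' leave the 10% band decides that side's verdict (lower = downhill,
#' higher = uphill), so the classification describes the local
#' topographic element the residue sits on rather than the global score
#' range. A terminus reached without any qualifying deviation leaves
#' that side undecided, which fails both the peak and the valley
#' condition. "10%" is interpreted multiplicatively by default
#' (`<= (1-delta)*s`, `>= (1+delta)*s`), switchable to an absolute
#' offset.
#'
#' @inheritParams segment_of
#' @param pos residue index, or `NULL` to classify every residue.
#' @param delta score difference defining a peak/valley (default 0.10).
#' @param delta_mode `"relative"` (multiplicative, default) or
#'   `"absolute"`.
#' @return Integer class(es) in `{-1, 0, 1}`.
#' @export
topography_class <- function(diso, pos = NULL, delta = 0.10,
                             delta_mode = c("relative", "absolute")) {
  delta_mode <- match.arg(delta_mode)
  s <- diso$scores
  L <- length(s)
  if (delta_mode == "relative") {
    lo <- (1 - delta) * s
    hi <- (1 + delta) * s
  } else {
    lo <- s - delta
    hi <- s + delta
  }
  # verdict of one side: +1 if the nearest out-of-band score is low,
  # -1 if high, 0 if the terminus is reached first
  side <- function(v, lo_i, hi_i) {
    j <- which(v <= lo_i | v >= hi_i)
    if (length(j) == 0) return(0L)
    if (v[j[1]] <= lo_i) 1L else -1L
  }
  klass <- integer(L)
  for (i in seq_len(L)) {
    left <- if (i > 1) side(s[(i - 1):1], lo[i], hi[i]) else 0L
    if (left == 0L) next
    right <- if (i < L) side(s[(i + 1):L], lo[i], hi[i]) else 0L
    if (left == right) klass[i] <- left
  }
  if (is.null(pos)) return(klass)
  if (any(pos < 1 | pos > L)) stop("position out of range")
  klass[pos]
}

#' Group 7: topography class and topographic length
#'
#' The class from [topography_class()] together with the length of the
#' maximal contiguous run of residues sharing that class; residues of
#' class 0 get length 0 (the length is only defined for the current
#' peak or valley).
#'
#' @inheritParams topography_class
#' @return For a single `pos`, a named numeric vector
#'   `(class, run_length)`; for `pos = NULL`, an L x 2 matrix.
#' @export
topography_features <- function(diso, pos = NULL, delta = 0.10,
                                delta_mode = c("relative", "absolute")) {
  block <- .topography_block(diso, delta, match.arg(delta_mode))
  if (is.null(pos)) return(block)
  if (any(pos < 1 | pos > length(diso$scores))) stop("position out of range")
  block[pos, ]
}

.topography_block <- function(diso, delta, delta_mode) {
  klass <- topography_class(diso, NULL, delta, delta_mode)
  r <- rle(klass)
  run_len <- rep(r$lengths, r$lengths)
  run_len[klass == 0L] <- 0L
  out <- cbind(g7_topo_class = klass, g7_topo_len = run_len)
  out
}
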
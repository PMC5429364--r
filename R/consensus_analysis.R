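# Sequence-consensus analyses: amino-acid propensities by residue class,
# secondary-structure content fractions, and the Altscore statistic that
# measures indecisiveness of predicted secondary structure over a segment.

#' Count amino acids over (masked) sequences
#'
#' Tallies the 20 standard amino acids over the residues selected by the
#' masks; ambiguity codes are ignored.
#'
#' @param sequences character vector of sequences.
#' @param masks optional list of logical vectors (one per sequence)
#'   selecting residues; `NULL` counts everything.
#' @return Named numeric vector of 20 counts in [AA_ORDER].
#' @export
count_amino_acids <- function(sequences, masks = NULL) {
  counts <- setNames(numeric(20), AA_ORDER)
  for (i in seq_along(sequences)) {
    res <- strsplit(sequences[[i]], "")[[1]]
    if (!is.null(masks)) {
      stopifnot(length(masks[[i]]) == length(res))
      res <- res[masks[[i]]]
    }
    tab <- table(factor(res, levels = AA_ORDER))
    counts <- counts + as.numeric(tab)
  }
  counts
}

#' Amino-acid propensity of a residue class
#'
#' The propensity of amino acid X for a class (protean, non-protean,
#' disordered, ordered, ...) is the ratio of its frequency within the
#' class to its frequency in the full corpus:
#' `Pr(X) = (N(X)_class / N(All)_class) / (N(X)_full / N(All)_full)`.
#' A value of 1 means no preference; above/below 1 means over/under
#' representation. The frequency-ratio form guarantees the normalization
#' identity `sum_X f_full(X) * Pr(X) = 1`. A variant that divides the
#' class count by the full-corpus total instead of the class total
#' (`formula = "unnormalized"`) is provided for comparison; it equals
#' `N(X)_class / N(X)_full` and does not satisfy the identity.
#'
#' @param class_counts named per-amino-acid counts for the class.
#' @param full_counts named per-amino-acid counts for the full corpus.
#' @param formula `"ratio"` (default, frequency ratio) or
#'   `"unnormalized"`.
#' @return data.frame `(aa, class_count, full_count, propensity)`.
#'   Amino acids absent from `full_counts` are excluded with a warning.
#' @export
propensity <- function(class_counts, full_counts,
                       formula = c("ratio", "unnormalized")) {
  formula <- match.arg(formula)
  aa <- intersect(names(full_counts), AA_ORDER)
  class_counts <- class_counts[aa]
  full_counts <- full_counts[aa]
  class_counts[is.na(class_counts)] <- 0
  if (sum(full_counts) <= 0) stop("full corpus has zero residues")
  if (sum(class_counts) <= 0) stop("class has zero residues")
  absent <- full_counts == 0
  if (any(absent)) {
    warning("amino acids absent from the full corpus excluded: ",
            paste(aa[absent], collapse = ", "))
    aa <- aa[!absent]
    class_counts <- class_counts[!absent]
    full_counts <- full_counts[!absent]
  }
  pr <- if (formula == "ratio") {
    (class_counts / sum(class_counts)) / (full_counts / sum(full_counts))
  } else {
    class_counts / full_counts
  }
  data.frame(aa = aa, class_count = as.numeric(class_counts),
             full_count = as.numeric(full_counts),
             propensity = as.numeric(pr), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Secondary-structure content of a residue class
#'
#' Relative fraction of helix, strand and coil calls among the residues
#' selected by the mask.
#'
#' @param ss_calls character vector of per-residue H/E/C calls.
#' @param mask logical vector selecting residues (`NULL` = all).
#' @return Named numeric vector `(H, E, C)` summing to 1.
#' @export
ss_content <- function(ss_calls, mask = NULL) {
  if (length(ss_calls) == 1 && nchar(ss_calls[1]) > 1)
    ss_calls <- strsplit(ss_calls, "")[[1]]
  if (!is.null(mask)) ss_calls <- ss_calls[mask]
  if (length(ss_calls) == 0) stop("empty residue mask")
  tab <- table(factor(ss_calls, levels = c("H", "E", "C")))
  as.vector(tab / sum(tab)) |> setNames(c("H", "E", "C"))
}

#' Altscore: secondary-structure indecisiveness of a segment
#'
#' The number of adjacent-call transitions (H->C, C->E, ...) in the
#' segment's predicted secondary-structure string, divided by the
#' segment length (transitions per residue, the default) or by
#' length - 1.
#'
#' @param calls character vector or single string of H/E/C calls over
#'   the segment.
#' @param denominator `"length"` (default) or `"length_minus_1"`.
#' @return Non-negative numeric; 0 iff the call string is constant.
#' @export
altscore <- function(calls, denominator = c("length", "length_minus_1")) {
  denominator <- match.arg(denominator)
  if (length(calls) == 1 && nchar(calls[1]) >= 1)
    calls <- strsplit(calls, "")[[1]]
  n <- length(calls)
  if (n < 1) stop("empty segment")
  transitions <- if (n == 1) 0L else sum(calls[-1] != calls[-n])
  d <- if (denominator == "length") n else max(n - 1L, 1L)
  transitions / d
}

#' Per-segment Altscore table for a corpus
#'
#' Splits every protein into maximal protean / non-protean segments
#' (runs of the residue label track) and computes each segment's
#' Altscore over its predicted secondary-structure calls.
#'
#' @param corpus corpus list (entries need `id`, `ss`, `labels`).
#' @param denominator passed to [altscore()].
#' @return data.frame `(protein_id, class, start, end, length,
#'   transitions, altscore, pure_coil)`.
#' @export
segment_altscores <- function(corpus, denominator = c("length", "length_minus_1")) {
  denominator <- match.arg(denominator)
  rows <- lapply(corpus, function(p) {
    lab <- p$labels$labels
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(
      protein_id = p$id,
      class = ifelse(r$values == 1L, "protean", "non_protean"),
      start = starts, end = ends, length = r$lengths,
      transitions = mapply(function(a, b) {
        cc <- p$ss$calls[a:b]
        if (length(cc) == 1) 0L else sum(cc[-1] != cc[-length(cc)])
      }, starts, ends),
      altscore = mapply(function(a, b)
        altscore(p$ss$calls[a:b], denominator), starts, ends),
      pure_coil = mapply(function(a, b)
        all(p$ss$calls[a:b] == "C"), starts, ends),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Altscore distributions per segment class
#'
#' Normalized histograms of segment Altscore values for each class,
#' after removing zero-Altscore segments (pure noise with respect to
#' indecisiveness) and, optionally, segments whose calls are purely
#' coil.
#'
#' @param segments a [segment_altscores()] table.
#' @param exclude_zero drop segments with Altscore 0 (default `TRUE`).
#' @param exclude_pure_coil drop purely-coil segments (default `TRUE`).
#' @param binwidth histogram bin width on `[0, 1]` (default 0.025, fine
#'   enough to resolve peaks 0.05 apart).
#' @return List per class with elements `histogram` (data.frame
#'   `bin_mid`, `prob`), `peak` (bin midpoint of the mode) and `n`.
#' @export
altscore_distribution <- function(segments, exclude_zero = TRUE,
                                  exclude_pure_coil = TRUE,
                                  binwidth = 0.025) {
  keep <- rep(TRUE, nrow(segments))
  if (exclude_zero) keep <- keep & segments$altscore > 0
  if (exclude_pure_coil) keep <- keep & !segments$pure_coil
  segments <- segments[keep, , drop = FALSE]
  if (nrow(segments) == 0)
    stop("all segments removed by the Altscore filters")
  breaks <- seq(0, 1 + binwidth, by = binwidth)
  out <- lapply(split(segments, segments$class), function(df) {
    if (nrow(df) == 0) stop("a class lost all segments to the filters")
    h <- hist(pmin(df$altscore, 1), breaks = breaks, plot = FALSE)
    prob <- h$counts / sum(h$counts)
    list(histogram = data.frame(bin_mid = h$mids, prob = prob),
         peak = h$mids[which.max(prob)],
         n = nrow(df))
  })
  out
}
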
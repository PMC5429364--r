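#' @importFrom utils read.table write.table head tail
NULL

# ---- constructors -----------------------------------------------------------

#' PSSM profile
#'
#' Container for one protein's position-specific scoring matrix: an L x 20
#' matrix of substitution log-odds scores (columns in [AA_ORDER]) plus the
#' per-position information (conservation) value reported alongside it.
#'
#' @param scores numeric L x 20 matrix, columns named by [AA_ORDER].
#' @param info numeric length-L vector of per-position information values.
#' @param protein_id protein identifier.
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(scores, info, protein_id = "") {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 20, nrow(scores) == length(info))
  if (!all(is.finite(scores)) || !all(is.finite(info)))
    stop("PSSM profile contains non-finite values")
  colnames(scores) <- AA_ORDER
  structure(list(scores = scores, info = as.numeric(info),
                 protein_id = protein_id),
            class = "pssm_profile")
}

#' Secondary-structure profile
#'
#' Three-state (H/E/C) secondary-structure probabilities and calls for one
#' protein, as produced by PSIPRED-style predictors. Probabilities are kept
#' internally in (H, E, C) column order regardless of the file layout.
#'
#' @param probs numeric L x 3 matrix with columns H, E, C.
#' @param calls character vector (or single string) of per-residue calls
#'   over `{H, E, C}`.
#' @return An object of class `ss_profile`.
#' @export
ss_profile <- function(probs, calls) {
  probs <- as.matrix(probs)
  if (length(calls) == 1 && nchar(calls[1]) > 1)
    calls <- strsplit(calls, "")[[1]]
  stopifnot(ncol(probs) == 3, nrow(probs) == length(calls))
  if (any(probs < 0 | probs > 1))
    stop("secondary-structure probabilities outside [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 0.05))
    stop("secondary-structure probability rows do not sum to 1 (+/- 0.05)")
  if (!all(calls %in% c("H", "E", "C")))
    stop("secondary-structure calls must be H, E or C")
  colnames(probs) <- c("H", "E", "C")
  structure(list(probs = probs, calls = calls), class = "ss_profile")
}

#' Disorder profile
#'
#' Per-residue disorder probabilities in `[0, 1]` for one protein.
#'
#' @param scores numeric vector of disorder probabilities.
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(scores) {
  scores <- as.numeric(scores)
  if (any(scores < 0 | scores > 1))
    stop("disorder scores outside [0, 1]")
  structure(list(scores = scores), class = "disorder_profile")
}

#' Per-residue protean labels
#'
#' Binary target vector derived from annotated protean intervals
#' (1-based, inclusive). A residue is labelled 1 iff it is covered by an
#' interval; proteins without annotation are all-zero (negative examples).
#'
#' @param protein_id protein identifier.
#' @param intervals two-column matrix or data.frame of (start, end) pairs;
#'   may be empty.
#' @param length_ sequence length L.
#' @return An object of class `protean_labels` with fields `protein_id`,
#'   `intervals`, `labels`.
#' @export
protean_labels <- function(protein_id, intervals, length_) {
  if (is.null(intervals) || NROW(intervals) == 0) {
    intervals <- matrix(numeric(0), ncol = 2)
  } else {
    intervals <- as.matrix(intervals)[, 1:2, drop = FALSE]
  }
  labels <- integer(length_)
  if (nrow(intervals) > 0) {
    if (any(intervals[, 1] > intervals[, 2]))
      stop("interval with start > end for protein ", protein_id)
    if (any(intervals[, 1] < 1) || any(intervals[, 2] > length_))
      stop(sprintf("interval [%d, %d] outside sequence bounds 1..%d for protein %s",
                   intervals[which.max(intervals[, 2]), 1],
                   max(intervals[, 2]), length_, protein_id))
    for (i in seq_len(nrow(intervals)))
      labels[intervals[i, 1]:intervals[i, 2]] <- 1L
    # normalize: merge to maximal runs so stored intervals never overlap
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values == 1L
    intervals <- cbind(start = starts[keep], end = ends[keep])
  } else {
    intervals <- cbind(start = integer(0), end = integer(0))
  }
  structure(list(protein_id = protein_id, intervals = intervals,
                 labels = labels),
            class = "protean_labels")
}

# ---- readers ----------------------------------------------------------------

#' Read a FASTA file of protein sequences
#'
#' @param path path to a FASTA file.
#' @return A list of records, each a list with `id` (first header token)
#'   and `sequence` (uppercased). Duplicate identifiers are an error.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1])
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  bad <- !grepl(paste0("^[", paste(c(AA_ORDER, AA_AMBIGUOUS), collapse = ""), "]+$"), seqs)
  if (any(bad))
    stop("sequence with invalid residue codes: ", ids[bad][1])
  mapply(function(id, s) list(id = id, sequence = s),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

.track_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the dialect written by PSI-BLAST's `-Q` option: a header line
#' giving the amino-acid column order, then one row per residue with the
#' position, the residue, 20 log-odds integers, 20 weighted observed
#' percentages, the per-position information value and a relative weight.
#' Scores are taken from the first 20-column (log-odds) block and permuted
#' into [AA_ORDER].
#'
#' @param path path to the PSSM file.
#' @param expected_length if given, the parsed row count must equal it.
#' @param protein_id identifier stored in the profile; defaults to the
#'   file base name.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, expected_length = NULL,
                      protein_id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  # header: the first line whose tokens are all single amino-acid letters
  is_header <- vapply(toks, function(tk)
    length(tk) >= 20 && all(tk %in% AA_ORDER) , logical(1))
  if (!any(is_header))
    stop("no amino-acid column header found in PSSM file: ", path)
  h <- which(is_header)[1]
  file_order <- toks[[h]][1:20]
  if (anyDuplicated(file_order))
    stop("duplicated amino-acid column in PSSM header: ", path)
  rows <- list(); info <- numeric(0); pos_seen <- 0L
  for (i in seq(h + 1, length(toks))) {
    tk <- toks[[i]]
    if (length(tk) == 0) next
    if (is.na(suppressWarnings(as.integer(tk[1])))) break  # trailer (K, Lambda...)
    if (length(tk) < 43)
      stop(sprintf("malformed PSSM row at line %d of %s (%d fields, need >= 43)",
                   i, path, length(tk)))
    pos <- as.integer(tk[1])
    if (pos != pos_seen + 1L)
      stop(sprintf("non-consecutive position index at line %d of %s", i, path))
    pos_seen <- pos
    sc <- suppressWarnings(as.numeric(tk[3:22]))
    iv <- suppressWarnings(as.numeric(tk[43]))
    if (any(is.na(sc)) || is.na(iv))
      stop(sprintf("malformed PSSM row at line %d of %s", i, path))
    rows[[pos]] <- sc
    info[pos] <- iv
  }
  if (length(rows) == 0) stop("PSSM file has no data rows: ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- file_order
  scores <- scores[, AA_ORDER, drop = FALSE]
  if (!is.null(expected_length) && nrow(scores) != expected_length)
    stop(sprintf("PSSM length mismatch for %s: %d rows, expected %d",
                 protein_id, nrow(scores), expected_length))
  pssm_profile(scores, info, protein_id)
}

#' Read a PSIPRED VFORMAT .ss2 file
#'
#' Rows carry the residue index, residue, three-state call, and the coil,
#' helix and strand probabilities (in that file order). The returned
#' probabilities are reordered to (H, E, C).
#'
#' @param path path to the .ss2 file.
#' @return An [ss_profile()].
#' @export
read_ss2 <- function(path) {
  lines <- .track_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) stop("empty .ss2 body: ", path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  n <- length(toks)
  idx <- integer(n); calls <- character(n)
  probs <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("H", "E", "C")))
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 6) stop(sprintf("malformed .ss2 row at line %d of %s", i, path))
    idx[i] <- suppressWarnings(as.integer(tk[1]))
    calls[i] <- tk[3]
    p <- suppressWarnings(as.numeric(tk[4:6]))  # file order: C, H, E
    if (is.na(idx[i]) || any(is.na(p)))
      stop(sprintf("malformed .ss2 row at line %d of %s", i, path))
    probs[i, ] <- p[c(2, 3, 1)]
  }
  if (any(diff(idx) <= 0))
    stop("non-monotone residue indices in .ss2 file: ", path)
  ss_profile(probs, calls)
}

#' Read a per-residue disorder probability track
#'
#' Accepts the DISOPRED-style four-column dialect (index, residue, call
#' mark, score) and a plain two-column (index, score) dialect; the dialect
#' is auto-detected from the column count. Scores are clamped to `[0, 1]`;
#' values outside `[-0.01, 1.01]` before clamping indicate the wrong kind
#' of file and raise an error.
#'
#' @param path path to the disorder track file.
#' @return A [disorder_profile()].
#' @export
read_diso <- function(path) {
  lines <- .track_lines(path)
  lines <- lines[!grepl("^#|^-", lines)]
  if (length(lines) == 0) stop("empty disorder track: ", path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  ncols <- length(toks[[1]])
  score_col <- if (ncols >= 4) 4L else if (ncols == 2) 2L else
    stop("unrecognized disorder-track layout (", ncols, " columns): ", path)
  scores <- vapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    if (length(tk) < score_col)
      stop(sprintf("malformed disorder row at line %d of %s", i, path))
    s <- suppressWarnings(as.numeric(tk[score_col]))
    if (is.na(s)) stop(sprintf("malformed disorder row at line %d of %s", i, path))
    s
  }, numeric(1))
  if (any(scores < -0.01 | scores > 1.01))
    stop("disorder score outside [-0.01, 1.01]; wrong file? ", path)
  disorder_profile(pmin(1, pmax(0, scores)))
}

#' Read protean-segment annotations
#'
#' Reads a TSV of `protein_id`, `start`, `end` (1-based inclusive)
#' intervals and converts them to per-residue binary label vectors.
#' Proteins present in `sequences` but absent from the file get all-zero
#' labels (negative examples).
#'
#' @param path path to the interval TSV (header optional).
#' @param sequences list of sequence records as returned by [read_fasta()].
#' @return Named list of [protean_labels()], one per sequence.
#' @export
read_segment_labels <- function(path, sequences) {
  lines <- .track_lines(path)
  lines <- lines[!grepl("^#", lines)]
  rows <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(rows) > 0 && is.na(suppressWarnings(as.integer(rows[[1]][2]))))
    rows <- rows[-1]  # header line
  ids <- vapply(sequences, `[[`, "", "id")
  by_protein <- setNames(vector("list", length(ids)), ids)
  for (tk in rows) {
    if (length(tk) < 3) stop("malformed label row: ", paste(tk, collapse = " "))
    pid <- tk[1]
    se <- suppressWarnings(as.integer(tk[2:3]))
    if (any(is.na(se))) stop("malformed label row for protein ", pid)
    if (!pid %in% ids)
      stop("label row for unknown protein: ", pid)
    by_protein[[pid]] <- rbind(by_protein[[pid]], se)
  }
  out <- lapply(ids, function(pid) {
    L <- nchar(sequences[[which(ids == pid)]]$sequence)
    protean_labels(pid, by_protein[[pid]], L)
  })
  names(out) <- ids
  out
}

#' Read a BLASTclust-style cluster file
#'
#' One cluster per line, whitespace-separated member identifiers; cluster
#' ids are assigned by line order (first line = cluster 1).
#'
#' @param path path to the cluster file.
#' @return Named integer vector mapping protein id to cluster id.
#' @export
read_clusters <- function(path) {
  lines <- .track_lines(path)
  out <- integer(0)
  cl <- 0L
  for (l in lines) {
    members <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(members) == 0) next
    cl <- cl + 1L
    dup <- members[members %in% names(out)]
    if (length(dup) > 0 || anyDuplicated(members))
      stop("protein listed in more than one cluster: ",
           c(dup, members[duplicated(members)])[1])
    out[members] <- cl
  }
  if (length(out) == 0) stop("empty cluster file: ", path)
  out
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path path to the predictions file.
#' @return data.frame with columns `protein_id`, `position`, `residue`,
#'   `protean_score`, `call`.
#' @export
read_predictions <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "character",
                            "numeric", "integer"))
}

# ---- writers ----------------------------------------------------------------

#' Write per-residue predictions
#'
#' Writes a TSV with the stable column order `protein_id`, `position`
#' (1-based), `residue`, `protean_score` (4 decimals), `call` (0/1 at
#' `p_cut`, ties called positive).
#'
#' @param track data.frame with columns `protein_id`, `position`,
#'   `residue`, `protean_score` (scores in `[0, 1]`).
#' @param path output path.
#' @param p_cut probability cutoff for the binary call.
#' @export
write_predictions <- function(track, path, p_cut = 0.5) {
  stopifnot(all(c("protein_id", "position", "residue", "protean_score")
                %in% names(track)))
  if (any(track$protean_score < 0 | track$protean_score > 1))
    stop("protean scores outside [0, 1]")
  out <- data.frame(
    protein_id = track$protein_id,
    position = as.integer(track$position),
    residue = track$residue,
    protean_score = sprintf("%.4f", track$protean_score),
    call = classify(track$protean_score, p_cut),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_fasta
#' @param records list of records with `id` and `sequence`.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r)
    c(paste0(">", r$id), r$sequence)))
  writeLines(lines, path)
  invisible(path)
}

# PSI-BLAST writes its matrix in this column order; the writer reproduces
# it so that round-trips exercise the parser's permutation step.
PSIBLAST_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname read_pssm
#' @param profile a [pssm_profile()].
#' @param sequence the protein sequence (supplies the residue column).
#' @export
write_pssm <- function(profile, sequence, path) {
  res <- strsplit(sequence, "")[[1]]
  stopifnot(length(res) == nrow(profile$scores))
  sc <- profile$scores[, PSIBLAST_ORDER, drop = FALSE]
  hdr <- c(
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ",
           paste(sprintf("%2s", c(PSIBLAST_ORDER, PSIBLAST_ORDER)), collapse = " "))
  )
  body <- vapply(seq_along(res), function(i) {
    paste0(sprintf("%5d %s  ", i, res[i]),
           paste(sprintf("%3d", round(sc[i, ])), collapse = " "), "  ",
           paste(sprintf("%3d", integer(20)), collapse = " "),
           sprintf("  %5.2f %9.2f", profile$info[i], 0))
  }, character(1))
  writeLines(c(hdr, body, ""), path)
  invisible(path)
}

#' @rdname read_ss2
#' @param ss an [ss_profile()].
#' @param sequence the protein sequence.
#' @export
write_ss2 <- function(ss, sequence, path) {
  res <- strsplit(sequence, "")[[1]]
  stopifnot(length(res) == nrow(ss$probs))
  body <- vapply(seq_along(res), function(i) {
    sprintf("%4d %s %s  %6.3f %6.3f %6.3f", i, res[i], ss$calls[i],
            ss$probs[i, "C"], ss$probs[i, "H"], ss$probs[i, "E"])
  }, character(1))
  writeLines(c("# PSIPRED VFORMAT (synthetic)", "", body), path)
  invisible(path)
}

#' @rdname read_diso
#' @param diso a [disorder_profile()].
#' @param sequence the protein sequence.
#' @export
write_diso <- function(diso, sequence, path) {
  res <- strsplit(sequence, "")[[1]]
  stopifnot(length(res) == length(diso$scores))
  marks <- ifelse(diso$scores >= 0.5, "*", ".")
  body <- sprintf("%5d %s %s %.3f", seq_along(res), res, marks, diso$scores)
  writeLines(c("#  synthetic disorder track", body), path)
  invisible(path)
}

#' @rdname read_segment_labels
#' @param labels named list of [protean_labels()].
#' @export
write_segment_labels <- function(labels, path) {
  rows <- do.call(rbind, lapply(labels, function(lb) {
    if (nrow(lb$intervals) == 0) return(NULL)
    data.frame(protein_id = lb$protein_id,
               start = lb$intervals[, 1], end = lb$intervals[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(protein_id = character(0), start = integer(0),
                       end = integer(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_clusters
#' @param clusters named integer vector protein id -> cluster id.
#' @export
write_clusters <- function(clusters, path) {
  lines <- vapply(sort(unique(clusters)), function(cl)
    paste(names(clusters)[clusters == cl], collapse = " "), character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- corpus-level validation ------------------------------------------------

#' Validate track length consistency across a corpus
#'
#' Asserts that, for every protein, the sequence, PSSM, secondary
#' structure, disorder track and labels all share the same length L.
#'
#' @param corpus a corpus list as built by [generate_corpus()] or
#'   assembled from the individual readers: each entry needs `id`,
#'   `sequence`, `pssm`, `ss`, `diso`, `labels`.
#' @return Invisibly `TRUE`; stops with the offending protein otherwise.
#' @export
validate_corpus <- function(corpus) {
  for (p in corpus) {
    L <- nchar(p$sequence)
    lens <- c(pssm = nrow(p$pssm$scores), ss = nrow(p$ss$probs),
              diso = length(p$diso$scores), labels = length(p$labels$labels))
    if (any(lens != L))
      stop(sprintf("track length mismatch for %s: sequence %d vs %s",
                   p$id, L,
                   paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")))
  }
  invisible(TRUE)
}
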
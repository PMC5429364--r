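# Synthetic corpus generator: sequences, PSSM / secondary-structure /
# disorder tracks and protean labels with the statistical structure the
# predictor is designed to exploit -- disorder-promoting composition in
# disordered regions, hydrophobic + charged re-enrichment in planted
# protean segments, coil-dominant but indecisive secondary structure
# inside protean segments, and disorder-score valleys centred on them.

# region-specific amino-acid compositions (probability vectors over
# AA_ORDER). "ordered" approximates globular-protein background
# frequencies; "disordered" enriches P,G,S,D,E,K,R and depletes
# W,F,Y,I,L,C; "protean" re-enriches the large hydrophobics L,I,F,Y,W
# and the charged D,E,K,R while staying depleted in P,G,C.
.region_compositions <- function() {
  ordered <- c(A = .083, C = .014, D = .055, E = .067, F = .039, G = .071,
               H = .023, I = .059, K = .058, L = .097, M = .024, N = .040,
               P = .047, Q = .039, R = .055, S = .066, T = .053, V = .069,
               W = .011, Y = .029)
  disordered <- c(A = .070, C = .004, D = .080, E = .100, F = .015, G = .100,
                  H = .020, I = .025, K = .080, L = .040, M = .012, N = .040,
                  P = .100, Q = .050, R = .070, S = .100, T = .050, V = .030,
                  W = .003, Y = .011)
  protean <- c(A = .055, C = .003, D = .090, E = .105, F = .045, G = .030,
               H = .020, I = .060, K = .095, L = .100, M = .018, N = .037,
               P = .025, Q = .035, R = .085, S = .060, T = .040, V = .050,
               W = .015, Y = .032)
  lapply(list(ordered = ordered, disordered = disordered, protean = protean),
         function(x) x[AA_ORDER] / sum(x))
}

#' Synthetic corpus configuration
#'
#' Defines the study conditions the generator emulates. The defaults
#' yield a corpus with roughly 2% protean residues (one planted segment
#' in a quarter of the proteins, mode length near 15 residues), a
#' disorder track that plateaus high over disordered regions with a
#' valley dipping toward (but not below) the 0.5 threshold at each
#' protean segment, coil-dominant secondary structure in disordered
#' regions (85% coil) with a higher state-switching rate inside protean
#' segments, and pseudo-PSSMs peaked on the true residue with lower
#' per-position information in disordered regions.
#'
#' The `"topography_only"` preset removes every signal except the
#' disorder-track topography: uniform residue composition everywhere,
#' one secondary-structure process for the whole chain, pure-noise
#' PSSMs, a fully disordered plateau, and -- besides the shallow valley
#' at each protean segment -- longer decoy valleys elsewhere, so that
#' the topographic run length (not the peak/valley class alone)
#' separates the classes.
#'
#' @param n_proteins number of proteins.
#' @param length_range min/max sequence length.
#' @param disorder_frac fraction of each sequence that is disordered.
#' @param protean_prob probability that a protein carries one protean
#'   segment.
#' @param protean_meanlog,protean_sdlog log-normal segment-length
#'   parameters (mode near 15 residues).
#' @param protean_range hard min/max protean segment length.
#' @param plateau_high,plateau_low disorder-track levels over
#'   disordered / ordered regions.
#' @param valley_depth relative dip of the disorder track at a protean
#'   segment (fraction of the plateau level).
#' @param noise half-width of the uniform noise added to the disorder
#'   track (must stay below the valley depth for the valley to remain
#'   detectable).
#' @param ss_switch_rate per-residue probability of resampling the
#'   secondary-structure state, by region kind.
#' @param ss_stationary stationary H/E/C distributions by region kind.
#' @param homolog_frac fraction of proteins generated as mutated copies
#'   (~85% identity) of earlier proteins, giving non-trivial sequence
#'   clusters.
#' @param preset `"default"` or `"topography_only"`.
#' @param seed RNG seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200,
                             length_range = c(100, 300),
                             disorder_frac = 0.40,
                             protean_prob = 0.30,
                             protean_meanlog = log(15),
                             protean_sdlog = 0.35,
                             protean_range = c(5, 60),
                             plateau_high = 0.82,
                             plateau_low = 0.18,
                             valley_depth = 0.30,
                             noise = 0.03,
                             ss_switch_rate = c(ordered = 0.10,
                                                disordered = 0.08,
                                                protean = 0.35),
                             ss_stationary = list(
                               ordered = c(H = 0.35, E = 0.15, C = 0.50),
                               disordered = c(H = 0.075, E = 0.075, C = 0.85),
                               protean = c(H = 0.32, E = 0.05, C = 0.63)),
                             homolog_frac = 0.10,
                             preset = c("default", "topography_only"),
                             seed = 1) {
  preset <- match.arg(preset)
  stopifnot(n_proteins >= 1, disorder_frac > 0, disorder_frac < 1,
            protean_prob >= 0, protean_prob <= 1,
            valley_depth >= 0, valley_depth < 1, noise >= 0)
  if (noise > 0 && valley_depth > 0 && noise >= valley_depth * plateau_high / 2)
    stop("noise too large relative to the valley depth")
  structure(list(
    n_proteins = as.integer(n_proteins), length_range = length_range,
    disorder_frac = disorder_frac, protean_prob = protean_prob,
    protean_meanlog = protean_meanlog, protean_sdlog = protean_sdlog,
    protean_range = protean_range, plateau_high = plateau_high,
    plateau_low = plateau_low, valley_depth = valley_depth, noise = noise,
    ss_switch_rate = ss_switch_rate, ss_stationary = ss_stationary,
    homolog_frac = homolog_frac, preset = preset, seed = as.integer(seed),
    compositions = .region_compositions()
  ), class = "synthetic_config")
}

# sample one element of a vector (avoids sample()'s scalar expansion)
.sample1 <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

.sample_ss <- function(n, rate, stationary) {
  states <- character(n)
  states[1] <- sample(names(stationary), 1, prob = stationary)
  if (n > 1) for (i in 2:n) {
    states[i] <- if (runif(1) < rate)
      sample(names(stationary), 1, prob = stationary) else states[i - 1]
  }
  states
}

# region kinds per residue -> SS calls + smoothed probability rows
.make_ss <- function(kinds, config) {
  L <- length(kinds)
  calls <- character(L)
  r <- rle(kinds)
  pos <- 1L
  for (j in seq_along(r$lengths)) {
    n <- r$lengths[j]
    kind <- r$values[j]
    calls[pos:(pos + n - 1L)] <-
      .sample_ss(n, config$ss_switch_rate[[kind]], config$ss_stationary[[kind]])
    pos <- pos + n
  }
  probs <- matrix(0.09, L, 3, dimnames = list(NULL, c("H", "E", "C")))
  probs[cbind(seq_len(L), match(calls, c("H", "E", "C")))] <- 0.82
  ss_profile(probs, calls)
}

.make_pssm <- function(res, kinds, config, id) {
  L <- length(res)
  if (config$preset == "topography_only") {
    scores <- matrix(round(rnorm(L * 20, 0, 2)), L, 20,
                     dimnames = list(NULL, AA_ORDER))
    info <- rep(1, L)
  } else {
    scores <- matrix(round(rnorm(L * 20, -1, 1.2)), L, 20,
                     dimnames = list(NULL, AA_ORDER))
    idx <- match(res, AA_ORDER)
    ok <- !is.na(idx)
    scores[cbind(which(ok), idx[ok])] <- round(rnorm(sum(ok), 6, 1))
    info <- ifelse(kinds == "ordered", rnorm(L, 1.5, 0.3), rnorm(L, 0.6, 0.2))
    info <- pmax(info, 0)
  }
  pssm_profile(scores, info, id)
}

.sample_protean_length <- function(config) {
  len <- round(stats::rlnorm(1, config$protean_meanlog, config$protean_sdlog))
  min(max(len, config$protean_range[1]), config$protean_range[2])
}

# one protein under the default preset; returns the corpus entry
.generate_default <- function(config, id) {
  L <- .sample1(config$length_range[1]:config$length_range[2])
  dis_len <- max(round(config$disorder_frac * L), config$protean_range[1] + 4L)
  dis_start <- .sample1(seq_len(L - dis_len + 1L))
  dis_end <- dis_start + dis_len - 1L
  kinds <- rep("ordered", L)
  kinds[dis_start:dis_end] <- "disordered"
  protean <- NULL
  if (runif(1) < config$protean_prob) {
    plen <- min(.sample_protean_length(config), dis_len - 4L)
    if (plen >= config$protean_range[1]) {
      pstart <- .sample1((dis_start + 2L):(dis_end - plen - 1L))
      protean <- c(pstart, pstart + plen - 1L)
      kinds[protean[1]:protean[2]] <- "protean"
    }
  }
  comp <- config$compositions
  res <- vapply(kinds, function(kd) {
    key <- if (kd == "protean") "protean" else if (kd == "disordered")
      "disordered" else "ordered"
    sample(AA_ORDER, 1, prob = comp[[key]])
  }, character(1), USE.NAMES = FALSE)
  track <- ifelse(kinds == "ordered", config$plateau_low, config$plateau_high)
  if (!is.null(protean))
    track[protean[1]:protean[2]] <-
      config$plateau_high * (1 - config$valley_depth)
  if (config$noise > 0)
    track <- track + runif(L, -config$noise, config$noise)
  track <- pmin(1, pmax(0, track))
  list(id = id, sequence = paste(res, collapse = ""),
       kinds = kinds,
       pssm = .make_pssm(res, kinds, config, id),
       ss = .make_ss(kinds, config),
       diso = disorder_profile(track),
       labels = protean_labels(id, if (is.null(protean)) NULL else
         matrix(protean, ncol = 2), L))
}

# one protein under the topography_only preset: all-disordered plateau,
# shallow true valleys (length ~15) plus longer decoy valleys, and no
# other informative track
.generate_topography_only <- function(config, id) {
  L <- .sample1(config$length_range[1]:config$length_range[2])
  res <- sample(AA_ORDER, L, replace = TRUE)
  kinds <- rep("disordered", L)
  track <- rep(config$plateau_high, L)
  depth <- 0.15
  place <- function(len, occupied) {
    # free interval with 3-residue flanks inside the plateau
    cand <- which(!occupied)
    starts <- cand[cand + len + 2L <= L & cand >= 4L]
    starts <- starts[vapply(starts, function(s)
      !any(occupied[(s - 3L):(s + len + 2L)]), logical(1))]
    if (length(starts) == 0) return(NULL)
    s <- .sample1(starts)
    c(s, s + len - 1L)
  }
  occupied <- rep(FALSE, L)
  plen <- .sample1(11:19)
  protean <- place(plen, occupied)
  if (is.null(protean)) stop("could not place a protean valley; sequence too short")
  occupied[(protean[1] - 3L):(protean[2] + 3L)] <- TRUE
  track[protean[1]:protean[2]] <- config$plateau_high * (1 - depth)
  for (d in seq_len(sample(1:2, 1))) {
    dec <- place(sample(35:55, 1), occupied)
    if (is.null(dec)) break
    occupied[max(dec[1] - 3L, 1L):min(dec[2] + 3L, L)] <- TRUE
    track[dec[1]:dec[2]] <- config$plateau_high * (1 - depth)
  }
  list(id = id, sequence = paste(res, collapse = ""),
       kinds = kinds,
       pssm = .make_pssm(res, kinds, config, id),
       ss = .make_ss(kinds, config),
       diso = disorder_profile(track),
       labels = protean_labels(id, matrix(protean, ncol = 2), L))
}

#' Generate one synthetic protein
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed for this protein.
#' @param id protein identifier.
#' @return A corpus entry: `id`, `sequence`, `kinds` (per-residue region
#'   kind), `pssm`, `ss`, `diso`, `labels`.
#' @export
generate_protein <- function(config, seed = config$seed, id = "p1") {
  .with_seed(seed, {
    if (config$preset == "topography_only")
      .generate_topography_only(config, id)
    else .generate_default(config, id)
  })
}

#' Generate a synthetic corpus
#'
#' Generates `n_proteins` proteins (a `homolog_frac` share of them as
#' mutated copies of earlier proteins, forming sequence families) and,
#' optionally, writes the corpus to disk in all supported external
#' formats: a FASTA file, per-protein `.pssm` / `.ss2` / `.diso` track
#' files, a protean-interval TSV and a family cluster file. Re-reading
#' the files with [read_corpus()] reproduces the in-memory corpus.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (`NULL` = in-memory only).
#' @return Corpus list of class `protean_corpus` with attributes
#'   `config` and `families` (named vector protein id -> family id).
#' @export
generate_corpus <- function(config = synthetic_config(), dir = NULL) {
  n <- config$n_proteins
  n_hom <- if (config$preset == "default")
    min(round(config$homolog_frac * n), n - 1L) else 0L
  n_base <- n - n_hom
  ids <- sprintf("p%03d", seq_len(n))
  corpus <- vector("list", n)
  families <- integer(n)
  for (i in seq_len(n_base)) {
    corpus[[i]] <- generate_protein(config, seed = config$seed + i, id = ids[i])
    families[i] <- i
  }
  if (n_hom > 0) {
    comp <- config$compositions
    for (j in seq_len(n_hom)) {
      i <- n_base + j
      corpus[[i]] <- .with_seed(config$seed + i, {
        base <- corpus[[sample.int(n_base, 1)]]
        res <- strsplit(base$sequence, "")[[1]]
        L <- length(res)
        nmut <- round(0.15 * L)
        at <- sample.int(L, nmut)
        res[at] <- vapply(base$kinds[at], function(kd)
          sample(AA_ORDER, 1, prob = comp[[kd]]), character(1),
          USE.NAMES = FALSE)
        entry <- base
        entry$id <- ids[i]
        entry$sequence <- paste(res, collapse = "")
        entry$pssm <- .make_pssm(res, base$kinds, config, ids[i])
        entry$labels$protein_id <- ids[i]
        attr(entry, "family_of") <- base$id
        entry
      })
      families[i] <- match(attr(corpus[[i]], "family_of"), ids)
    }
  }
  names(families) <- ids
  corpus <- structure(corpus, names = ids, config = config,
                      families = families, class = "protean_corpus")
  if (!is.null(dir)) write_corpus(corpus, dir)
  corpus
}

#' Write a corpus to disk in all external formats
#'
#' @param corpus a `protean_corpus`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_fasta(lapply(corpus, function(p) list(id = p$id, sequence = p$sequence)),
              file.path(dir, "sequences.fasta"))
  for (p in corpus) {
    write_pssm(p$pssm, p$sequence, file.path(dir, "tracks", paste0(p$id, ".pssm")))
    write_ss2(p$ss, p$sequence, file.path(dir, "tracks", paste0(p$id, ".ss2")))
    write_diso(p$diso, p$sequence, file.path(dir, "tracks", paste0(p$id, ".diso")))
  }
  write_segment_labels(lapply(corpus, `[[`, "labels"),
                       file.path(dir, "labels.tsv"))
  fam <- attr(corpus, "families")
  if (!is.null(fam)) write_clusters(fam, file.path(dir, "clusters.txt"))
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' Expects `sequences.fasta`, a `tracks/` directory with per-protein
#' `<id>.pssm`, `<id>.ss2` and `<id>.diso` files, and `labels.tsv`.
#' A missing track file is an error naming the protein.
#'
#' @param dir corpus directory.
#' @return A `protean_corpus` (without generator metadata).
#' @export
read_corpus <- function(dir) {
  records <- read_fasta(file.path(dir, "sequences.fasta"))
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path))
    read_segment_labels(labels_path, records)
  else lapply(records, function(r)
    protean_labels(r$id, NULL, nchar(r$sequence)))
  corpus <- lapply(records, function(r) {
    L <- nchar(r$sequence)
    paths <- file.path(dir, "tracks", paste0(r$id, c(".pssm", ".ss2", ".diso")))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("missing track file for protein ", r$id, ": ", missing[1])
    list(id = r$id, sequence = r$sequence,
         pssm = read_pssm(paths[1], expected_length = L, protein_id = r$id),
         ss = read_ss2(paths[2]),
         diso = read_diso(paths[3]),
         labels = labels[[r$id]])
  })
  names(corpus) <- vapply(records, `[[`, "", "id")
  structure(corpus, class = "protean_corpus")
}

#' Shuffle corpus labels (negative control)
#'
#' Permutes the per-residue label vectors across residues within each
#' protein, preserving the overall positive fraction while destroying
#' the association between tracks and labels. Used as the
#' shuffled-label control against which cross-validated performance is
#' compared.
#'
#' @param corpus a `protean_corpus`.
#' @param seed RNG seed.
#' @return The corpus with permuted labels.
#' @export
shuffle_labels <- function(corpus, seed = 1) {
  .with_seed(seed, {
    for (i in seq_along(corpus)) {
      lab <- corpus[[i]]$labels$labels
      corpus[[i]]$labels$labels <- sample(lab)
      corpus[[i]]$labels$intervals <- matrix(integer(0), ncol = 2)
    }
    corpus
  })
}
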
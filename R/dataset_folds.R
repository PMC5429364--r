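# Cluster-grouped cross-validation: approximate single-linkage sequence
# clustering plus size-balanced fold construction so that similar
# sequences never straddle the train/test boundary.

# union-find with path compression
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Greedy single-linkage sequence clustering
#'
#' A lightweight stand-in for an external clustering tool: two sequences
#' are linked when a gapless (single-diagonal) alignment seeded by a
#' shared k-mer reaches at least `identity_threshold` identity over at
#' least `coverage_threshold` of the shorter sequence; clusters are the
#' connected components (single linkage), so similarity is transitive by
#' construction. Precomputed cluster files from a dedicated tool
#' ([read_clusters()]) are first-class input everywhere this result is
#' used.
#'
#' @param sequences list of records with `id` and `sequence` (as from
#'   [read_fasta()]).
#' @param identity_threshold minimum fractional identity over the
#'   aligned overlap (default 0.30).
#' @param coverage_threshold minimum overlap length as a fraction of the
#'   shorter sequence (default 0.50).
#' @param k seed k-mer length; pairs sharing no k-mer are never aligned.
#' @return Named integer vector protein id -> cluster id (1-based,
#'   ordered by first member appearance).
#' @export
greedy_cluster <- function(sequences, identity_threshold = 0.30,
                           coverage_threshold = 0.50, k = 5) {
  n <- length(sequences)
  if (n == 0) stop("no sequences to cluster")
  ids <- vapply(sequences, `[[`, "", "id")
  seqs <- lapply(sequences, function(r) strsplit(r$sequence, "")[[1]])
  lens <- lengths(seqs)
  # k-mer index: kmer string -> integer vector of sequence indices
  kmer_index <- new.env(hash = TRUE, parent = emptyenv())
  kmers_of <- vector("list", n)
  for (i in seq_len(n)) {
    if (lens[i] < k) next
    km <- vapply(seq_len(lens[i] - k + 1), function(p)
      paste(seqs[[i]][p:(p + k - 1)], collapse = ""), character(1))
    kmers_of[[i]] <- km
    for (kmu in unique(km))
      assign(kmu, c(kmer_index[[kmu]], i), envir = kmer_index)
  }
  # candidate pairs share at least one k-mer
  cand <- new.env(hash = TRUE, parent = emptyenv())
  for (kmu in ls(kmer_index)) {
    members <- unique(kmer_index[[kmu]])
    if (length(members) < 2) next
    for (a in seq_along(members)) for (b in seq_len(a - 1)) {
      i <- min(members[a], members[b]); j <- max(members[a], members[b])
      assign(paste0(i, "_", j), TRUE, envir = cand)
    }
  }
  parent <- seq_len(n)
  for (key in ls(cand)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    i <- ij[1]; j <- ij[2]
    if (.uf_find(parent, i) == .uf_find(parent, j)) next
    if (.pair_linked(seqs[[i]], seqs[[j]], kmers_of[[i]], kmers_of[[j]],
                     identity_threshold, coverage_threshold, k)) {
      parent[.uf_find(parent, i)] <- .uf_find(parent, j)
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  cl <- match(roots, unique(roots))
  setNames(cl, ids)
}

# best gapless diagonal alignment restricted to diagonals seeded by a
# shared k-mer
.pair_linked <- function(a, b, km_a, km_b, id_thr, cov_thr, k) {
  shared <- intersect(km_a, km_b)
  if (length(shared) == 0) return(FALSE)
  diags <- unique(unlist(lapply(shared, function(kmu)
    outer(which(km_a == kmu), which(km_b == kmu), `-`))))
  min_len <- min(length(a), length(b))
  need <- ceiling(cov_thr * min_len)
  for (d in diags) {
    # a[i] aligned with b[i - d]
    i_lo <- max(1L, 1L + d); i_hi <- min(length(a), length(b) + d)
    overlap <- i_hi - i_lo + 1L
    if (overlap < need) next
    idty <- mean(a[i_lo:i_hi] == b[(i_lo - d):(i_hi - d)])
    if (idty >= id_thr) return(TRUE)
  }
  FALSE
}

#' Build cluster-grouped, size-balanced folds
#'
#' Assigns whole clusters to folds so that no cluster ever spans a fold
#' boundary, balancing folds by protein count: clusters are taken in
#' decreasing size order (ties broken by cluster id) and each is placed
#' in the currently smallest fold. The max-min fold size difference is
#' therefore bounded by the largest cluster's size.
#'
#' @param clusters named integer vector protein id -> cluster id.
#' @param k number of folds (default 5).
#' @param seed optional seed; when given, clusters of equal size are
#'   shuffled among themselves before the greedy pass.
#' @return Object of class `fold_assignment`: named integer vector
#'   protein id -> fold in `1..k`, with attribute `k`.
#' @export
build_folds <- function(clusters, k = 5, seed = NULL) {
  sizes <- table(clusters)
  if (k > length(sizes))
    stop("more folds (", k, ") than clusters (", length(sizes), ")")
  ord_ids <- as.integer(names(sizes))
  ord <- order(-as.integer(sizes), ord_ids)
  if (!is.null(seed)) {
    # shuffle within equal-size blocks only; balance is unaffected
    sz <- as.integer(sizes)[ord]
    blocks <- split(ord, factor(sz, levels = unique(sz)))
    ord <- .with_seed(seed, unlist(
      lapply(blocks, function(ix) if (length(ix) > 1) sample(ix) else ix),
      use.names = FALSE))
  }
  fold_of_cluster <- integer(length(sizes))
  names(fold_of_cluster) <- names(sizes)
  fold_sizes <- integer(k)
  for (ci in ord) {
    cl_name <- names(sizes)[ci]
    target <- which.min(fold_sizes)
    fold_of_cluster[cl_name] <- target
    fold_sizes[target] <- fold_sizes[target] + as.integer(sizes[[cl_name]])
  }
  out <- fold_of_cluster[as.character(clusters)]
  names(out) <- names(clusters)
  structure(out, k = k, class = "fold_assignment")
}

#' Split a corpus into train and test sets by fold
#'
#' @param corpus corpus list; entries carry `id` and residue labels.
#' @param folds a [build_folds()] assignment.
#' @param test_fold the held-out fold index in `1..k`.
#' @return List with `train` and `test` corpus subsets (disjoint cover
#'   of the corpus).
#' @export
split_corpus <- function(corpus, folds, test_fold) {
  k <- attr(folds, "k")
  if (!test_fold %in% seq_len(k)) stop("invalid test fold: ", test_fold)
  ids <- vapply(corpus, `[[`, "", "id")
  missing <- setdiff(ids, names(folds))
  if (length(missing) > 0)
    stop("proteins without fold assignment: ", paste(missing, collapse = ", "))
  in_test <- folds[ids] == test_fold
  list(train = corpus[!in_test], test = corpus[in_test])
}

#' @rdname build_folds
#' @param folds a `fold_assignment`.
#' @param path output TSV path.
#' @export
write_fold_assignment <- function(folds, path) {
  write.table(data.frame(protein_id = names(folds), fold = as.integer(folds)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
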
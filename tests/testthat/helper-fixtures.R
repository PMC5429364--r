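# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small default-preset corpus for fast structural tests
tiny_corpus <- function() .cached("tiny", function()
  generate_corpus(synthetic_config(n_proteins = 12,
                                   length_range = c(60, 120), seed = 11)))

# mid-size default corpus for cross-validation checks
cv_corpus <- function() .cached("cv", function()
  generate_corpus(synthetic_config(n_proteins = 60,
                                   length_range = c(80, 160), seed = 7)))

# corpus where only the disorder-track topography separates the classes
topo_corpus <- function() .cached("topo", function()
  generate_corpus(synthetic_config(n_proteins = 40,
                                   length_range = c(120, 200),
                                   preset = "topography_only", seed = 19)))

# large default corpus for consensus parameter-recovery checks
consensus_corpus <- function() .cached("consensus", function()
  generate_corpus(synthetic_config(n_proteins = 200, seed = 23)))

# feature-group subset search on the topography-only corpus (3 folds,
# 10 trees: enumeration and ranking, not absolute performance)
topo_search <- function() .cached("topo_search", function() {
  corpus <- topo_corpus()
  folds <- build_folds(setNames(seq_along(corpus), names(corpus)), k = 3)
  group_subset_search(corpus, folds,
                      forest_config(n_trees = 10, max_depth = 13, seed = 29))
})

# cluster-grouped 5-fold CV on the 200-protein corpus, with the
# shuffled-label negative control under the same folds and forest
study_cv <- function() .cached("study_cv", function() {
  corpus <- consensus_corpus()
  folds <- build_folds(attr(corpus, "families"), k = 5)
  cfg <- forest_config(n_trees = 30, max_depth = 13, seed = 17)
  oof <- cross_validate(corpus, folds, cfg)
  pr <- pr_curve(oof$score, oof$label)
  oof0 <- cross_validate(shuffle_labels(corpus, seed = 18), folds, cfg)
  pr0 <- pr_curve(oof0$score, oof0$label)
  list(oof = oof, auc = attr(pr, "auc"), baseline = attr(pr, "baseline"),
       auc_shuffled = attr(pr0, "auc"))
})

# O(L^2) brute-force topography oracle: per residue and side, step
# outward one position at a time until a score leaves the 10% band;
# that first deviation (lower/higher) is the side's verdict. A peak
# needs "lower" on both sides, a valley "higher" on both sides.
topography_oracle <- function(s, delta = 0.10) {
  L <- length(s)
  verdict <- function(i, step) {
    j <- i + step
    while (j >= 1 && j <= L) {
      if (s[j] <= (1 - delta) * s[i]) return("lower")
      if (s[j] >= (1 + delta) * s[i]) return("higher")
      j <- j + step
    }
    "none"
  }
  vapply(seq_len(L), function(i) {
    a <- verdict(i, -1L)
    b <- verdict(i, 1L)
    if (a == "lower" && b == "lower") 1L
    else if (a == "higher" && b == "higher") -1L
    else 0L
  }, integer(1))
}

# hand-built 3-residue PSSM file in the PSI-BLAST -Q dialect
write_tiny_pssm <- function(path, n = 3) {
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hdr <- c("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
           paste(" ", paste(c(ord, ord), collapse = "  ")))
  res <- c("M", "K", "V", "A", "L")[seq_len(n)]
  rows <- vapply(seq_len(n), function(i) {
    scores <- ((i - 1) * 20 + 1):(i * 20)  # distinct values per cell
    paste(c(sprintf("%5d %s", i, res[i]), sprintf("%3d", scores),
            sprintf("%3d", rep(0, 20)), sprintf("%5.2f", i / 10),
            sprintf("%5.2f", 0)), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows, ""), path)
  list(file_order = ord, residues = res)
}
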
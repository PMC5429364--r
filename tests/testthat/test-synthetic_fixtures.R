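test_that("generation is deterministic and internally consistent", {
  cfg <- synthetic_config(n_proteins = 6, length_range = c(60, 100), seed = 61)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  expect_true(validate_corpus(c1))
  # labels consistent with the planted intervals
  for (p in c1) {
    want <- integer(nchar(p$sequence))
    iv <- p$labels$intervals
    if (nrow(iv) > 0) for (i in seq_len(nrow(iv)))
      want[iv[i, 1]:iv[i, 2]] <- 1L
    expect_equal(p$labels$labels, want)
  }
})

test_that("protean segments sit inside disordered regions above threshold", {
  cfg <- synthetic_config(n_proteins = 15, length_range = c(80, 160),
                          noise = 0, seed = 62)
  corpus <- generate_corpus(cfg)
  for (p in corpus) {
    lab <- p$labels$labels
    if (sum(lab) == 0) next
    expect_true(all(p$diso$scores[lab == 1] >= 0.5))
    expect_true(all(p$kinds[lab == 1] == "protean"))
  }
})

test_that("the corpus positive fraction matches the configured target", {
  corpus <- consensus_corpus()
  labels <- unlist(lapply(corpus, function(p) p$labels$labels))
  # protean_prob 0.30 x mode-15 segments over ~200-residue proteins
  # lands in the 1.4-2.2% band typical of protean-annotated corpora
  expect_gt(mean(labels), 0.013)
  expect_lt(mean(labels), 0.025)
})

test_that("disorder valleys make protean residues valley-classified", {
  cfg <- synthetic_config(n_proteins = 10, length_range = c(100, 160),
                          seed = 63)
  corpus <- generate_corpus(cfg)
  hits <- 0L; total <- 0L
  for (p in corpus) {
    lab <- p$labels$labels
    if (sum(lab) == 0) next
    total <- total + 1L
    klass <- topography_class(p$diso)
    if (any(klass[lab == 1] == -1L)) hits <- hits + 1L
  }
  expect_gt(total, 0)
  expect_equal(hits, total)  # every planted valley is detected
})

test_that("writing and re-reading a corpus round-trips", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_proteins = 5, length_range = c(60, 90), seed = 64)
  corpus <- generate_corpus(cfg, dir = dir)
  back <- read_corpus(dir)
  expect_equal(names(back), names(corpus))
  for (id in names(corpus)) {
    expect_equal(back[[id]]$sequence, corpus[[id]]$sequence)
    expect_equal(back[[id]]$pssm$scores, corpus[[id]]$pssm$scores)
    expect_lt(max(abs(back[[id]]$pssm$info - corpus[[id]]$pssm$info)),
              0.006)  # printed at 2 decimals
    expect_equal(back[[id]]$ss$calls, corpus[[id]]$ss$calls)
    expect_lt(max(abs(back[[id]]$diso$scores - corpus[[id]]$diso$scores)),
              0.0006)  # printed at 3 decimals
    expect_equal(back[[id]]$labels$labels, corpus[[id]]$labels$labels)
  }
  # family clusters round-trip through the cluster file
  cl <- read_clusters(file.path(dir, "clusters.txt"))
  fam <- attr(corpus, "families")
  expect_equal(length(unique(cl)), length(unique(fam)))
})

test_that("homolog copies share their family's cluster under greedy clustering", {
  cfg <- synthetic_config(n_proteins = 12, length_range = c(80, 120),
                          homolog_frac = 0.25, seed = 65)
  corpus <- generate_corpus(cfg)
  fam <- attr(corpus, "families")
  expect_gt(sum(duplicated(fam)), 0)
  cl <- greedy_cluster(lapply(corpus, function(p)
    list(id = p$id, sequence = p$sequence)))
  for (f in unique(fam[duplicated(fam)])) {
    members <- names(fam)[fam == f]
    expect_equal(length(unique(cl[members])), 1)
  }
})

test_that("shuffled labels keep the rate but destroy the intervals", {
  corpus <- tiny_corpus()
  sh <- shuffle_labels(corpus, seed = 66)
  expect_equal(sum(unlist(lapply(sh, function(p) p$labels$labels))),
               sum(unlist(lapply(corpus, function(p) p$labels$labels))))
  per <- vapply(seq_along(corpus), function(i)
    sum(corpus[[i]]$labels$labels) == sum(sh[[i]]$labels$labels), logical(1))
  expect_true(all(per))
})

test_that("the topography-only preset plants decoy valleys and no other signal", {
  corpus <- topo_corpus()
  p <- corpus[[1]]
  expect_true(all(p$diso$scores >= 0.5))        # fully disordered plateau
  expect_true(all(p$kinds == "disordered"))
  klass <- topography_class(p$diso)
  lab <- p$labels$labels
  expect_true(all(klass[lab == 1] == -1L))      # true valley at the segment
  # decoys: valley residues outside the labelled segment exist
  expect_gt(sum(klass == -1L & lab == 0L), 0)
})
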
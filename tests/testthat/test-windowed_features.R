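make_pssm <- function(scores, info = NULL, id = "p") {
  if (is.null(info)) info <- rep(1, nrow(scores))
  pssm_profile(scores, info, id)
}

test_that("PSSM scaler takes per-amino-acid extrema and pools corpora", {
  set.seed(4)
  m1 <- matrix(rnorm(5 * 20), 5, 20)
  m1[, 1] <- c(-2, 0, 3, 1, 2)
  p1 <- make_pssm(m1)
  sc <- fit_pssm_scaler(list(p1))
  expect_equal(unname(sc$min["A"]), -2)
  expect_equal(unname(sc$max["A"]), 3)

  # scaler on two profiles equals scaler on their concatenation
  m2 <- matrix(rnorm(7 * 20), 7, 20)
  pooled <- fit_pssm_scaler(list(make_pssm(rbind(m1, m2))))
  separate <- fit_pssm_scaler(list(p1, make_pssm(m2)))
  expect_equal(separate$min, pooled$min)
  expect_equal(separate$max, pooled$max)

  expect_error(fit_pssm_scaler(list()), "zero profiles")
})

test_that("PSSM scaling maps extrema to 0/1, clamps, and handles constants", {
  m <- matrix(0, 4, 20)
  m[, 2] <- c(-1, 0, 1, 3)   # column C
  m[, 3] <- 1                # constant column D
  train <- make_pssm(m)
  scaler <- fit_pssm_scaler(list(train))
  scaled <- scale_pssm(train, scaler)
  expect_equal(unname(scaled$scores[1, "C"]), 0)
  expect_equal(unname(scaled$scores[4, "C"]), 1)
  expect_equal(unname(scaled$scores[, "D"]), rep(0.5, 4))

  unseen <- matrix(0, 1, 20)
  unseen[1, 2] <- 10  # above the training max
  expect_equal(unname(scale_pssm(make_pssm(unseen), scaler)$scores[1, "C"]), 1)
  expect_true(all(scaled$scores >= 0 & scaled$scores <= 1))
})

test_that("mutability features concatenate the window with zero padding", {
  set.seed(5)
  L <- 30
  scaled <- make_pssm(matrix(runif(L * 20), L, 20))
  v <- mutability_features(scaled, pos = 15)
  expect_length(v, 300)
  expect_equal(v[1:20], unname(scaled$scores[8, ]))
  expect_equal(v[281:300], unname(scaled$scores[22, ]))

  first <- mutability_features(scaled, pos = 1)
  expect_equal(first[1:140], rep(0, 140))  # 7 offsets before the start
  expect_equal(first[141:160], unname(scaled$scores[1, ]))
  expect_error(mutability_features(scaled, pos = 31), "range")
})

test_that("conservation averages information over the truncated window", {
  L <- 29
  info <- rep(0, L); info[15] <- 15
  prof <- make_pssm(matrix(0, L, 20), info)
  expect_equal(conservation_feature(prof, 15), 1.0)  # 15/15, full window

  const <- make_pssm(matrix(0, 8, 20), rep(0.7, 8))
  for (p in c(1, 4, 8))
    expect_equal(conservation_feature(const, p), 0.7)

  # terminal residue of a length-8 protein: mean over 8 residues, not 15
  info8 <- seq(0.1, 0.8, by = 0.1)
  prof8 <- make_pssm(matrix(0, 8, 20), info8)
  expect_equal(conservation_feature(prof8, 1), mean(info8))
})

test_that("composition is a window fraction over standard residues", {
  polyA <- paste(rep("A", 20), collapse = "")
  cf <- composition_features(polyA, 10)
  expect_equal(unname(cf["A"]), 1)
  expect_equal(sum(cf), 1)

  distinct <- paste(AA_ORDER, collapse = "")
  cf2 <- composition_features(distinct, 10)  # window covers residues 3..17
  expect_equal(unname(cf2[AA_ORDER[3]]), 1 / 15)
  expect_equal(unname(cf2[AA_ORDER[1]]), 0)
  expect_equal(sum(cf2), 1)

  # ambiguity codes count toward neither numerator nor denominator
  withX <- "AAAXXAAA"
  cfx <- composition_features(withX, 4, window = 5)
  expect_equal(unname(cfx["A"]), 1)
})

test_that("property features recover class fractions, hydropathy and mass", {
  polyK <- paste(rep("K", 21), collapse = "")
  pf <- property_features(polyK, 11)
  expect_equal(unname(pf["pol_basic"]), 1)
  expect_equal(unname(pf["charge_positive"]), 1)
  expect_equal(unname(pf["hydropathy"]), -3.9)
  expect_equal(unname(pf["mass"]), 128.17)

  polyI <- paste(rep("I", 21), collapse = "")
  expect_equal(unname(property_features(polyI, 11)["hydropathy"]), 4.5)

  set.seed(6)
  mixed <- paste(sample(AA_ORDER, 40, replace = TRUE), collapse = "")
  pm <- property_features(mixed, 20)
  expect_equal(sum(pm[1:4]), 1)  # polarity fractions
  expect_equal(sum(pm[5:7]), 1)  # charge fractions
})

test_that("secondary-structure features are truncated window means", {
  probs <- matrix(rep(c(0.2, 0.1, 0.7), each = 9), 9, 3)
  ss <- ss_profile(probs, strrep("C", 9))
  expect_equal(unname(ss_features(ss, 5)), c(0.2, 0.1, 0.7))

  probs3 <- rbind(c(0.5, 0.2, 0.3), c(0.1, 0.1, 0.8), c(0.3, 0.3, 0.4))
  ss3 <- ss_profile(probs3, "HCC")
  expect_equal(unname(ss_features(ss3, 2)), colMeans(probs3), tolerance = 1e-12)
  v <- ss_features(ss3, 1)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(sum(v), 1, tolerance = 0.05)
})

test_that("assembled matrices have the full column layout for any protein", {
  corpus <- tiny_corpus()
  scaler <- fit_pssm_scaler(lapply(corpus, `[[`, "pssm"))
  p <- corpus[[3]]
  fm <- assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss, p$diso)
  expect_equal(ncol(fm), 342)
  expect_equal(nrow(fm), nchar(p$sequence))
  gi <- attr(fm, "group_index")
  expect_equal(range(gi$group1), c(1, 300))
  expect_equal(gi$group2, 301L)
  expect_equal(range(gi$group3), c(302, 321))
  expect_equal(range(gi$group4), c(322, 330))
  expect_equal(range(gi$group5), c(331, 333))
  expect_equal(range(gi$group6), c(334, 340))
  expect_equal(range(gi$group7), c(341, 342))
  expect_equal(sort(unlist(gi)), 1:342, ignore_attr = TRUE)
  expect_true(all(is.finite(fm)))
  expect_true(all(fm[, gi$group1] >= 0 & fm[, gi$group1] <= 1))

  # an all-zero disorder track zeroes the disordered-segment triplet
  zero <- disorder_profile(rep(0, nchar(p$sequence)))
  fz <- assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss, zero)
  expect_true(all(fz[, gi$group6[2:4]] == 0))

  expect_error(
    assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss,
                      disorder_profile(c(0.5, 0.5))),
    "mismatch")
})

test_that("feature values do not depend on corpus ordering", {
  corpus <- tiny_corpus()
  scaler <- fit_pssm_scaler(lapply(corpus, `[[`, "pssm"))
  ext1 <- extract_corpus_features(corpus[c(1, 2)], scaler)
  ext2 <- extract_corpus_features(corpus[c(2, 1)], scaler)
  i1 <- ext1$protein_id == corpus[[1]]$id
  i2 <- ext2$protein_id == corpus[[1]]$id
  expect_equal(ext1$features[i1, ], ext2$features[i2, ])
})

test_that("window size is configurable and only group 1 widens", {
  corpus <- tiny_corpus()
  scaler <- fit_pssm_scaler(lapply(corpus, `[[`, "pssm"))
  p <- corpus[[1]]
  fm9 <- assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss,
                           p$diso, window = 9)
  expect_equal(ncol(fm9), 9 * 20 + 42)
  expect_error(
    assemble_features(p$sequence, scale_pssm(p$pssm, scaler), p$ss, p$diso,
                      window = 8),
    "odd")
})
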
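test_that("segment lookup returns the maximal run containing the residue", {
  whole <- disorder_profile(rep(0.9, 10))
  s <- segment_of(whole, 5)
  expect_equal(s$kind, "disordered")
  expect_equal(s$length, 10)
  expect_equal(s$start_rel, 0.1)
  expect_equal(s$stop_rel, 1.0)

  mixed <- disorder_profile(c(0.9, 0.9, 0.9, 0.2, 0.2))
  d <- segment_of(mixed, 1)
  expect_equal(d$kind, "disordered")
  expect_equal(d$length, 3)
  o <- segment_of(mixed, 4)
  expect_equal(o$kind, "ordered")
  expect_equal(o$length, 2)
})

test_that("segments partition the protein into alternating maximal runs", {
  set.seed(12)
  for (rep in 1:20) {
    L <- sample(5:120, 1)
    diso <- disorder_profile(runif(L))
    segs <- lapply(seq_len(L), function(i) segment_of(diso, i))
    kinds <- vapply(segs, `[[`, "", "kind")
    starts <- vapply(segs, `[[`, 0, "start")
    # unique segments in order of appearance
    uniq <- !duplicated(starts)
    expect_equal(sum(vapply(segs[uniq], `[[`, 0, "length")), L)
    ks <- kinds[uniq]
    if (length(ks) > 1)
      expect_true(all(ks[-1] != ks[-length(ks)]))  # alternating kinds
    # every residue inside its segment's bounds
    for (i in seq_len(L))
      expect_true(segs[[i]]$start <= i && i <= segs[[i]]$stop)
  }
})

test_that("the seven disorder-segment features keep one triplet at zero", {
  ex <- disorder_profile(c(0.9, 0.9, 0.9, 0.2, 0.2))
  v <- disorder_segment_features(ex, 1, window = 15)
  expect_equal(unname(v[1]), 0.62)         # truncated-window mean of all 5
  expect_equal(unname(v[2:4]), c(3, 0.2, 0.6))
  expect_equal(unname(v[5:7]), c(0, 0, 0))

  v4 <- disorder_segment_features(ex, 4, window = 15)
  expect_equal(unname(v4[2:4]), c(0, 0, 0))
  expect_equal(unname(v4[5:7]), c(2, 4 / 5, 1))

  const <- disorder_profile(rep(0.9, 30))
  block <- t(vapply(1:30, function(i)
    disorder_segment_features(const, i), numeric(7)))
  expect_equal(unname(block[, 1]), rep(0.9, 30))

  set.seed(13)
  rnd <- disorder_profile(runif(50))
  for (i in c(1, 17, 50)) {
    v <- disorder_segment_features(rnd, i)
    expect_true(all(v[2:4] == 0) || all(v[5:7] == 0))
  }
})

test_that("distance mode reports boundary distances instead of positions", {
  ex <- disorder_profile(c(0.9, 0.9, 0.9, 0.2, 0.2))
  v <- disorder_segment_features(ex, 2, position_mode = "distance")
  # segment 1..3, L = 5: distance to start = 2/5, to stop = 2/5
  expect_equal(unname(v[3:4]), c(2 / 5, 2 / 5))
})

test_that("topography classification matches hand-worked cases", {
  expect_equal(topography_class(disorder_profile(rep(0.4, 9))),
               rep(0L, 9))
  expect_equal(topography_class(disorder_profile(c(0.2, 0.2, 0.8, 0.2, 0.2))),
               c(0L, 0L, 1L, 0L, 0L))
  mono <- disorder_profile(seq(0.1, 0.9, by = 0.1))
  expect_equal(topography_class(mono), rep(0L, 9))
})

test_that("topography agrees with the brute-force oracle on random tracks", {
  set.seed(14)
  for (rep in 1:60) {
    L <- sample(5:200, 1)
    s <- runif(L)
    diso <- disorder_profile(s)
    expect_identical(topography_class(diso), topography_oracle(s))
  }
})

test_that("relative topography is invariant to positive rescaling", {
  set.seed(15)
  s <- runif(80)
  base <- topography_class(disorder_profile(s))
  for (fac in c(0.25, 0.5)) {
    expect_identical(topography_class(disorder_profile(s * fac)), base)
  }
})

test_that("absolute-offset mode uses a fixed score difference", {
  s <- c(0.50, 0.50, 0.58, 0.50, 0.50)
  # relative: needs <= 0.9 * 0.58 = 0.522 on both sides -> peak
  expect_equal(topography_class(disorder_profile(s))[3], 1L)
  # absolute: needs <= 0.48 on both sides -> neither
  expect_equal(topography_class(disorder_profile(s), delta_mode = "absolute")[3], 0L)
})

test_that("topographic length is the same-class run length, zero for neither", {
  expect_equal(unname(topography_features(disorder_profile(rep(0.4, 7)), 3)),
               c(0, 0))
  peak1 <- disorder_profile(c(0.2, 0.2, 0.8, 0.2, 0.2))
  expect_equal(unname(topography_features(peak1, 3)), c(1, 1))
  plateau <- disorder_profile(c(0.2, 0.8, 0.8, 0.8, 0.2))
  tf <- topography_features(plateau)
  expect_equal(unname(tf[3, ]), c(1, 3))

  # oracle cross-check of run lengths on random tracks
  set.seed(16)
  for (rep in 1:10) {
    s <- runif(sample(10:150, 1))
    klass <- topography_oracle(s)
    r <- rle(klass)
    want <- rep(r$lengths, r$lengths)
    want[klass == 0] <- 0
    expect_equal(unname(topography_features(disorder_profile(s))[, 2]), want)
  }
})
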
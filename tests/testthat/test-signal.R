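# densification, normalization modes and the two smoothers

test_that("crosslink counts land at their region offsets, zero elsewhere", {
  # sites at the 3rd and 5th nucleotide of the six-base window
  sites <- GRanges("chr1", IRanges(c(103, 105), width = 1), strand = "+",
                   score = c(3, 5))
  trk <- new("CrosslinkTrack", name = "t", sites = sites, librarySize = 8)
  reg <- testRegion("chr1", 101, 106, "+")
  expect_equal(profileValues(extractRegionSignal(trk, reg)),
               c(0, 0, 3, 0, 5, 0))
  # opposite strand: nothing survives the strand filter
  expect_warning(
    p <- extractRegionSignal(trk, testRegion("chr1", 101, 106, "-")),
    "no --strand signal")
  expect_true(all(profileValues(p) == 0))
})

test_that("densification agrees with a naive per-position lookup", {
  set.seed(21)
  for (i in 1:10) {
    trk <- randomTrack(n = 50, span = 300)
    reg <- testRegion("chr1", 20, 280, "+")
    got <- profileValues(extractRegionSignal(trk, reg))
    s <- crosslinkSites(trk)
    naive <- vapply(20:280, function(pos) {
      sum(score(s)[start(s) == pos & as.character(strand(s)) == "+"])
    }, numeric(1))
    expect_identical(got, naive)
  }
})

test_that("library-size normalization is count / total * 1e6", {
  p <- mkProfile(c(0, 5, 0))
  n <- normalizeLibsize(p, 1e6)
  expect_equal(profileValues(n), c(0, 5, 0))
  expect_equal(unitsLabel(n), "Crosslinks per million")

  # a library of exactly one crosslink event scores 1,000,000
  one <- writeTempLines("chr5\t99\t100\t1")
  trk <- readCrosslinks(one)
  prof <- processTrack(trk, testRegion("chr5", 90, 110, "+"),
                       normalization = "libsize", smoothing = "none")
  expect_equal(max(profileValues(prof)), 1e6)
  expect_equal(profileValues(prof)[100 - 90 + 1], 1e6)

  expect_equal(profileValues(normalizeLibsize(mkProfile(c(0, 0)), 10)),
               c(0, 0))
  expect_error(normalizeLibsize(p, 0), "must be positive")
})

test_that("CPM sums to 1e6 over the whole library", {
  set.seed(3)
  trk <- randomTrack(n = 60, span = 400, strand = "+")
  reg <- testRegion("chr1", 1, 400, "+")  # covers every site
  prof <- normalizeLibsize(extractRegionSignal(trk, reg), librarySize(trk))
  expect_equal(sum(profileValues(prof)), 1e6)
})

test_that("maxpeak scales a group by its pooled maximum", {
  out <- normalizeMaxpeak(list(mkProfile(c(2, 4, 8))))[[1]]
  expect_equal(profileValues(out), c(0.25, 0.5, 1))
  expect_equal(unitsLabel(out), "Fraction of maximum")

  # two grouped tracks share the group-wide maximum
  two <- normalizeMaxpeak(list(mkProfile(c(0, 8, 2)), mkProfile(c(4, 1, 0))))
  expect_equal(max(profileValues(two[[1]])), 1)
  expect_equal(max(profileValues(two[[2]])), 0.5)

  expect_warning(z <- normalizeMaxpeak(list(mkProfile(c(0, 0)))),
                 "no signal")
  expect_equal(profileValues(z[[1]]), c(0, 0))
})

test_that("maxpeak output is in [0,1] with maximum exactly 1 (random groups)", {
  set.seed(5)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    grp <- lapply(seq_len(k), function(j)
      mkProfile(stats::rpois(50, 1) * stats::runif(50, 0, 10)))
    if (all(vapply(grp, function(p) all(profileValues(p) == 0), logical(1))))
      next
    out <- normalizeMaxpeak(grp)
    vals <- unlist(lapply(out, profileValues))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_identical(max(vals), 1)
  }
})

test_that("custom normalization divides by the size factor", {
  expect_equal(profileValues(normalizeCustom(mkProfile(c(2, 4)), 2)), c(1, 2))
  p <- mkProfile(c(1, 3))
  expect_equal(profileValues(normalizeCustom(p, 1)), c(1, 3))
  expect_error(normalizeCustom(p, 0), "positive")
  expect_error(normalizeCustom(p), "positive")
})

test_that("rolling mean matches the brute-force centered mean", {
  expect_equal(smoothRollmean(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    w <- sample(seq(1, 99, by = 2), 1)
    x <- stats::runif(n, 0, 50)
    expect_equal(smoothRollmean(x, min(w, n - (n + 1) %% 2)),
                 bruteRollmean(x, min(w, n - (n + 1) %% 2)),
                 tolerance = 1e-9)
  }
  # identity and constancy
  x <- stats::runif(20)
  expect_identical(smoothRollmean(x, 1), x)
  expect_equal(smoothRollmean(rep(2.5, 30), 7), rep(2.5, 30))
})

test_that("window hygiene: even windows widen, oversized windows clamp", {
  x <- stats::runif(21)
  expect_message(a <- smoothRollmean(x, 4), "adjusted to 5")
  expect_equal(a, bruteRollmean(x, 5))
  expect_warning(b <- smoothRollmean(x, 100), "clamping")
  expect_equal(b, bruteRollmean(x, 21))
  expect_error(smoothRollmean(x, 0), "positive")
})

test_that("gaussian smoother matches a double-loop Nadaraya-Watson oracle", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(60:500, 1)
    w <- sample(seq(3, 51, by = 2), 1)
    x <- stats::rpois(n, 2) * stats::runif(n, 0, 5)
    expect_equal(smoothGaussian(x, w), bruteGaussian(x, w),
                 tolerance = 1e-9)
  }
  # kernel weights sum to one: constants are fixed points
  expect_equal(smoothGaussian(rep(3.2, 40), 11), rep(3.2, 40))
  # impulse response is symmetric and peaks at the impulse
  imp <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smoothGaussian(imp, 9)
  expect_equal(which.max(sm), 11L)
  expect_equal(sm, rev(sm))
})

test_that("both smoothers commute with scalar multiplication", {
  set.seed(51)
  x <- stats::runif(80, 0, 9)
  for (f in list(smoothRollmean, smoothGaussian)) {
    expect_equal(f(7 * x, 9), 7 * f(x, 9), tolerance = 1e-12)
  }
})

test_that("rolling mean preserves the mean exactly on circularly padded input", {
  set.seed(61)
  x <- stats::runif(50)
  w <- 9; h <- (w - 1) / 2
  xc <- c(utils::tail(x, h), x, utils::head(x, h))
  core <- smoothRollmean(xc, w)[(h + 1):(h + length(x))]
  expect_equal(mean(core), mean(x), tolerance = 1e-12)
})

test_that("pipeline order is densify, normalize, then smooth", {
  set.seed(71)
  trk1 <- randomTrack(n = 40, span = 200, name = "a", strand = "+")
  trk2 <- randomTrack(n = 40, span = 200, name = "b", strand = "+")
  reg <- testRegion("chr1", 1, 200, "+")

  # libsize_maxpeak with no smoothing: group maxima are exactly 1,
  # and the result equals maxpeak applied to the CPM profiles
  out <- processTracks(list(trk1, trk2), reg,
                       normalization = "libsize_maxpeak",
                       smoothing = "none",
                       groups = c(a = "G", b = "G"))
  expect_equal(max(unlist(lapply(out, profileValues))), 1)
  cpm <- lapply(list(trk1, trk2), function(t)
    normalizeLibsize(extractRegionSignal(t, reg), librarySize(t)))
  expect_equal(lapply(normalizeMaxpeak(cpm), profileValues),
               lapply(out, profileValues))

  # with smoothing, normalization is applied before the smoother:
  # maxpeak-then-smooth differs from smooth-then-maxpeak, and the pipeline
  # implements the former
  smoothed <- processTracks(list(trk1), reg, normalization = "maxpeak",
                            smoothing = "rollmean", smoothingWindow = 11)
  raw <- profileValues(extractRegionSignal(trk1, reg))
  normFirst <- smoothRollmean(raw / max(raw), 11)
  smoothFirst <- local({s <- smoothRollmean(raw, 11); s / max(s)})
  expect_equal(profileValues(smoothed[[1]]), normFirst)
  expect_false(isTRUE(all.equal(normFirst, smoothFirst)))

  # libsize is linear, so it commutes with smoothing even though the
  # implementation normalizes first
  viaPipeline <- processTracks(list(trk1), reg, normalization = "libsize",
                               smoothing = "rollmean", smoothingWindow = 11)
  expect_equal(profileValues(viaPipeline[[1]]),
               smoothRollmean(raw, 11) / librarySize(trk1) * 1e6)

  # none + none is the identity pipeline
  ident <- processTrack(trk1, reg, normalization = "none",
                        smoothing = "none")
  expect_identical(profileValues(ident), raw)
})

test_that("an unstranded region yields overlaid profiles for both strands", {
  sites <- GRanges("chr1", IRanges(c(10, 20), width = 1),
                   strand = c("+", "-"), score = c(4, 6))
  trk <- new("CrosslinkTrack", name = "t", sites = sites, librarySize = 10)
  reg <- testRegion("chr1", 1, 30, "*")
  expect_message(
    out <- processTracks(list(trk), reg, normalization = "none",
                         smoothing = "none"),
    "both strands")
  expect_equal(vapply(out, profileStrand, character(1)), c("+", "-"))
  expect_equal(profileValues(out[[1]])[10], 4)
  expect_equal(profileValues(out[[2]])[20], 6)
})

test_that("custom mode requires one size factor per track", {
  trk <- randomTrack(name = "a")
  reg <- testRegion("chr1", 1, 100, "+")
  expect_error(processTracks(list(trk), reg, normalization = "custom",
                             smoothing = "none"),
               "one size factor per")
})
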
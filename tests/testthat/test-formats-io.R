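# parsing of BedGraph/BED crosslink tracks, auxiliary BED, bigWig coverage
# and the GTF annotation index

test_that("signed BedGraph encodes strand in the score sign", {
  f <- writeTempLines(c("chr1\t100\t101\t-3", "chr1\t105\t106\t2",
                        "chr1\t200\t201\t5"))
  trk <- readCrosslinks(f)
  s <- crosslinkSites(trk)
  expect_equal(length(s), 3L)
  # 0-based [100,101) is base 101 in 1-based coordinates
  expect_equal(start(s), c(101L, 106L, 201L))
  expect_equal(as.character(strand(s)), c("-", "+", "+"))
  expect_equal(score(s), c(3, 2, 5))
  expect_equal(librarySize(trk), 10)  # sum of magnitudes over the file
})

test_that("BED6 records map columns 5/6 to count and strand", {
  f <- writeTempLines("chr1\t100\t101\t.\t7\t+", ext = ".bed")
  s <- crosslinkSites(readCrosslinks(f))
  expect_equal(start(s), 101L)
  expect_equal(as.character(strand(s)), "+")
  expect_equal(score(s), 7)
})

test_that("BED without a strand column is taken as plus strand, with a warning", {
  f <- writeTempLines("chr1\t100\t101\tx\t4", ext = ".bed")
  expect_warning(trk <- readCrosslinks(f), "treating them as \\+ strand")
  expect_equal(as.character(strand(crosslinkSites(trk))), "+")
})

test_that("multi-nucleotide records expand to per-position sites with the full score", {
  f <- writeTempLines("chr1\t100\t105\t-2")
  s <- crosslinkSites(readCrosslinks(f))
  expect_equal(length(s), 5L)
  expect_equal(start(s), 101:105)
  expect_true(all(width(s) == 1L))
  expect_true(all(score(s) == 2))
  expect_true(all(strand(s) == "-"))
})

test_that("duplicate positions are summed with a warning; zero scores are kept", {
  f <- writeTempLines(c("chr1\t10\t11\t3", "chr1\t10\t11\t2",
                        "chr1\t20\t21\t0"))
  expect_warning(trk <- readCrosslinks(f), "summed")
  s <- crosslinkSites(trk)
  expect_equal(score(s), c(5, 0))
  expect_equal(librarySize(trk), 5)
})

test_that("malformed BedGraph lines are reported with their line number", {
  f <- writeTempLines(c("chr1\t10\t11\t3", "chr1\toops\t12\t1"))
  expect_error(readCrosslinks(f), "line 2")
  f2 <- writeTempLines(c("chr1\t30\t20\t1"))
  expect_error(readCrosslinks(f2), "line 1")
  expect_error(readCrosslinks(tempfile()), "not found")
})

test_that("signed BedGraph round-trips losslessly and library size is order-invariant", {
  set.seed(11)
  for (i in 1:5) {
    trk <- randomTrack(n = 40, name = "rt")
    f <- tempfile(fileext = ".bedgraph")
    writeCrosslinks(trk, f)
    back <- readCrosslinks(f, name = "rt")
    expect_identical(as.character(seqnames(crosslinkSites(back))),
                     as.character(seqnames(crosslinkSites(trk))))
    expect_equal(start(crosslinkSites(back)), start(crosslinkSites(trk)))
    expect_identical(as.character(strand(crosslinkSites(back))),
                     as.character(strand(crosslinkSites(trk))))
    expect_equal(score(crosslinkSites(back)), score(crosslinkSites(trk)))
    expect_equal(librarySize(back), librarySize(trk))
    # permuting the records must not change the library size
    ln <- readLines(f)
    f2 <- writeTempLines(sample(ln))
    expect_equal(librarySize(readCrosslinks(f2)), librarySize(trk))
  }
})

test_that("interval extents survive the BED half-open convention", {
  # a BED record covering k bases yields k single-nucleotide sites
  for (k in c(1L, 3L, 10L)) {
    f <- writeTempLines(sprintf("chr2\t50\t%d\t1", 50L + k))
    expect_equal(length(crosslinkSites(readCrosslinks(f))), k)
  }
})

test_that("auxiliary BED9 carries itemRgb; BED6 gets no color; empty file is empty", {
  b9 <- writeTempLines(
    "chr1\t100\t200\tpeak1\t0\t+\t100\t200\t255,0,0", ext = ".bed")
  ft <- readAuxiliary(b9)
  expect_equal(ft$name, "peak1")
  expect_equal(toupper(ft$color), "#FF0000")

  b6 <- writeTempLines("chr1\t100\t200\tpeak2\t0\t-", ext = ".bed")
  expect_true(is.na(readAuxiliary(b6)$color))

  empty <- writeTempLines(character(), ext = ".bed")
  expect_length(readAuxiliary(empty), 0L)
})

test_that("bigWig coverage densifies with zero fill and round-trips", {
  bw <- tempfile(fileext = ".bw")
  gr <- GRanges("chr1", IRanges(101, 105), score = 2.5)
  seqlengths(gr) <- c(chr1 = 1000)
  rtracklayer::export(gr, bw, format = "bigWig")
  # 0-based region [98,107) = 1-based 99..107
  prof <- readCoverage(bw, testRegion("chr1", 99, 107), name = "cov")
  expect_equal(profileValues(prof), c(0, 0, 2.5, 2.5, 2.5, 2.5, 2.5, 0, 0))
  expect_equal(unitsLabel(prof), "Signal")

  # chromosome missing from the file: all zeros plus a loud warning
  expect_warning(p2 <- readCoverage(bw, testRegion("1", 99, 107)),
                 "chromosome")
  expect_true(all(profileValues(p2) == 0))

  expect_error(readCoverage(writeTempLines("not a bigwig", ext = ".bw"),
                            testRegion()), "not a valid bigWig")
})

test_that("GTF loads into an index with the expected feature counts", {
  db <- loadToyAnnotation()
  expect_s4_class(db, "AnnotationIndex")
  expect_length(annotationGenes(db), 2L)
  expect_length(annotationTranscripts(db), 3L)
  expect_length(annotationExons(db), 6L)
})

test_that("the annotation cache is reused, and rebuilt when the GTF is newer", {
  dir <- tempfile(); dir.create(dir)
  gtf <- writeToyGtf(file.path(dir, "toy.gtf"))
  expect_message(db1 <- loadAnnotation(gtf), "cache written")
  expect_message(db2 <- loadAnnotation(gtf), "cache hit")
  expect_identical(annotationExons(db1), annotationExons(db2))
  # make the GTF newer than the cache
  Sys.setFileTime(gtf, Sys.time() + 5)
  expect_message(db3 <- loadAnnotation(gtf), "rebuilding")
  expect_identical(annotationGenes(db1), annotationGenes(db3))
})

test_that("a GTF exon without transcript_id is a fatal, located error", {
  bad <- writeTempLines(c(
    'chr1\ttoy\tgene\t1\t50\t.\t+\t.\tgene_id "G"; gene_name "g";',
    'chr1\ttoy\texon\t1\t50\t.\t+\t.\tgene_id "G"; gene_name "g";'),
    ext = ".gtf")
  expect_error(suppressMessages(loadAnnotation(bad, cache = FALSE)),
               "lacks gene_id/transcript_id")
})

test_that("coordinate queries are 1-based inclusive and validated", {
  db <- loadToyAnnotation()
  r <- resolveRegion(db, "chr1:207513000-207515000")
  expect_equal(as.character(seqnames(r)), "chr1")
  expect_equal(start(r), 207513000)
  expect_equal(end(r), 207515000)
  expect_equal(width(r), 2001L)
  expect_equal(as.character(strand(r)), "*")
  expect_equal(mcols(r)$label, "chr1:207513000-207515000")

  rs <- resolveRegion(db, "chr2:100:200:-")
  expect_equal(as.character(strand(rs)), "-")

  expect_error(resolveRegion(db, "chr1:500-100"), "start must not exceed")
})

test_that("gene queries return the full exon span, matching a naive GTF scan", {
  gtf <- writeToyGtf()
  db <- suppressMessages(loadAnnotation(gtf, cache = FALSE))
  for (q in c("alpha", "G2")) {
    r <- resolveRegion(db, q)
    # independent oracle: line-scan of the GTF text
    ln <- readLines(gtf)
    ln <- ln[grepl("\texon\t", ln) &
               grepl(sprintf('gene_%s "%s"', ifelse(q == "G2", "id", "name"),
                             q), ln, fixed = TRUE)]
    f <- strsplit(ln, "\t")
    expect_equal(start(r), min(vapply(f, function(x) as.integer(x[4]),
                                      integer(1))))
    expect_equal(end(r), max(vapply(f, function(x) as.integer(x[5]),
                                    integer(1))))
    # the span contains every exon of every transcript of the gene
    ex <- annotationExons(db)
    ex <- ex[mcols(ex)$gene_id == mcols(annotationGenes(db))$gene_id[
      match(TRUE, mcols(annotationGenes(db))$gene_name == q |
              mcols(annotationGenes(db))$gene_id == q)]]
    expect_true(all(start(ex) >= start(r) & end(ex) <= end(r)))
  }
  expect_equal(as.character(strand(resolveRegion(db, "beta"))), "-")
  expect_equal(mcols(resolveRegion(db, "G1"))$label, "alpha")
  expect_error(resolveRegion(db, "NOPE1"), "not found")
})

test_that("an ambiguous gene name is fatal and lists the candidates", {
  amb <- writeTempLines(c(
    'chr1\ttoy\tgene\t1\t50\t.\t+\t.\tgene_id "GA"; gene_name "dup";',
    'chr1\ttoy\texon\t1\t50\t.\t+\t.\tgene_id "GA"; gene_name "dup"; transcript_id "GA.t";',
    'chr1\ttoy\tgene\t100\t150\t.\t+\t.\tgene_id "GB"; gene_name "dup";',
    'chr1\ttoy\texon\t100\t150\t.\t+\t.\tgene_id "GB"; gene_name "dup"; transcript_id "GB.t";'),
    ext = ".gtf")
  db <- suppressMessages(loadAnnotation(amb, cache = FALSE))
  expect_error(resolveRegion(db, "dup"), "ambiguous.*GA.*GB")
})
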
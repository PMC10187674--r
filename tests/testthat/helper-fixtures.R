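suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

score <- BiocGenerics::score
`score<-` <- BiocGenerics::`score<-`

# one shared synthetic dataset per test session
fixtureDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "xlinkplot-fixture")
      suppressMessages(makeFixture(dir, seed = 7))
    }
    dir
  }
})

writeTempLines <- function(lines, ext = ".bedgraph") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small handwritten GTF: two genes, three transcripts
writeToyGtf <- function(path = tempfile(fileext = ".gtf")) {
  at <- function(g, n, t = NULL) {
    a <- sprintf('gene_id "%s"; gene_name "%s";', g, n)
    if (!is.null(t)) a <- sprintf('%s transcript_id "%s";', a, t)
    a
  }
  writeLines(c(
    sprintf("chr9\ttoy\tgene\t100\t900\t.\t+\t.\t%s", at("G1", "alpha")),
    sprintf("chr9\ttoy\ttranscript\t100\t900\t.\t+\t.\t%s",
            at("G1", "alpha", "G1.t1")),
    sprintf("chr9\ttoy\texon\t100\t250\t.\t+\t.\t%s", at("G1", "alpha", "G1.t1")),
    sprintf("chr9\ttoy\texon\t600\t900\t.\t+\t.\t%s", at("G1", "alpha", "G1.t1")),
    sprintf("chr9\ttoy\ttranscript\t100\t700\t.\t+\t.\t%s",
            at("G1", "alpha", "G1.t2")),
    sprintf("chr9\ttoy\texon\t100\t250\t.\t+\t.\t%s", at("G1", "alpha", "G1.t2")),
    sprintf("chr9\ttoy\texon\t400\t700\t.\t+\t.\t%s", at("G1", "alpha", "G1.t2")),
    sprintf("chr9\ttoy\tgene\t2000\t2500\t.\t-\t.\t%s", at("G2", "beta")),
    sprintf("chr9\ttoy\ttranscript\t2000\t2500\t.\t-\t.\t%s",
            at("G2", "beta", "G2.t1")),
    sprintf("chr9\ttoy\texon\t2000\t2100\t.\t-\t.\t%s", at("G2", "beta", "G2.t1")),
    sprintf("chr9\ttoy\texon\t2400\t2500\t.\t-\t.\t%s", at("G2", "beta", "G2.t1"))
  ), path)
  path
}

loadToyAnnotation <- function(...) {
  suppressMessages(loadAnnotation(writeToyGtf(), cache = FALSE, ...))
}

testRegion <- function(chrom = "chr1", start = 1, end = 100, strand = "+",
                       label = "test") {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$label <- label
  gr
}

randomTrack <- function(n = 30, chrom = "chr1", span = 500, name = "rnd",
                        strand = c("+", "-")) {
  pos <- sample.int(span, n)
  st <- sample(strand, n, replace = TRUE)
  keep <- !duplicated(paste(pos, st))
  sites <- GRanges(chrom, IRanges(pos[keep], width = 1), strand = st[keep],
                   score = stats::rpois(sum(keep), 4) + 1)
  # position-major order, matching the reader's canonical ordering
  sites <- sites[order(as.character(seqnames(sites)), start(sites),
                       as.character(strand(sites)))]
  new("CrosslinkTrack", name = name, sites = sites,
      librarySize = sum(score(sites)))
}

mkProfile <- function(values, name = "p", group = name, strand = "+",
                      units = "Crosslinks", chrom = "chr1", start = 1) {
  r <- GRanges(chrom, IRanges(start, width = length(values)))
  new("SignalProfile", name = name, group = group,
      values = as.numeric(values), region = r, strand = strand,
      unitsLabel = units)
}

# independent brute-force oracles -----------------------------------------

bruteRollmean <- function(x, window) {
  h <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(x[idx])
  }, numeric(1))
}

bruteGaussian <- function(x, window) {
  h <- window %/% 2
  sd <- window / 4
  n <- length(x)
  vapply(seq_len(n), function(i) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (abs(j - i) <= h) {
        w <- stats::dnorm(j - i, 0, sd)
        num <- num + w * x[j]
        den <- den + w
      }
    }
    num / den
  }, numeric(1))
}
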
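#' Generate a synthetic toy dataset in every consumed format
#'
#' Writes a small, fully synthetic but structurally realistic dataset to
#' `outDir`, emulating a two-protein competitive-binding study: two
#' replicate crosslink tracks of an RBP ("RBP-A") sharing a binding peak,
#' two replicates of a second RBP ("RBP-B") whose peak is shifted
#' downstream, a BED9 auxiliary feature (a repeat-like element) under the
#' shared peak, RNA-seq-style bigWig coverage in three grouped conditions
#' where knockdown expresses an extra exon, and a GTF with one multi-isoform
#' gene (one isoform carrying that extra exon under the auxiliary feature)
#' plus a second single-isoform gene. Everything lives on one synthetic
#' chromosome `chrT`.
#'
#' Crosslink counts are per-position Poisson draws around a Gaussian
#' peak-shaped mean plus a uniform low background on both strands; minus
#' strand sites are written with negative BedGraph scores (the iCLIP sign
#' convention). Output is byte-deterministic for a given `seed`.
#'
#' @param outDir writable output directory (created if needed).
#' @param seed RNG seed; the same seed yields byte-identical files.
#' @param peakHeight expected crosslink count at the shared peak center.
#' @param peakSd Gaussian peak width (nt standard deviation).
#' @param sharedCenter,shiftedCenter peak centers (nt) of RBP-A and RBP-B.
#' @param backgroundRate,minusRate per-position Poisson background rates on
#'   the plus and minus strands.
#' @param chromLength length of the synthetic chromosome (nt).
#' @return invisibly, the manifest `data.frame` (columns `file`, `flag`,
#'   `group`) that is also written to `manifest.tsv`.
#' @export
makeFixture <- function(outDir, seed = 42L, peakHeight = 30, peakSd = 40,
                        sharedCenter = 3400, shiftedCenter = 3640,
                        backgroundRate = 0.03, minusRate = 0.01,
                        chromLength = 6000L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", outDir, call. = FALSE)
  probe <- file.path(outDir, ".write-probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok))
    stop("fixture directory is not writable: ", outDir, call. = FALSE)
  unlink(probe)
  set.seed(seed)

  manifest <- list()
  addFile <- function(file, flag, group) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = file, flag = flag, group = group,
                 stringsAsFactors = FALSE)
  }

  peakLambda <- function(center, height, sd) {
    lam <- numeric(chromLength)
    i <- max(1, round(center - 4 * sd)):min(chromLength,
                                            round(center + 4 * sd))
    lam[i] <- height * exp(-(i - center)^2 / (2 * sd^2))
    lam
  }

  writeXlinkTrack <- function(file, lambdaPlus) {
    plus <- stats::rpois(chromLength, lambdaPlus + backgroundRate)
    minus <- stats::rpois(chromLength, minusRate)
    ip <- which(plus > 0); im <- which(minus > 0)
    df <- rbind(data.frame(pos = ip, score = plus[ip]),
                data.frame(pos = im, score = -minus[im]))
    df <- df[order(df$pos, -df$score), ]
    writeLines(sprintf("chrT\t%d\t%d\t%d", df$pos - 1L, df$pos, df$score),
               file.path(outDir, file))
  }

  for (rep in 1:2) {
    f <- sprintf("RBP-A_rep%d.bedgraph", rep)
    writeXlinkTrack(f, peakLambda(sharedCenter, peakHeight, peakSd))
    addFile(f, "--xlinks", "RBP-A")
  }
  for (rep in 1:2) {
    f <- sprintf("RBP-B_rep%d.bedgraph", rep)
    writeXlinkTrack(f, peakLambda(shiftedCenter, 0.8 * peakHeight, peakSd))
    addFile(f, "--xlinks", "RBP-B")
  }

  # auxiliary BED9: one repeat-like element under the shared peak, colored
  aux <- sprintf("chrT\t%d\t%d\tsynRepeat\t0\t+\t%d\t%d\t214,39,40",
                 sharedCenter - 151L, sharedCenter + 150L,
                 sharedCenter - 151L, sharedCenter + 150L)
  writeLines(aux, file.path(outDir, "features.bed"))
  addFile("features.bed", "--auxiliary", "features")

  # gene models: synGeneA (+, multi-isoform; isoform 2 gains an exon under
  # the auxiliary feature), synGeneB (-, single isoform)
  exonsA1 <- cbind(c(1001L, 2601L, 4801L), c(1200L, 2800L, 5000L))
  extraExon <- c(sharedCenter - 99L, sharedCenter + 100L)
  exonsA2 <- cbind(c(1001L, extraExon[1], 4801L),
                   c(1200L, extraExon[2], 5000L))
  exonsB1 <- cbind(c(5200L, 5700L), c(5400L, 5900L))
  gtf <- c(
    .gtfGene("synG000001", "synGeneA", 1001L, 5000L, "+"),
    .gtfTranscript("synG000001", "synGeneA", "synT000101", exonsA1, "+"),
    .gtfTranscript("synG000001", "synGeneA", "synT000102", exonsA2, "+"),
    .gtfGene("synG000002", "synGeneB", 5200L, 5900L, "-"),
    .gtfTranscript("synG000002", "synGeneB", "synT000201", exonsB1, "-"))
  writeLines(gtf, file.path(outDir, "annotation.gtf"))
  addFile("annotation.gtf", "--gtf", "annotation")

  # coverage bigWigs: exonic RNA-seq-like blocks; knockdown conditions
  # express the extra exon (an expression step under the auxiliary feature)
  covGroups <- c(CTRL = 2, KD1 = 40, KD2 = 34)
  for (g in names(covGroups)) {
    for (rep in 1:2) {
      blocks <- rbind(exonsA1, c(extraExon[1], extraExon[2]))
      base <- c(50, 55, 48, covGroups[[g]])
      vals <- round(base * stats::runif(length(base), 0.9, 1.1), 2)
      gr <- GRanges("chrT", IRanges(blocks[, 1], blocks[, 2]),
                    score = vals)
      gr <- sort(gr)
      seqlengths(gr) <- c(chrT = chromLength)
      f <- sprintf("coverage_%s_rep%d.bw", g, rep)
      rtracklayer::export(gr, file.path(outDir, f), format = "bigWig")
      addFile(f, "--coverage", g)
    }
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

.gtfAttrs <- function(gene_id, gene_name, transcript_id = NULL) {
  a <- sprintf('gene_id "%s"; gene_name "%s";', gene_id, gene_name)
  if (!is.null(transcript_id))
    a <- sprintf('%s transcript_id "%s";', a, transcript_id)
  a
}

.gtfGene <- function(gene_id, gene_name, start, end, strand) {
  sprintf("chrT\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s", start, end, strand,
          .gtfAttrs(gene_id, gene_name))
}

.gtfTranscript <- function(gene_id, gene_name, transcript_id, exons,
                           strand) {
  c(sprintf("chrT\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            min(exons[, 1]), max(exons[, 2]), strand,
            .gtfAttrs(gene_id, gene_name, transcript_id)),
    sprintf("chrT\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
            exons[, 1], exons[, 2], strand,
            .gtfAttrs(gene_id, gene_name, transcript_id)))
}

#' The end-to-end example command for a generated fixture
#'
#' Returns the argument vector of the full four-panel run on a
#' [makeFixture()] dataset (four crosslink tracks in two groups, the BED9
#' auxiliary feature, three coverage groups, multi-isoform annotation,
#' highlight box over the shared peak, CPM normalization with a 50 nt
#' rolling mean), ready to pass to [runCLI()] or [parseArgs()].
#'
#' @param dir the fixture directory.
#' @param output output figure path (default `figure.png` inside `dir`).
#' @return character vector of command-line arguments.
#' @export
fixtureCommand <- function(dir, output = file.path(dir, "figure.png")) {
  p <- function(...) file.path(dir, ...)
  c("--xlinks", paste(p(c("RBP-A_rep1.bedgraph", "RBP-A_rep2.bedgraph",
                          "RBP-B_rep1.bedgraph", "RBP-B_rep2.bedgraph")),
                      collapse = ","),
    "--gtf", p("annotation.gtf"),
    "--region", "synGeneA",
    "--output", output,
    "--normalization", "libsize",
    "--smoothing", "rollmean",
    "--smoothing_window", "50",
    "--groups", "RBP-A,RBP-A,RBP-B,RBP-B",
    "--auxiliary", p("features.bed"),
    "--coverage", paste(p(sprintf("coverage_%s_rep%d.bw",
                                  rep(c("CTRL", "KD1", "KD2"), each = 2),
                                  rep(1:2, 3))), collapse = ","),
    "--coverage_groups", "CTRL,CTRL,KD1,KD1,KD2,KD2",
    "--highlight", "3300:3500")
}
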
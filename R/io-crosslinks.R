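#' Read a crosslink track from BED or signed BedGraph
#'
#' Parses one CLIP experiment's nucleotide-resolution crosslink positions.
#' Two encodings are supported:
#'
#' * **BedGraph** (4 columns): each record is a position and the score is the
#'   number of crosslinks there. Strand is encoded in the sign of the score
#'   (iCLIP convention): positive = plus strand, negative = minus strand.
#'   The magnitude becomes the count.
#' * **BED** (>= 5 columns): column 5 is the crosslink count; column 6, when
#'   present, is the strand. A BED file without a strand column is treated
#'   as plus strand with a warning.
#'
#' Records spanning more than one nucleotide are expanded to one site per
#' covered position, each carrying the full per-position score (BedGraph
#' semantics: the value applies to every base of the interval). Records with
#' score 0 are kept. If the same position/strand occurs in several records
#' the counts are summed with a warning. The library size is the sum of
#' counts over the *whole file* (all chromosomes, both strands), which is
#' what crosslinks-per-million normalization later divides by.
#'
#' @param path path to the BED/BedGraph file.
#' @param name experiment label; defaults to the file basename without
#'   extension.
#' @param format `"auto"` (from the extension, falling back to column
#'   sniffing), `"bedgraph"` or `"bed"`.
#' @return a [CrosslinkTrack].
#' @examples
#' f <- tempfile(fileext = ".bedgraph")
#' writeLines(c("chr1\t100\t101\t-3", "chr1\t105\t106\t7"), f)
#' trk <- readCrosslinks(f)
#' librarySize(trk)  # 10
#' @export
readCrosslinks <- function(path, name = trackNameFromPath(path),
                           format = c("auto", "bedgraph", "bed")) {
  .assertFileExists(path, "crosslink file")
  format <- match.arg(format)
  if (format == "auto") format <- .sniffXlinkFormat(path)

  gr <- if (format == "bedgraph") {
    .validateBedgraphLines(path)
    tryCatch(rtracklayer::import(path, format = "bedGraph"),
             error = function(e) stop(sprintf(
               "failed to parse BedGraph '%s': %s", path,
               conditionMessage(e)), call. = FALSE))
  } else {
    tryCatch(rtracklayer::import(path, format = "BED"),
             error = function(e) stop(sprintf(
               "failed to parse BED '%s': %s", path, conditionMessage(e)),
               call. = FALSE))
  }

  if (length(gr) == 0L) {
    sites <- GRanges(score = numeric())
    return(new("CrosslinkTrack", name = name, sites = sites,
               librarySize = 0))
  }

  score <- mcols(gr)$score
  if (is.null(score) || all(is.na(score)))
    stop(sprintf("'%s' has no score column; crosslink files need per-%s",
                 path, "position counts"), call. = FALSE)
  if (anyNA(score))
    stop(sprintf("'%s' has missing scores", path), call. = FALSE)

  strnd <- if (format == "bedgraph") {
    ifelse(score < 0, "-", "+")
  } else {
    s <- as.character(strand(gr))
    if (any(s == "*")) {
      warning(sprintf(
        "'%s' has records without strand; treating them as + strand", path),
        call. = FALSE)
      s[s == "*"] <- "+"
    }
    s
  }
  count <- abs(score)

  # expand multi-nucleotide records: the value applies to every covered base
  wid <- width(gr)
  if (any(wid > 1L)) {
    pos <- unlist(lapply(which(wid > 1L), function(i) start(gr)[i]:end(gr)[i]))
    i1 <- which(wid == 1L)
    chrom <- c(as.character(seqnames(gr))[i1],
               rep(as.character(seqnames(gr))[wid > 1L], wid[wid > 1L]))
    pos <- c(start(gr)[i1], pos)
    count <- c(count[i1], rep(count[wid > 1L], wid[wid > 1L]))
    strnd <- c(strnd[i1], rep(strnd[wid > 1L], wid[wid > 1L]))
  } else {
    chrom <- as.character(seqnames(gr))
    pos <- start(gr)
  }

  # collapse duplicate position/strand records, summing their counts
  key <- paste(chrom, pos, strnd)
  if (anyDuplicated(key)) {
    warning(sprintf(
      "'%s' lists the same position more than once; counts were summed",
      path), call. = FALSE)
    agg <- rowsum(count, key, reorder = FALSE)
    keep <- !duplicated(key)
    chrom <- chrom[keep]; pos <- pos[keep]; strnd <- strnd[keep]
    count <- as.numeric(agg[match(key[keep], rownames(agg)), 1L])
  }

  o <- order(chrom, pos, strnd)
  sites <- GRanges(chrom[o], IRanges(pos[o], width = 1L), strand = strnd[o],
                   score = count[o])
  new("CrosslinkTrack", name = name, sites = sites, librarySize = sum(count))
}

.sniffXlinkFormat <- function(path) {
  ext <- tolower(file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("bedgraph", "bg")) return("bedgraph")
  if (ext == "bed") return("bed")
  ln <- .dataLines(path, n = 1L)
  if (!length(ln))
    return("bedgraph")
  nf <- length(strsplit(ln[1], "[\t ]+")[[1]])
  if (nf <= 4L) "bedgraph" else "bed"
}

.dataLines <- function(path, n = -1L) {
  ln <- readLines(path, n = if (n > 0) n + 50L else -1L, warn = FALSE)
  ln <- ln[nzchar(ln) & !grepl("^(track|browser|#)", ln)]
  if (n > 0) utils::head(ln, n) else ln
}

# line-numbered validation so malformed files are reported usably
.validateBedgraphLines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  for (i in seq_along(ln)) {
    l <- ln[i]
    if (!nzchar(l) || grepl("^(track|browser|#)", l)) next
    f <- strsplit(l, "[\t ]+")[[1]]
    bad <- length(f) != 4L ||
      anyNA(suppressWarnings(as.numeric(f[2:4]))) ||
      suppressWarnings(as.numeric(f[2])) > suppressWarnings(as.numeric(f[3]))
    if (bad)
      stop(sprintf("malformed BedGraph line %d in '%s': %s", i, path, l),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a crosslink track as a signed BedGraph
#'
#' Inverse of [readCrosslinks()] for BedGraph input: each width-1 site is
#' written as a 4-column record whose score magnitude is the count and whose
#' sign encodes the strand (positive = plus strand). Re-reading the file
#' reproduces the track exactly.
#'
#' @param track a [CrosslinkTrack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCrosslinks <- function(track, path) {
  s <- crosslinkSites(track)
  sgn <- ifelse(as.character(strand(s)) == "-", -1, 1)
  lines <- sprintf("%s\t%d\t%d\t%.15g", as.character(seqnames(s)),
                   start(s) - 1L, end(s), sgn * mcols(s)$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read an auxiliary interval track (BED6/BED9)
#'
#' Auxiliary tracks hold contextual intervals — called peaks, repeat
#' elements and the like — drawn between the crosslink and coverage panels.
#' If the file is BED9, the `itemRgb` color of each interval is kept and used
#' for drawing; BED6 features get the panel's default color.
#'
#' @param path path to a BED file.
#' @return a [GenomicRanges::GRanges] with `name` and `color` metadata
#'   columns (`color` is `NA` when the source had no itemRgb field). An
#'   empty file yields an empty `GRanges`; the auxiliary panel is then drawn
#'   empty.
#' @export
readAuxiliary <- function(path) {
  .assertFileExists(path, "auxiliary BED file")
  if (!length(.dataLines(path, n = 1L))) {
    return(GRanges(name = character(), color = character()))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop(sprintf(
                   "failed to parse BED '%s': %s", path, conditionMessage(e)),
                   call. = FALSE))
  nm <- mcols(gr)$name
  if (is.null(nm) || all(is.na(nm))) nm <- paste0("feature_", seq_along(gr))
  col <- mcols(gr)$itemRgb
  if (is.null(col)) col <- rep(NA_character_, length(gr))
  mcols(gr) <- S4Vectors::DataFrame(name = nm, color = as.character(col))
  gr
}

#' Read a coverage profile from a bigWig over a region
#'
#' Coverage tracks (RNA-seq, Ribo-seq, ...) are read as stored — no
#' normalization or smoothing is applied — and densified to one value per
#' nucleotide of the region, with 0 filled where the bigWig has no interval.
#' If the region's chromosome is absent from the bigWig an all-zero profile
#' is returned with a warning (chromosome naming dialects are not aliased).
#'
#' @param path path to a bigWig file.
#' @param region length-1 `GRanges`, e.g. from [resolveRegion()].
#' @param name track label; defaults to the file basename.
#' @return a [SignalProfile] with units label `"Signal"`.
#' @export
readCoverage <- function(path, region, name = trackNameFromPath(path)) {
  .assertFileExists(path, "coverage bigWig")
  bwf <- tryCatch(rtracklayer::BigWigFile(path),
                  error = function(e) NULL)
  si <- tryCatch(suppressWarnings(seqinfo(bwf)), error = function(e) NULL)
  if (is.null(si))
    stop(sprintf("'%s' is not a valid bigWig file", path), call. = FALSE)

  n <- width(region)
  vals <- numeric(n)
  chr <- as.character(seqnames(region))
  if (.checkChromDialect(GenomeInfoDb::seqnames(si), region,
                         "coverage track", name)) {
    chrLen <- seqlengths(si)[[chr]]
    qs <- max(1L, start(region))
    qe <- min(end(region), chrLen)
    if (qs <= qe) {
      q <- GRanges(chr, IRanges(qs, qe))
      v <- rtracklayer::import(bwf, which = q, as = "NumericList")[[1]]
      v[is.na(v)] <- 0
      vals[(qs - start(region) + 1L):(qe - start(region) + 1L)] <- v
    }
  }
  new("SignalProfile", name = name, group = name, values = vals,
      region = granges(region), strand = "*", unitsLabel = "Signal")
}
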
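#' @import methods
#' @importFrom GenomicRanges GRanges granges strand `strand<-` start end width
#'   seqnames findOverlaps reduce tile
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors mcols `mcols<-` queryHits subjectHits Rle runValue
#' @importFrom GenomeInfoDb seqlevels seqinfo seqlengths `seqlengths<-`
NULL

#' CrosslinkTrack: one CLIP experiment's crosslink positions
#'
#' Holds the single-nucleotide crosslink sites of one experiment, as parsed
#' from a BED or signed BedGraph file, together with the experiment label and
#' the library size (the total number of crosslink events summed over the
#' whole file, all chromosomes and both strands). The library size is what
#' crosslinks-per-million normalization divides by, so it is computed from
#' the complete file, never from a region subset.
#'
#' @slot name experiment label (scalar character).
#' @slot sites a [GenomicRanges::GRanges] of width-1 ranges with a
#'   non-negative numeric `score` metadata column (crosslink events at that
#'   nucleotide) and strand `+` or `-`.
#' @slot librarySize total crosslink events in the source file; equals
#'   `sum(score(sites))`.
#'
#' @seealso [readCrosslinks()]
#' @export
setClass("CrosslinkTrack",
  slots = c(name = "character", sites = "GRanges", librarySize = "numeric")
)

setValidity("CrosslinkTrack", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  s <- object@sites
  if (length(s)) {
    if (any(width(s) != 1L))
      msg <- c(msg, "all crosslink sites must span exactly one nucleotide")
    sc <- mcols(s)$score
    if (is.null(sc) || !is.numeric(sc))
      msg <- c(msg, "'sites' must carry a numeric 'score' column")
    else if (any(!is.finite(sc)) || any(sc < 0))
      msg <- c(msg, "crosslink counts must be finite and non-negative")
    if (!all(as.character(strand(s)) %in% c("+", "-")))
      msg <- c(msg, "crosslink sites must be stranded (+ or -)")
  }
  if (length(object@librarySize) != 1L || !is.finite(object@librarySize) ||
      object@librarySize < 0)
    msg <- c(msg, "'librarySize' must be a single non-negative number")
  else {
    tot <- if (length(s)) sum(mcols(s)$score) else 0
    if (abs(object@librarySize - tot) > 1e-6 * max(1, tot))
      msg <- c(msg, "'librarySize' must equal the sum of site counts")
  }
  if (length(msg)) msg else TRUE
})

#' SignalProfile: dense per-nucleotide signal over a region
#'
#' A dense vector of per-position values spanning a plotted region, produced
#' by densifying a [CrosslinkTrack] (and then normalizing/smoothing it) or by
#' reading a bigWig coverage track. Carries the experiment label, the display
#' group, the strand the values came from and the y-axis label implied by the
#' normalization mode.
#'
#' @slot name experiment label.
#' @slot group display group label (defaults to the experiment label).
#' @slot values numeric vector, one value per nucleotide of `region`.
#' @slot region length-1 [GenomicRanges::GRanges]; `length(values)` equals
#'   `width(region)`.
#' @slot strand `"+"`, `"-"` or `"*"`; minus-strand profiles of an
#'   unstranded region are drawn with their own linetype.
#' @slot unitsLabel y-axis text, set by the normalization mode (one of
#'   "Crosslinks", "Crosslinks per million", "Fraction of maximum",
#'   "Custom-scaled crosslinks") or "Signal" for raw coverage.
#'
#' @export
setClass("SignalProfile",
  slots = c(name = "character", group = "character", values = "numeric",
            region = "GRanges", strand = "character", unitsLabel = "character")
)

setValidity("SignalProfile", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
  if (length(object@group) != 1L) msg <- c(msg, "'group' must be length 1")
  if (length(object@region) != 1L)
    msg <- c(msg, "'region' must be a single range")
  else if (length(object@values) != width(object@region))
    msg <- c(msg, "length(values) must equal width(region)")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "profile values must be finite")
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "'strand' must be one of +, -, *")
  if (length(object@unitsLabel) != 1L || !nzchar(object@unitsLabel))
    msg <- c(msg, "'unitsLabel' must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' AnnotationIndex: an in-memory, cacheable GTF annotation index
#'
#' Gene, transcript and exon records parsed from a GTF (GENCODE/Ensembl
#' attribute dialects), queryable by gene name, gene id or interval overlap.
#' Built once per GTF and persisted next to it (or in a configured cache
#' directory) so later runs skip the parse; staleness is detected from the
#' GTF modification time.
#'
#' @slot sourcePath path of the GTF the index was built from.
#' @slot cachePath path of the on-disk cache, `NA` if caching was disabled.
#' @slot genes `GRanges` with `gene_id`, `gene_name`.
#' @slot transcripts `GRanges` with `transcript_id`, `gene_id`, `gene_name`.
#' @slot exons `GRanges` with `transcript_id`, `gene_id`, `gene_name`.
#'
#' @seealso [loadAnnotation()], [resolveRegion()], [transcriptsInRegion()]
#' @export
setClass("AnnotationIndex",
  slots = c(sourcePath = "character", cachePath = "character",
            genes = "GRanges", transcripts = "GRanges", exons = "GRanges")
)

setValidity("AnnotationIndex", function(object) {
  msg <- character()
  need <- function(gr, cols, what) {
    miss <- setdiff(cols, names(mcols(gr)))
    if (length(miss))
      sprintf("%s lack column(s): %s", what, paste(miss, collapse = ", "))
    else character()
  }
  msg <- c(msg,
    need(object@genes, c("gene_id", "gene_name"), "genes"),
    need(object@transcripts, c("transcript_id", "gene_id", "gene_name"),
         "transcripts"),
    need(object@exons, c("transcript_id", "gene_id", "gene_name"), "exons"))
  if (length(msg)) msg else TRUE
})

#' GroupStyle: track grouping and group colors
#'
#' Maps each track name to a display group and each group to a color.
#' Applied independently to crosslink tracks and coverage tracks.
#'
#' @slot trackGroup named character: track name -> group label.
#' @slot groupColor named character: group label -> color.
#'
#' @seealso [assignStyles()]
#' @export
setClass("GroupStyle",
  slots = c(trackGroup = "character", groupColor = "character")
)

setValidity("GroupStyle", function(object) {
  msg <- character()
  if (is.null(names(object@trackGroup)) || anyNA(names(object@trackGroup)))
    msg <- c(msg, "'trackGroup' must be a named character vector")
  if (is.null(names(object@groupColor)))
    msg <- c(msg, "'groupColor' must be a named character vector")
  missing <- setdiff(unique(object@trackGroup), names(object@groupColor))
  if (length(missing))
    msg <- c(msg, sprintf("groups without a color: %s",
                          paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FigureSpec: layout and output options for the composed figure
#'
#' @slot region length-1 `GRanges` (with a `label` metadata column) that all
#'   panels are clipped and aligned to.
#' @slot ratios four positive panel height ratios
#'   (crosslink, auxiliary, coverage, annotation) or `NA` for dynamic
#'   scaling; absent panels receive ratio 0 when resolved.
#' @slot size page width and height in inches.
#' @slot scaleYPerGroup give each crosslink group an independently scaled
#'   facet (the `--scale_y` behavior).
#' @slot highlight two region coordinates bounding a gray highlight box, or
#'   `NA` for none.
#' @slot output output file path; format (pdf/png) follows the extension.
#'
#' @export
setClass("FigureSpec",
  slots = c(region = "GRanges", ratios = "numeric", size = "numeric",
            scaleYPerGroup = "logical", highlight = "numeric",
            output = "character")
)

setValidity("FigureSpec", function(object) {
  msg <- character()
  if (length(object@region) != 1L)
    msg <- c(msg, "'region' must be a single range")
  if (!(length(object@ratios) == 4L || all(is.na(object@ratios))))
    msg <- c(msg, "'ratios' must be four numbers or NA")
  if (length(object@size) != 2L || any(object@size <= 0, na.rm = TRUE))
    msg <- c(msg, "'size' must be two positive numbers (width, height)")
  if (!all(is.na(object@highlight)) &&
      (length(object@highlight) != 2L || object@highlight[1] > object@highlight[2]))
    msg <- c(msg, "'highlight' must be NA or two ordered coordinates")
  if (length(msg)) msg else TRUE
})
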
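.CACHE_VERSION <- 1L

#' Load (and cache) a GTF annotation
#'
#' Parses a GENCODE/Ensembl-dialect GTF into an [AnnotationIndex] of gene,
#' transcript and exon records. The first run persists the index next to the
#' GTF (suffix `.xlinkplot-cache.rds`, or under `cacheDir`); later runs with
#' the same annotation load the cache and skip the parse. A cache older than
#' the GTF is rebuilt with a notice.
#'
#' Every exon/transcript feature must carry `gene_id` and `transcript_id`
#' attributes; `gene_name` falls back to `gene_id` where absent. Gene and
#' transcript records are derived from the exons when the GTF does not list
#' them explicitly.
#'
#' @param gtfPath path to the GTF.
#' @param cacheDir directory for the cache file; default is the GTF's own
#'   directory.
#' @param cache set `FALSE` to disable reading/writing the cache.
#' @return an [AnnotationIndex].
#' @seealso [resolveRegion()], [transcriptsInRegion()]
#' @export
loadAnnotation <- function(gtfPath, cacheDir = dirname(gtfPath),
                           cache = TRUE) {
  .assertFileExists(gtfPath, "annotation GTF")
  cachePath <- file.path(cacheDir,
                         paste0(basename(gtfPath), ".xlinkplot-cache.rds"))

  if (cache && file.exists(cachePath)) {
    st <- tryCatch(readRDS(cachePath), error = function(e) NULL)
    ok <- !is.null(st) && identical(st$version, .CACHE_VERSION) &&
      identical(st$gtf, basename(gtfPath))
    if (ok && st$mtime >= file.mtime(gtfPath)) {
      message("annotation cache hit: ", cachePath, " (GTF parse skipped)")
      return(new("AnnotationIndex", sourcePath = gtfPath,
                 cachePath = cachePath, genes = st$genes,
                 transcripts = st$transcripts, exons = st$exons))
    }
    if (ok) message("annotation cache is older than the GTF; rebuilding")
  }

  gr <- tryCatch(rtracklayer::import(gtfPath, format = "gtf"),
                 error = function(e) stop(sprintf(
                   "failed to parse GTF '%s': %s", gtfPath,
                   conditionMessage(e)), call. = FALSE))
  mc <- mcols(gr)
  if (is.null(mc$type) || is.null(mc$gene_id))
    stop(sprintf("GTF '%s' lacks feature types or gene_id attributes",
                 gtfPath), call. = FALSE)
  type <- as.character(mc$type)

  exons <- gr[type == "exon"]
  if (!length(exons))
    stop(sprintf("GTF '%s' contains no exon features", gtfPath),
         call. = FALSE)
  tid <- mcols(exons)$transcript_id
  if (is.null(tid)) tid <- rep(NA_character_, length(exons))
  mcols(exons)$transcript_id <- tid
  bad <- which(is.na(mcols(exons)$gene_id) |
                 is.na(mcols(exons)$transcript_id))
  if (length(bad)) {
    b <- exons[bad[1]]
    stop(sprintf(
      "GTF '%s': exon %s:%d-%d lacks gene_id/transcript_id attributes",
      gtfPath, as.character(seqnames(b)), start(b), end(b)), call. = FALSE)
  }

  gname <- mcols(exons)$gene_name
  if (is.null(gname)) gname <- rep(NA_character_, length(exons))
  gname <- ifelse(is.na(gname), mcols(exons)$gene_id, gname)
  mcols(exons) <- S4Vectors::DataFrame(
    transcript_id = mcols(exons)$transcript_id,
    gene_id = mcols(exons)$gene_id, gene_name = gname)
  exons <- sort(exons, ignore.strand = TRUE)

  transcripts <- .featureOrDerive(gr, type, "transcript", exons,
                                  by = "transcript_id")
  genes <- .featureOrDerive(gr, type, "gene", exons, by = "gene_id")
  mcols(genes)$transcript_id <- NULL

  db <- new("AnnotationIndex", sourcePath = gtfPath,
            cachePath = if (cache) cachePath else NA_character_,
            genes = genes, transcripts = transcripts, exons = exons)
  message(sprintf("parsed '%s': %d genes, %d transcripts, %d exons",
                  gtfPath, length(genes), length(transcripts),
                  length(exons)))
  if (cache) {
    saveRDS(list(version = .CACHE_VERSION, gtf = basename(gtfPath),
                 mtime = file.mtime(gtfPath), genes = genes,
                 transcripts = transcripts, exons = exons),
            cachePath)
    message("annotation cache written: ", cachePath)
  }
  db
}

# take explicit gene/transcript rows when the GTF has them, otherwise derive
# spans from the exons
.featureOrDerive <- function(gr, type, what, exons, by) {
  rows <- gr[type == what]
  if (length(rows)) {
    gname <- mcols(rows)$gene_name
    if (is.null(gname)) gname <- rep(NA_character_, length(rows))
    gname <- ifelse(is.na(gname), mcols(rows)$gene_id, gname)
    tid <- if (by == "transcript_id") mcols(rows)$transcript_id
           else rep(NA_character_, length(rows))
    mcols(rows) <- S4Vectors::DataFrame(
      transcript_id = tid, gene_id = mcols(rows)$gene_id, gene_name = gname)
    return(sort(rows, ignore.strand = TRUE))
  }
  ids <- mcols(exons)[[by]]
  sp <- split(seq_along(exons), ids)
  first <- vapply(sp, `[`, integer(1), 1L)
  rows <- GRanges(
    seqnames(exons)[first],
    IRanges(vapply(sp, function(i) min(start(exons)[i]), integer(1)),
            vapply(sp, function(i) max(end(exons)[i]), integer(1))),
    strand = strand(exons)[first],
    transcript_id = if (by == "transcript_id") names(sp)
                    else NA_character_,
    gene_id = as.character(mcols(exons)$gene_id[first]),
    gene_name = as.character(mcols(exons)$gene_name[first]))
  sort(rows, ignore.strand = TRUE)
}

#' Resolve a region query to genomic coordinates
#'
#' The region of interest can be given as browser-style coordinates —
#' `"chrom:start-end"` or `"chrom:start:end:strand"`, 1-based inclusive —
#' or as a gene name or gene id present in the annotation. Gene queries
#' return the gene's full span and strand; coordinate queries are unstranded
#' unless a strand is given. The query text becomes the region label (the
#' plot title), with the gene symbol preferred for gene queries.
#'
#' @param db an [AnnotationIndex].
#' @param query query string.
#' @return a length-1 [GenomicRanges::GRanges] with a `label` metadata
#'   column.
#' @examples
#' \dontrun{resolveRegion(db, "chr1:207513000-207515000")}
#' @export
resolveRegion <- function(db, query) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query))
  m <- regmatches(query, regexec(
    "^([^:]+):([0-9,]+)[-:]([0-9,]+)(?::([+-]))?$", query))[[1]]
  if (length(m)) {
    s <- as.numeric(gsub(",", "", m[3]))
    e <- as.numeric(gsub(",", "", m[4]))
    if (!is.finite(s) || !is.finite(e) || s > e)
      stop(sprintf("invalid coordinate region '%s': start must not exceed end",
                   query), call. = FALSE)
    strnd <- if (is.na(m[5]) || !nzchar(m[5])) "*" else m[5]
    gr <- GRanges(m[2], IRanges(s, e), strand = strnd)
    mcols(gr)$label <- query
    return(gr)
  }

  g <- annotationGenes(db)
  hit <- which(mcols(g)$gene_name == query | mcols(g)$gene_id == query)
  if (!length(hit))
    stop(sprintf("gene '%s' not found in annotation '%s'", query,
                 db@sourcePath), call. = FALSE)
  if (length(unique(mcols(g)$gene_id[hit])) > 1L)
    stop(sprintf("gene name '%s' is ambiguous in '%s'; candidates: %s",
                 query, db@sourcePath,
                 paste(mcols(g)$gene_id[hit], collapse = ", ")),
         call. = FALSE)
  gr <- granges(g[hit[1]])
  lab <- mcols(g)$gene_name[hit[1]]
  mcols(gr)$label <- if (is.na(lab) || !nzchar(lab)) query else lab
  gr
}
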
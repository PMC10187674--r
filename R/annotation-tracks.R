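#' Transcript models overlapping a region
#'
#' Returns every transcript whose genomic span overlaps the region by at
#' least one nucleotide — a transcript overlapping only through an intron is
#' still included, since its span overlaps. Exon structures are returned
#' whole (clipping to the window happens at draw time, with a cut-edge cue
#' when a transcript extends beyond it).
#'
#' @param db an [AnnotationIndex].
#' @param region length-1 `GRanges`. Overlap is tested ignoring strand: the
#'   annotation panel shows all transcripts in the window.
#' @return a [GenomicRanges::GRangesList] of exons, one element per
#'   transcript, named by `transcript_id`, with `transcript_id`, `gene_id`,
#'   `gene_name` and `strand` in its `mcols`. Empty when nothing overlaps.
#' @export
transcriptsInRegion <- function(db, region) {
  tx <- annotationTranscripts(db)
  hit <- tx[suppressWarnings(overlapsAny(tx, region, ignore.strand = TRUE))]
  ex <- annotationExons(db)
  ex <- ex[mcols(ex)$transcript_id %in% mcols(hit)$transcript_id]
  grl <- GenomicRanges::GRangesList(split(granges(ex),
                                          mcols(ex)$transcript_id))
  # order by genomic start for stable downstream layout
  ord <- order(vapply(start(grl), min, integer(1)),
               vapply(end(grl), max, integer(1)), names(grl))
  grl <- grl[ord]
  idx <- match(names(grl), mcols(hit)$transcript_id)
  mcols(grl) <- S4Vectors::DataFrame(
    transcript_id = names(grl),
    gene_id = mcols(hit)$gene_id[idx],
    gene_name = mcols(hit)$gene_name[idx],
    tx_strand = as.character(strand(hit))[idx])
  grl
}

#' Collapse transcripts of one gene into a meta-transcript
#'
#' The "gene"-level annotation draws a single meta-transcript per gene whose
#' exons are the interval union of all exons across all the gene's isoforms.
#' The union is computed with `GenomicRanges::reduce`, so the resulting
#' meta-exons are disjoint and sorted, and every input exon is contained in
#' some meta-exon.
#'
#' @param transcripts a `GRangesList` of exons (as returned by
#'   [transcriptsInRegion()]) whose elements all belong to one gene.
#' @return a length-1 `GRangesList` named by `gene_id`, holding the
#'   meta-exons, with `gene_id`, `gene_name`, `strand` mcols.
#' @export
collapseToMetagene <- function(transcripts) {
  gid <- unique(mcols(transcripts)$gene_id)
  if (length(gid) != 1L)
    stop("collapseToMetagene() requires transcripts of a single gene; got: ",
         paste(gid, collapse = ", "), call. = FALSE)
  meta <- reduce(sort(unlist(transcripts, use.names = FALSE)),
                 ignore.strand = TRUE)
  out <- GenomicRanges::GRangesList(stats::setNames(list(meta), gid))
  mcols(out) <- S4Vectors::DataFrame(
    transcript_id = gid, gene_id = gid,
    gene_name = mcols(transcripts)$gene_name[1],
    tx_strand = mcols(transcripts)$tx_strand[1])
  out
}

#' @describeIn collapseToMetagene collapse every gene overlapping the region
#'   to its meta-transcript.
#' @param db an [AnnotationIndex].
#' @param region length-1 `GRanges`.
#' @export
genesInRegion <- function(db, region) {
  tx <- transcriptsInRegion(db, region)
  if (!length(tx)) return(tx)
  out <- lapply(split(seq_along(tx), mcols(tx)$gene_id),
                function(i) collapseToMetagene(tx[i]))
  metas <- do.call(c, unname(out))
  metas[order(vapply(start(metas), min, integer(1)), names(metas))]
}

#' Assign non-overlapping display rows to transcript models
#'
#' Greedy first-fit interval scheduling: models are sorted by genomic start
#' (ties broken by end, then id, so the layout is deterministic) and each is
#' placed on the lowest row where its span, padded by a fixed horizontal
#' gap, does not collide with a model already on that row.
#'
#' @param models a `GRangesList` as returned by [transcriptsInRegion()] or
#'   [genesInRegion()].
#' @param padding horizontal gap (nt) kept between same-row models; default
#'   1% of the widest span, at least 1 nt.
#' @return `models` with an integer `row` mcol (0-based from the bottom).
#' @export
layoutTranscripts <- function(models, padding = NULL) {
  if (!length(models)) {
    mcols(models)$row <- integer()
    return(models)
  }
  sp_start <- vapply(start(models), min, integer(1))
  sp_end <- vapply(end(models), max, integer(1))
  if (is.null(padding))
    padding <- max(1, round(0.01 * max(sp_end - sp_start + 1)))
  ord <- order(sp_start, sp_end, names(models))
  rowEnds <- numeric(0)  # rightmost occupied coordinate per row
  row <- integer(length(models))
  for (i in ord) {
    fit <- which(rowEnds + padding < sp_start[i])
    r <- if (length(fit)) min(fit) else length(rowEnds) + 1L
    rowEnds[r] <- sp_end[i]
    row[i] <- r - 1L
  }
  mcols(models)$row <- row
  models
}
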
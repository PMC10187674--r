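#' Accessors for xlinkplot classes
#'
#' Small accessor generics: `trackName()` and `librarySize()` on
#' [CrosslinkTrack] and [SignalProfile], `crosslinkSites()` on
#' [CrosslinkTrack], `profileValues()`, `profileRegion()`, `profileGroup()`,
#' `profileStrand()` and `unitsLabel()` on [SignalProfile], and
#' `annotationGenes()`, `annotationTranscripts()`, `annotationExons()` on
#' [AnnotationIndex].
#'
#' @param x an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))
#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))
#' @rdname accessors
#' @export
setGeneric("crosslinkSites", function(x) standardGeneric("crosslinkSites"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profileRegion", function(x) standardGeneric("profileRegion"))
#' @rdname accessors
#' @export
setGeneric("profileGroup", function(x) standardGeneric("profileGroup"))
#' @rdname accessors
#' @export
setGeneric("profileStrand", function(x) standardGeneric("profileStrand"))
#' @rdname accessors
#' @export
setGeneric("unitsLabel", function(x) standardGeneric("unitsLabel"))
#' @rdname accessors
#' @export
setGeneric("annotationGenes", function(x) standardGeneric("annotationGenes"))
#' @rdname accessors
#' @export
setGeneric("annotationTranscripts",
           function(x) standardGeneric("annotationTranscripts"))
#' @rdname accessors
#' @export
setGeneric("annotationExons", function(x) standardGeneric("annotationExons"))

#' @rdname accessors
setMethod("trackName", "CrosslinkTrack", function(x) x@name)
#' @rdname accessors
setMethod("trackName", "SignalProfile", function(x) x@name)
#' @rdname accessors
setMethod("librarySize", "CrosslinkTrack", function(x) x@librarySize)
#' @rdname accessors
setMethod("crosslinkSites", "CrosslinkTrack", function(x) x@sites)
#' @rdname accessors
setMethod("profileValues", "SignalProfile", function(x) x@values)
#' @rdname accessors
setMethod("profileRegion", "SignalProfile", function(x) x@region)
#' @rdname accessors
setMethod("profileGroup", "SignalProfile", function(x) x@group)
#' @rdname accessors
setMethod("profileStrand", "SignalProfile", function(x) x@strand)
#' @rdname accessors
setMethod("unitsLabel", "SignalProfile", function(x) x@unitsLabel)
#' @rdname accessors
setMethod("annotationGenes", "AnnotationIndex", function(x) x@genes)
#' @rdname accessors
setMethod("annotationTranscripts", "AnnotationIndex",
          function(x) x@transcripts)
#' @rdname accessors
setMethod("annotationExons", "AnnotationIndex", function(x) x@exons)

setMethod("show", "CrosslinkTrack", function(object) {
  cat("CrosslinkTrack '", object@name, "': ", length(object@sites),
      " sites, library size ", format(object@librarySize, big.mark = ","),
      "\n", sep = "")
})

setMethod("show", "SignalProfile", function(object) {
  r <- object@region
  cat("SignalProfile '", object@name, "' (group '", object@group, "', ",
      object@strand, ") over ", as.character(seqnames(r)), ":", start(r),
      "-", end(r), " [", length(object@values), " nt]; units: ",
      object@unitsLabel, "\n", sep = "")
})

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex from ", object@sourcePath, "\n  ",
      length(object@genes), " genes, ", length(object@transcripts),
      " transcripts, ", length(object@exons), " exons",
      if (!is.na(object@cachePath)) paste0("\n  cache: ", object@cachePath),
      "\n", sep = "")
})

setMethod("show", "GroupStyle", function(object) {
  cat("GroupStyle: ", length(object@trackGroup), " tracks in ",
      length(unique(object@trackGroup)), " groups\n", sep = "")
  for (g in unique(object@trackGroup))
    cat("  ", g, " (", object@groupColor[[g]], "): ",
        paste(names(object@trackGroup)[object@trackGroup == g],
              collapse = ", "), "\n", sep = "")
})
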
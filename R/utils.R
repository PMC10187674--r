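# internal helpers

#' @importFrom tools file_path_sans_ext file_ext
trackNameFromPath <- function(path) {
  nm <- file_path_sans_ext(basename(path))
  # strip a second extension layer for e.g. track.bedgraph.gz
  if (tolower(file_ext(nm)) %in% c("bed", "bedgraph", "bg", "bw", "bigwig"))
    nm <- file_path_sans_ext(nm)
  nm
}

# Fixed ordered palette for automatic group colors (Okabe-Ito first, then
# extras), so identical inputs always receive identical colors.
.xlinkPalette <- c(
  "#E69F00", "#56B4E9", "#009E73", "#D55E00", "#CC79A7", "#0072B2",
  "#F0E442", "#999999", "#882255", "#44AA99", "#332288", "#AA4499"
)

.assertFileExists <- function(path, what = "input file") {
  if (length(path) != 1L || is.na(path) || !file.exists(path))
    stop(sprintf("%s not found: %s", what, path), call. = FALSE)
  invisible(path)
}

# region label helper: the plot title
regionLabel <- function(region) {
  lab <- mcols(region)$label
  if (is.null(lab) || is.na(lab) || !nzchar(lab))
    sprintf("%s:%d-%d", as.character(seqnames(region)), start(region),
            end(region))
  else lab
}

# warn loudly when a track's chromosome naming does not match the region's
# (e.g. "chr1" vs "1"); no automatic aliasing is attempted
.checkChromDialect <- function(trackSeqnames, region, what, name) {
  chr <- as.character(seqnames(region))
  have <- unique(as.character(trackSeqnames))
  if (length(have) && !chr %in% have) {
    warning(sprintf(
      paste0("%s '%s' has no data on chromosome '%s' (chromosomes present: ",
             "%s); chromosome naming dialects are not aliased automatically ",
             "and the profile will be empty"),
      what, name, chr, paste(utils::head(have, 5), collapse = ", ")),
      call. = FALSE)
    return(FALSE)
  }
  TRUE
}
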
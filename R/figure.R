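#' @import ggplot2
#' @importFrom grid arrow unit
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve track grouping and colors
#'
#' Every track belongs to a display group (defaulting to its own name) and
#' every group has one color. Unspecified colors are drawn from a fixed
#' ordered palette in order of group appearance, so identical inputs always
#' produce identical styling. Grouped replicates share their group's color.
#'
#' @param trackNames character vector of track names (file basenames are
#'   used when tracks were named from paths).
#' @param groups optional named character, track name -> group label;
#'   unnamed values are matched to tracks positionally.
#' @param colors optional colors: either named (group -> color) or an
#'   unnamed vector matched to groups in order of appearance. Supplying
#'   fewer colors than groups is an error.
#' @return a [GroupStyle].
#' @export
assignStyles <- function(trackNames, groups = NULL, colors = NULL) {
  stopifnot(is.character(trackNames), length(trackNames) > 0)
  tg <- stats::setNames(trackNames, trackNames)
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != length(trackNames))
        stop(sprintf("got %d group labels for %d tracks", length(groups),
                     length(trackNames)), call. = FALSE)
      names(groups) <- trackNames
    }
    unknown <- setdiff(names(groups), trackNames)
    if (length(unknown))
      stop("groups reference unknown tracks: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    tg[names(groups)] <- groups
  }
  glevels <- unique(unname(tg))
  if (is.null(colors)) {
    gc <- stats::setNames(rep_len(.xlinkPalette, length(glevels)), glevels)
  } else if (is.null(names(colors))) {
    if (length(colors) < length(glevels))
      stop(sprintf("%d colors supplied for %d groups", length(colors),
                   length(glevels)), call. = FALSE)
    gc <- stats::setNames(colors[seq_along(glevels)], glevels)
  } else {
    unknown <- setdiff(names(colors), glevels)
    if (length(unknown))
      stop("colors reference unknown groups: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    gc <- stats::setNames(rep_len(.xlinkPalette, length(glevels)), glevels)
    gc[names(colors)] <- colors
  }
  new("GroupStyle", trackGroup = tg, groupColor = gc)
}

#' Resolve panel height ratios
#'
#' Four ratios, in panel order crosslink : auxiliary : coverage :
#' annotation. Absent panels always get ratio 0. When the user supplies no
#' ratios, defaults of 40:10:25:25 are used, with the annotation share
#' growing with the number of stacked transcript rows so crowded regions
#' stay legible. User-supplied ratios are used verbatim for the panels that
#' are present.
#'
#' @param panels named logical of length 4
#'   (`crosslink`, `auxiliary`, `coverage`, `annotation`).
#' @param userRatios optional numeric of length 4; a non-positive value for
#'   a present panel is an error.
#' @param nAnnotationRows number of stacked rows in the annotation panel.
#' @return numeric of length 4.
#' @export
computePanelRatios <- function(panels, userRatios = NULL,
                               nAnnotationRows = 1) {
  want <- c("crosslink", "auxiliary", "coverage", "annotation")
  stopifnot(is.logical(panels), all(want %in% names(panels)))
  panels <- panels[want]
  if (!is.null(userRatios) && !all(is.na(userRatios))) {
    if (length(userRatios) != 4L)
      stop("expected exactly four panel ratios", call. = FALSE)
    if (any(userRatios[panels] <= 0))
      stop("panel ratios must be positive for panels that are present",
           call. = FALSE)
    r <- userRatios
  } else {
    r <- c(40, 10, 25, 25 + 3 * max(0, nAnnotationRows - 1))
  }
  r[!panels] <- 0
  stats::setNames(r, want)
}

#' Construct a FigureSpec
#'
#' @param region length-1 `GRanges` with a `label` mcol.
#' @param output output path ending in `.pdf` or `.png`.
#' @param ratios four panel height ratios, or `NA` for dynamic scaling.
#' @param size page `c(width, height)` in inches (default 10 x 8; PNG is
#'   rendered at 300 dpi).
#' @param scaleY independently scale the y-axis of each crosslink group.
#' @param highlight `c(start, end)` of a gray highlight box, or `NA`.
#' @return a [FigureSpec].
#' @export
figureSpec <- function(region, output, ratios = NA_real_, size = c(10, 8),
                       scaleY = FALSE, highlight = NA_real_) {
  new("FigureSpec", region = region, ratios = as.numeric(ratios),
      size = as.numeric(size), scaleYPerGroup = scaleY,
      highlight = as.numeric(highlight), output = output)
}

.hasHighlight <- function(spec) !all(is.na(spec@highlight))

.highlightLayer <- function(highlight) {
  annotate("rect", xmin = highlight[1], xmax = highlight[2], ymin = -Inf,
           ymax = Inf, fill = "grey82", alpha = 0.6)
}

.panelTheme <- function(showX = FALSE) {
  t <- theme_classic(base_size = 10) +
    theme(legend.title = element_blank(),
          legend.key.height = unit(0.45, "cm"))
  if (!showX)
    t <- t + theme(axis.text.x = element_blank(),
                   axis.ticks.x = element_blank(),
                   axis.title.x = element_blank())
  t
}

.xlim <- function(region) c(start(region) - 0.5, end(region) + 0.5)

.profileFrame <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    r <- profileRegion(p)
    data.frame(pos = seq(start(r), end(r)), value = profileValues(p),
               name = trackName(p), group = profileGroup(p),
               strand = profileStrand(p), stringsAsFactors = FALSE)
  }))
}

# crosslink panel: one line (or per-nucleotide bars when unsmoothed) per
# track, colored by group; optional per-group free-y facets
.plotCrosslinkPanel <- function(profiles, style, spec, geom = c("line", "bar"),
                                showX = FALSE) {
  geom <- match.arg(geom)
  df <- .profileFrame(profiles)
  df$group <- factor(df$group, levels = unique(style@trackGroup))
  p <- ggplot(df, aes(x = .data$pos, y = .data$value))
  if (.hasHighlight(spec)) p <- p + .highlightLayer(spec@highlight)
  p <- if (geom == "line") {
    p + geom_line(aes(colour = .data$group, linetype = .data$strand,
                      group = interaction(.data$name, .data$strand)),
                  linewidth = 0.4) +
      scale_linetype_manual(values = c(`+` = "solid", `-` = "42",
                                       `*` = "solid"), guide = "none")
  } else {
    p + geom_col(aes(fill = .data$group,
                     group = interaction(.data$name, .data$strand)),
                 width = 1, position = "identity", alpha = 0.7)
  }
  p <- p +
    scale_colour_manual(values = style@groupColor, drop = FALSE,
                        aesthetics = c("colour", "fill")) +
    coord_cartesian(xlim = .xlim(spec@region), expand = FALSE) +
    labs(y = unitsLabel(profiles[[1]])) +
    .panelTheme(showX)
  if (spec@scaleYPerGroup)
    p <- p + facet_grid(rows = vars(.data$group), scales = "free_y") +
      theme(strip.text.y = element_text(angle = 0, size = 7))
  p
}

.plotAuxiliaryPanel <- function(features, spec, defaultColor = "grey35",
                                showX = FALSE) {
  region <- spec@region
  p <- ggplot()
  if (.hasHighlight(spec)) p <- p + .highlightLayer(spec@highlight)
  if (length(features)) {
    keep <- overlapsAny(features, region, ignore.strand = TRUE)
    features <- features[keep]
  }
  if (length(features)) {
    grl <- GenomicRanges::GRangesList(
      stats::setNames(as.list(split(granges(features),
                                    seq_along(features))),
                      mcols(features)$name))
    row <- mcols(layoutTranscripts(grl))$row
    df <- data.frame(
      xmin = pmax(start(features), start(region)),
      xmax = pmin(end(features), end(region)),
      row = row, name = mcols(features)$name,
      fill = ifelse(is.na(mcols(features)$color), defaultColor,
                    mcols(features)$color))
    p <- p +
      geom_rect(data = df,
                aes(xmin = .data$xmin - 0.5, xmax = .data$xmax + 0.5,
                    ymin = .data$row + 0.1, ymax = .data$row + 0.75),
                fill = df$fill) +
      geom_text(data = df,
                aes(x = (.data$xmin + .data$xmax) / 2, y = .data$row + 0.92,
                    label = .data$name), size = 2.3, vjust = 0.5)
    ymax <- max(df$row) + 1.2
  } else ymax <- 1
  p + coord_cartesian(xlim = .xlim(region), ylim = c(0, ymax),
                      expand = FALSE) +
    labs(y = "Features") + .panelTheme(showX) +
    theme(axis.text.y = element_blank(), axis.ticks.y = element_blank())
}

.plotCoveragePanel <- function(covProfiles, style, spec, showX = FALSE) {
  df <- .profileFrame(covProfiles)
  df$group <- factor(style@trackGroup[df$name],
                     levels = unique(style@trackGroup))
  p <- ggplot(df, aes(x = .data$pos, y = .data$value))
  if (.hasHighlight(spec)) p <- p + .highlightLayer(spec@highlight)
  p + geom_line(aes(colour = .data$group, group = .data$name),
                linewidth = 0.4) +
    scale_colour_manual(values = style@groupColor, drop = FALSE) +
    coord_cartesian(xlim = .xlim(spec@region), expand = FALSE) +
    labs(y = "Signal") + .panelTheme(showX)
}

# annotation panel: exons as filled boxes, introns as a thin line with a
# strand arrow; transcripts clipped to the window with a dotted cut cue
.plotAnnotationPanel <- function(models, spec, showX = TRUE) {
  region <- spec@region
  p <- ggplot()
  if (length(models)) {
    geneIds <- sort(unique(mcols(models)$gene_id))
    geneCol <- stats::setNames(rep_len(.xlinkPalette, length(geneIds)),
                               geneIds)
    row <- mcols(models)$row
    spanS <- vapply(start(models), min, integer(1))
    spanE <- vapply(end(models), max, integer(1))
    spans <- data.frame(
      xmin = pmax(spanS, start(region)), xmax = pmin(spanE, end(region)),
      cutL = spanS < start(region), cutR = spanE > end(region),
      row = row, gene = mcols(models)$gene_name,
      gene_id = mcols(models)$gene_id, strand = mcols(models)$tx_strand)
    ex <- unlist(models, use.names = FALSE)
    exrow <- rep(row, lengths(models))
    exgene <- rep(mcols(models)$gene_id, lengths(models))
    keep <- start(ex) <= end(region) & end(ex) >= start(region)
    exdf <- data.frame(
      xmin = pmax(start(ex), start(region))[keep],
      xmax = pmin(end(ex), end(region))[keep],
      row = exrow[keep], gene_id = exgene[keep])
    exdf$gene <- mcols(models)$gene_name[match(exdf$gene_id,
                                               mcols(models)$gene_id)]
    p <- p +
      geom_segment(data = spans,
                   aes(x = .data$xmin, xend = .data$xmax,
                       y = .data$row + 0.4, yend = .data$row + 0.4,
                       colour = .data$gene_id), linewidth = 0.3) +
      geom_rect(data = exdf,
                aes(xmin = .data$xmin - 0.5, xmax = .data$xmax + 0.5,
                    ymin = .data$row + 0.12, ymax = .data$row + 0.68,
                    fill = .data$gene_id)) +
      geom_segment(data = spans,
                   aes(x = ifelse(.data$strand == "-", .data$xmax,
                                  .data$xmin),
                       xend = ifelse(.data$strand == "-", .data$xmin,
                                     .data$xmax),
                       y = .data$row + 0.4, yend = .data$row + 0.4,
                       colour = .data$gene_id),
                   linewidth = 0.2,
                   arrow = arrow(length = unit(1.6, "mm"), ends = "last",
                                 type = "open")) +
      scale_colour_manual(values = geneCol,
                          labels = spans$gene[match(names(geneCol),
                                                    spans$gene_id)],
                          aesthetics = c("colour", "fill"),
                          name = NULL)
    cut <- data.frame(
      x = c(rep(start(region), sum(spans$cutL)),
            rep(end(region), sum(spans$cutR))),
      row = c(spans$row[spans$cutL], spans$row[spans$cutR]))
    if (nrow(cut))
      p <- p + geom_segment(data = cut,
                            aes(x = .data$x, xend = .data$x,
                                y = .data$row + 0.05, yend = .data$row + 0.75),
                            linetype = "13", linewidth = 0.4,
                            colour = "grey30")
    ymax <- max(row) + 1
  } else ymax <- 1
  p + coord_cartesian(xlim = .xlim(region), ylim = c(-0.05, ymax),
                      expand = FALSE) +
    labs(y = "Annotation", x = sprintf("Position on %s",
                                       as.character(seqnames(region)))) +
    .panelTheme(showX) +
    theme(axis.text.y = element_blank(), axis.ticks.y = element_blank())
}

#' Assemble the multi-panel figure object
#'
#' Builds the one-to-four panel figure — crosslink signal, auxiliary
#' intervals, coverage, annotation — as a patchwork of ggplot panels that
#' all share the region's x-range. The crosslink panel is always drawn; the
#' other panels appear when their inputs are supplied. Panel heights follow
#' [computePanelRatios()]. The figure object is returned without touching
#' the filesystem; [composeFigure()] additionally writes it to file.
#'
#' @param profiles list of crosslink [SignalProfile] (from
#'   [processTracks()]).
#' @param spec a [FigureSpec].
#' @param style a [GroupStyle] for the crosslink tracks; defaults to
#'   singleton groups with palette colors.
#' @param aux auxiliary features ([readAuxiliary()]), or `NULL` for no
#'   auxiliary panel (an empty `GRanges` still draws the panel, empty).
#' @param coverage list of coverage [SignalProfile]s, or `NULL`.
#' @param coverageStyle a [GroupStyle] for the coverage tracks.
#' @param annotation a laid-out `GRangesList` ([layoutTranscripts()]), or
#'   `NULL` for no annotation panel.
#' @param crosslinkGeom `"line"` for smoothed profiles or `"bar"` for
#'   per-nucleotide bars (the natural choice with `smoothing = "none"`).
#' @return a patchwork object.
#' @export
buildFigure <- function(profiles, spec, style = NULL, aux = NULL,
                        coverage = NULL, coverageStyle = NULL,
                        annotation = NULL,
                        crosslinkGeom = c("line", "bar")) {
  crosslinkGeom <- match.arg(crosslinkGeom)
  stopifnot(length(profiles) >= 1)
  if (is.null(style))
    style <- assignStyles(unique(vapply(profiles, trackName, character(1))))
  present <- c(crosslink = TRUE, auxiliary = !is.null(aux),
               coverage = !is.null(coverage) && length(coverage) > 0,
               annotation = !is.null(annotation))
  nRows <- if (present[["annotation"]] && length(annotation))
    max(mcols(annotation)$row) + 1L else 1L
  ratios <- computePanelRatios(present, spec@ratios, nRows)

  last <- max(which(present))
  panels <- list()
  panels$crosslink <- .plotCrosslinkPanel(profiles, style, spec,
                                          geom = crosslinkGeom,
                                          showX = last == 1L)
  if (present[["auxiliary"]])
    panels$auxiliary <- .plotAuxiliaryPanel(aux, spec, showX = last == 2L)
  if (present[["coverage"]]) {
    if (is.null(coverageStyle))
      coverageStyle <- assignStyles(
        unique(vapply(coverage, trackName, character(1))))
    panels$coverage <- .plotCoveragePanel(coverage, coverageStyle, spec,
                                          showX = last == 3L)
  }
  if (present[["annotation"]])
    panels$annotation <- .plotAnnotationPanel(annotation, spec, showX = TRUE)

  patchwork::wrap_plots(panels, ncol = 1,
                        heights = ratios[present][names(panels)]) +
    patchwork::plot_annotation(title = regionLabel(spec@region))
}

#' Compose and write the figure
#'
#' Builds the figure with [buildFigure()] and writes it in the format
#' implied by the output filename extension: `.pdf` or `.png` (PNG at 300
#' dpi). Any other extension is an error. The file is written atomically
#' (rendered to a temporary sibling and renamed), so a failed run leaves no
#' partial output behind.
#'
#' @inheritParams buildFigure
#' @param ... further arguments passed to [buildFigure()].
#' @return the figure object, invisibly.
#' @export
composeFigure <- function(profiles, spec, ...) {
  fig <- buildFigure(profiles, spec, ...)
  writeFigure(fig, spec)
  invisible(fig)
}

#' @describeIn composeFigure write an already-built figure object.
#' @param fig a figure object from [buildFigure()].
#' @export
writeFigure <- function(fig, spec) {
  out <- spec@output
  ext <- tolower(file_ext(out))
  if (!ext %in% c("pdf", "png"))
    stop(sprintf("unsupported output format '.%s'; use one of .pdf, .png",
                 ext), call. = FALSE)
  tmp <- file.path(dirname(out),
                   paste0(".", basename(out), ".partial.", ext))
  on.exit(unlink(tmp), add = TRUE)
  if (ext == "pdf") {
    grDevices::pdf(tmp, width = spec@size[1], height = spec@size[2],
                   useDingbats = FALSE)
  } else {
    grDevices::png(tmp, width = spec@size[1], height = spec@size[2],
                   units = "in", res = 300)
  }
  print(fig)
  grDevices::dev.off()
  if (!file.rename(tmp, out)) {
    file.copy(tmp, out, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(out)
}
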
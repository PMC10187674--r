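#' Densify a crosslink track over a region
#'
#' Places the track's per-position counts into a dense vector spanning the
#' region (one value per nucleotide, 0 where no crosslink was observed).
#' Only sites on `strandUse` contribute; by default that is the region's
#' strand. For an unstranded region the caller (see [processTracks()])
#' extracts each strand separately and overlays the two profiles.
#'
#' @param track a [CrosslinkTrack].
#' @param region length-1 `GRanges`.
#' @param strandUse `"+"` or `"-"`; defaults to the region strand (or `"+"`
#'   when the region is unstranded).
#' @return a [SignalProfile] with units label `"Crosslinks"`.
#' @export
extractRegionSignal <- function(track, region,
                                strandUse = as.character(strand(region))) {
  stopifnot(length(region) == 1L)
  if (strandUse == "*") strandUse <- "+"
  s <- crosslinkSites(track)
  n <- width(region)
  vals <- numeric(n)
  if (length(s)) {
    .checkChromDialect(seqnames(s), region, "crosslink track",
                       trackName(track))
    sel <- s[as.character(strand(s)) == strandUse &
               as.character(seqnames(s)) == as.character(seqnames(region)) &
               start(s) >= start(region) & start(s) <= end(region)]
    if (length(sel)) {
      idx <- start(sel) - start(region) + 1L
      vals[idx] <- vals[idx] + mcols(sel)$score
    } else {
      warning(sprintf(
        "crosslink track '%s' has no %s-strand signal in the region",
        trackName(track), strandUse), call. = FALSE)
    }
  }
  new("SignalProfile", name = trackName(track), group = trackName(track),
      values = vals, region = granges(region), strand = strandUse,
      unitsLabel = "Crosslinks")
}

#' Library-size (crosslinks-per-million) normalization
#'
#' Divides every value by the experiment's total crosslink count — computed
#' from the whole input file, not the displayed region — and multiplies by
#' 1,000,000, giving a crosslinks-per-million (CPM) value comparable across
#' libraries of different depths.
#'
#' @param profile a [SignalProfile].
#' @param librarySize total crosslink events of the experiment; must be > 0.
#' @return the normalized [SignalProfile] (units label
#'   `"Crosslinks per million"`).
#' @export
normalizeLibsize <- function(profile, librarySize) {
  if (!is.numeric(librarySize) || length(librarySize) != 1L ||
      !is.finite(librarySize) || librarySize <= 0)
    stop(sprintf(
      "library size of '%s' must be positive for libsize normalization",
      trackName(profile)), call. = FALSE)
  profile@values <- profile@values / librarySize * 1e6
  profile@unitsLabel <- "Crosslinks per million"
  validObject(profile)
  profile
}

#' Maximum-peak normalization of a group of profiles
#'
#' Divides every profile in one display group by the single group-wide
#' maximum value within the region, so the group's values range from 0 to 1
#' and its maximum is exactly 1. The maximum is pooled across grouped
#' replicates (not per track), so relative differences between replicates
#' are preserved. An all-zero group is returned unchanged with a warning.
#'
#' @param profiles list of [SignalProfile] belonging to one group.
#' @return list of normalized profiles (units label
#'   `"Fraction of maximum"`).
#' @export
normalizeMaxpeak <- function(profiles) {
  if (inherits(profiles, "SignalProfile")) profiles <- list(profiles)
  m <- max(vapply(profiles, function(p) max(p@values, 0), numeric(1)))
  if (m <= 0) {
    warning("group has no signal in the region; maxpeak normalization skipped",
            call. = FALSE)
    return(profiles)
  }
  lapply(profiles, function(p) {
    p@values <- p@values / m
    p@unitsLabel <- "Fraction of maximum"
    validObject(p)
    p
  })
}

#' Custom (size-factor) normalization
#'
#' Divides the profile by a user-supplied per-experiment size factor, e.g.
#' one derived from an external normalization procedure.
#'
#' @param profile a [SignalProfile].
#' @param sizeFactor positive number.
#' @return the scaled [SignalProfile] (units label
#'   `"Custom-scaled crosslinks"`).
#' @export
normalizeCustom <- function(profile, sizeFactor) {
  if (missing(sizeFactor) || !is.numeric(sizeFactor) ||
      length(sizeFactor) != 1L || !is.finite(sizeFactor) || sizeFactor <= 0)
    stop(sprintf("size factor for track '%s' must be a positive number",
                 trackName(profile)), call. = FALSE)
  profile@values <- profile@values / sizeFactor
  profile@unitsLabel <- "Custom-scaled crosslinks"
  profile
}

# shared window hygiene: integer >= 1, odd (so "centered" is well defined),
# no larger than the profile
.checkWindow <- function(window, n) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1)
    stop("smoothing window must be a positive integer", call. = FALSE)
  window <- as.integer(round(window))
  if (window > n) {
    warning(sprintf(
      "smoothing window (%d nt) exceeds the region (%d nt); clamping",
      window, n), call. = FALSE)
    window <- n
  }
  if (window %% 2L == 0L) {
    window <- window + ifelse(window + 1L <= n, 1L, -1L)
    message("even smoothing window adjusted to ", window,
            " nt so the window can be centered")
  }
  max(window, 1L)
}

#' Rolling-mean smoothing
#'
#' Replaces each position by the mean of the values in a window centered on
#' it. Crosslink counts are sparse single-nucleotide spikes; averaging over
#' a window aggregates adjacent sites into a binding-region signal while
#' retaining local variability. Positions whose window extends past the
#' region edge use the truncated window (partial mean), so the output has
#' the same length as the input with no missing values. Even windows are
#' widened by 1 nt so the window can be centered; window 1 is the identity.
#'
#' @param profile a [SignalProfile] (or bare numeric vector).
#' @param window window width in nucleotides.
#' @return the smoothed profile (same class as the input).
#' @export
smoothRollmean <- function(profile, window) {
  if (is.numeric(profile)) return(.rollmeanVec(profile, window))
  profile@values <- .rollmeanVec(profile@values, window)
  profile
}

.rollmeanVec <- function(x, window) {
  window <- .checkWindow(window, length(x))
  if (window == 1L) return(x)
  as.numeric(zoo::rollapply(zoo::zoo(x), width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Gaussian-kernel smoothing
#'
#' Nadaraya-Watson kernel regression on the equally spaced per-nucleotide
#' grid: each position becomes a Gaussian-weighted mean of its neighbours.
#' The kernel standard deviation is `window / 4` and the kernel is truncated
#' at `+/- window / 2`; near the region edges the weights renormalize over
#' the positions that exist, mirroring the rolling mean's truncated-window
#' rule. Heavier to compute than the rolling mean, and most useful on
#' smaller regions or particularly noisy data.
#'
#' @inheritParams smoothRollmean
#' @return the smoothed profile (same class as the input).
#' @export
smoothGaussian <- function(profile, window) {
  if (is.numeric(profile)) return(.gaussianVec(profile, window))
  profile@values <- .gaussianVec(profile@values, window)
  profile
}

.gaussianVec <- function(x, window) {
  window <- .checkWindow(window, length(x))
  if (window == 1L) return(x)
  n <- length(x)
  h <- window %/% 2L
  sd <- window / 4
  num <- numeric(n)
  den <- numeric(n)
  for (o in -h:h) {
    w <- stats::dnorm(o, mean = 0, sd = sd)
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w * x[src[ok]]
    den[ok] <- den[ok] + w
  }
  num / den
}

#' Run the full per-track signal pipeline over a region
#'
#' Fixed order: densify, then normalize, then smooth. For the combined
#' `libsize_maxpeak` mode, library-size normalization is carried out first
#' and maximum-peak normalization second; maxpeak maxima are pooled within
#' each display group (ungrouped tracks are singleton groups). Smoothing is
#' always applied after normalization so smoothed replicates are directly
#' comparable.
#'
#' For a stranded region each track yields one profile; for an unstranded
#' coordinate region both strands are extracted and any strand carrying
#' signal is kept as its own overlaid profile.
#'
#' @param tracks list of [CrosslinkTrack].
#' @param region length-1 `GRanges`.
#' @param normalization one of `"none"`, `"libsize"`, `"maxpeak"`,
#'   `"libsize_maxpeak"`, `"custom"`.
#' @param smoothing one of `"rollmean"`, `"gaussian"`, `"none"`.
#' @param smoothingWindow window in nucleotides (default 100).
#' @param sizeFactors numeric vector, one per track, required when
#'   `normalization = "custom"`.
#' @param groups named character mapping track name to group label; unnamed
#'   tracks form singleton groups. Used for maxpeak pooling and carried onto
#'   the profiles.
#' @return list of [SignalProfile].
#' @export
processTracks <- function(tracks, region,
                          normalization = c("libsize", "none", "maxpeak",
                                            "libsize_maxpeak", "custom"),
                          smoothing = c("rollmean", "gaussian", "none"),
                          smoothingWindow = 100, sizeFactors = NULL,
                          groups = NULL) {
  normalization <- match.arg(normalization)
  smoothing <- match.arg(smoothing)
  if (inherits(tracks, "CrosslinkTrack")) tracks <- list(tracks)
  nms <- vapply(tracks, trackName, character(1))
  if (normalization == "custom") {
    if (is.null(sizeFactors) || length(sizeFactors) != length(tracks))
      stop("custom normalization needs one size factor per crosslink track",
           call. = FALSE)
    names(sizeFactors) <- nms
  }

  strands <- as.character(strand(region))
  unstranded <- strands == "*"
  if (unstranded) {
    message("region is unstranded: both strands are processed and overlaid ",
            "(minus strand drawn with its own linetype)")
  }

  profiles <- list()
  for (i in seq_along(tracks)) {
    trk <- tracks[[i]]
    if (unstranded && length(crosslinkSites(trk)))
      .checkChromDialect(seqnames(crosslinkSites(trk)), region,
                         "crosslink track", trackName(trk))
    for (st in if (unstranded) c("+", "-") else strands) {
      p <- if (unstranded)
        suppressWarnings(extractRegionSignal(trk, region, strandUse = st))
      else extractRegionSignal(trk, region, strandUse = st)
      # for unstranded regions keep a silent strand only if the other one
      # carries signal too; always keep the plus profile
      if (unstranded && st == "-" && all(p@values == 0)) next
      p@group <- if (!is.null(groups) && !is.na(groups[trackName(trk)]))
        unname(groups[trackName(trk)]) else trackName(trk)
      p <- switch(normalization,
        none = p,
        libsize = ,
        libsize_maxpeak = normalizeLibsize(p, librarySize(trk)),
        custom = normalizeCustom(p, sizeFactors[[trackName(trk)]]),
        maxpeak = p)
      profiles[[length(profiles) + 1L]] <- p
    }
  }

  if (normalization %in% c("maxpeak", "libsize_maxpeak")) {
    grp <- vapply(profiles, profileGroup, character(1))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      profiles[idx] <- normalizeMaxpeak(profiles[idx])
    }
  }

  if (smoothing != "none") {
    smoother <- if (smoothing == "rollmean") smoothRollmean else smoothGaussian
    profiles <- lapply(profiles, smoother, window = smoothingWindow)
  }
  profiles
}

#' @describeIn processTracks convenience wrapper for a single track; maxpeak
#'   treats the track as a singleton group.
#' @param track a single [CrosslinkTrack].
#' @param sizeFactor size factor for the single track (custom mode).
#' @export
processTrack <- function(track, region, normalization = "libsize",
                         smoothing = "rollmean", smoothingWindow = 100,
                         sizeFactor = NULL) {
  out <- processTracks(list(track), region, normalization = normalization,
                       smoothing = smoothing,
                       smoothingWindow = smoothingWindow,
                       sizeFactors = sizeFactor)
  if (length(out) == 1L) out[[1]] else out
}
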
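# Spheroid-induced mesothelial clearance: segment spheroid and cleared
# areas from fluorescence channels, fit the cleared-area growth rate,
# normalize by initial spheroid size, and classify spheroid locations
# relative to detected defects.

#' Segment the dominant object in a fluorescence image
#'
#' Otsu threshold, largest connected component at least `min_object_px`
#' pixels, holes filled. Used for the spheroid channel and (on the
#' inverted mesothelial channel) for the cleared region.
#'
#' @param image numeric matrix
#' @param pixel_size micrometres per pixel
#' @param min_object_px discard components smaller than this
#' @param invert segment low-intensity instead of high-intensity pixels
#' @return list `mask` (logical matrix), `area` (um^2), `flagged`
#'   (TRUE when no object was found)
#' @export
segment_area <- function(image, pixel_size = 1, min_object_px = 9L,
                         invert = FALSE) {
  rng <- range(image, finite = TRUE)
  if (diff(rng) == 0)
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                area = 0, flagged = TRUE))
  norm <- (image - rng[1]) / diff(rng)
  if (invert) norm <- 1 - norm
  th <- EBImage::otsu(norm, range = c(0, 1))
  bw <- norm > th
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0)
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                area = 0, flagged = TRUE))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_object_px)
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                area = 0, flagged = TRUE))
  mask <- lab == big
  mask <- EBImage::fillHull(EBImage::Image(mask + 0)) > 0.5
  mask <- matrix(as.logical(mask), nrow(image), ncol(image))
  list(mask = mask, area = sum(mask) * pixel_size^2, flagged = FALSE)
}

#' Cleared-area growth rate
#'
#' Fits cleared area versus time to a line and reports the slope, as the
#' cleared area grows approximately linearly during invasion.
#'
#' @param times hours, strictly increasing, >= 3 points
#' @param cleared_areas um^2, same length
#' @return list `rate` (um^2/h), `intercept`, `r_squared`, `residual_sd`
#' @export
clearance_rate <- function(times, cleared_areas) {
  stopifnot(length(times) >= 3, length(times) == length(cleared_areas),
            all(diff(times) > 0))
  fit <- linreg_ci(times, cleared_areas)
  list(rate = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, residual_sd = fit$residual_sd)
}

#' Normalize a clearance rate by initial spheroid area
#'
#' Larger spheroids clear larger areas; dividing the rate by the
#' spheroid's initial area gives a size-independent rate in 1/h.
#'
#' @param rate um^2/h
#' @param spheroid_area_t0 um^2, must be > 0
#' @return normalized rate (h^-1)
#' @export
normalized_rate <- function(rate, spheroid_area_t0) {
  if (!is.finite(spheroid_area_t0) || spheroid_area_t0 <= 0)
    stop("initial spheroid area must be positive")
  rate / spheroid_area_t0
}

#' Classify a spheroid location relative to detected defects
#'
#' A spheroid within `radius` of a +1/2 core *on the comet-tail side*
#' (positive projection on the tail axis) is `plus_half`. Within
#' `radius` of a -1/2 core it is `minus_half_on_leg` when its
#' perpendicular distance to any leg ray is at most `leg_halfwidth`,
#' else `minus_half_outside_leg`. Anything else is `control`. When a
#' spheroid qualifies for several defects the nearest core wins; exact
#' ties go to the +1/2 class.
#'
#' @param centroid `c(x, y)` of the spheroid (um)
#' @param defects data.frame of defect records with `x`, `y`, `charge`
#'   and a list-column `axes` (tail angle for +1/2, three leg angles for
#'   -1/2)
#' @param radius qualification radius (um)
#' @param leg_halfwidth on-leg band half-width (um)
#' @return one of "control", "plus_half", "minus_half_on_leg",
#'   "minus_half_outside_leg"
#' @export
classify_location <- function(centroid, defects, radius = 750,
                              leg_halfwidth = 45) {
  if (is.null(defects) || nrow(defects) == 0) return("control")
  dx <- centroid[1] - defects$x
  dy <- centroid[2] - defects$y
  d <- sqrt(dx^2 + dy^2)
  cls <- rep(NA_character_, nrow(defects))
  for (i in seq_len(nrow(defects))) {
    if (d[i] > radius) next
    ax <- defects$axes[[i]]
    if (defects$charge[i] > 0) {
      if (dx[i] * cos(ax[1]) + dy[i] * sin(ax[1]) > 0) cls[i] <- "plus_half"
    } else {
      perp <- vapply(ax, function(L) {
        along <- dx[i] * cos(L) + dy[i] * sin(L)
        if (along <= 0) Inf else abs(-dx[i] * sin(L) + dy[i] * cos(L))
      }, 0)
      cls[i] <- if (min(perp) <= leg_halfwidth) "minus_half_on_leg"
      else "minus_half_outside_leg"
    }
  }
  hit <- which(!is.na(cls))
  if (length(hit) == 0) return("control")
  best <- hit[order(d[hit], -defects$charge[hit])][1]
  cls[best]
}

#' Measure one clearance trace from a two-channel stack
#'
#' Segments the spheroid channel per frame for spread area and the
#' inverted mesothelial channel for cleared area, fits the clearance
#' rate, and normalizes by the first-frame spheroid area.
#'
#' @param spheroid,mesothelium lists of image matrices (one per frame)
#' @param times hours, one per frame
#' @param pixel_size micrometres per pixel
#' @param cleared_masks optional list of logical matrices overriding the
#'   automatic cleared-area segmentation (manual masks)
#' @return a `clearance_trace` list: `times`, `spheroid_area`,
#'   `cleared_area`, `rate`, `normalized_rate`, `r_squared`,
#'   `residual_sd`, `flagged`
#' @export
measure_clearance <- function(spheroid, mesothelium, times, pixel_size = 1,
                              cleared_masks = NULL) {
  stopifnot(length(spheroid) == length(times),
            length(mesothelium) == length(times))
  sph_area <- numeric(length(times))
  clr_area <- numeric(length(times))
  flagged <- FALSE
  for (k in seq_along(times)) {
    s <- segment_area(spheroid[[k]], pixel_size)
    sph_area[k] <- s$area
    flagged <- flagged || s$flagged
    if (!is.null(cleared_masks)) {
      clr_area[k] <- sum(cleared_masks[[k]]) * pixel_size^2
    } else {
      cseg <- segment_area(mesothelium[[k]], pixel_size, invert = TRUE)
      clr_area[k] <- if (cseg$flagged) 0 else cseg$area
    }
  }
  fit <- clearance_rate(times, clr_area)
  structure(list(times = times, spheroid_area = sph_area,
                 cleared_area = clr_area, rate = fit$rate,
                 normalized_rate = normalized_rate(fit$rate, sph_area[1]),
                 r_squared = fit$r_squared, residual_sd = fit$residual_sd,
                 flagged = flagged),
            class = "clearance_trace")
}

#' Per-class medians and tests for a cohort of clearance rates
#'
#' Medians per location class; when at least two classes have three or
#' more traces, a Kruskal-Wallis omnibus test plus pairwise rank-sum
#' tests against control with Bonferroni correction.
#'
#' @param rates numeric vector of normalized clearance rates (h^-1)
#' @param classes character vector of location classes, same length
#' @param control name of the control class
#' @return list `medians` (named), `n` (named), `omnibus`
#'   (`TestResult` or NULL), `pairwise` (list or NULL)
#' @export
group_rates <- function(rates, classes, control = "control") {
  stopifnot(length(rates) == length(classes))
  groups <- split(rates, classes)
  medians <- vapply(groups, stats::median, 0)
  usable <- groups[lengths(groups) >= 3]
  omnibus <- NULL; pairwise <- NULL
  if (length(usable) >= 2) {
    omnibus <- kruskal_wallis(usable)
    if (control %in% names(usable) && length(usable) >= 2)
      pairwise <- pairwise_vs_control(usable, control, method = "rank_sum")
  }
  list(medians = medians, n = lengths(groups), omnibus = omnibus,
       pairwise = pairwise)
}
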
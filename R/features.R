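#' Gating thresholds
#'
#' Configuration of the three event gates, applied in order: nucleated,
#' in-focus, singlet. Numeric defaults are tuned to the synthetic renderer and
#' are deliberately configuration-exposed rather than fixed constants, since
#' instrument gating thresholds are study-specific.
#'
#' @param draq5_min_total minimum integrated DRAQ5 intensity for the
#'   nucleated gate.
#' @param focus_min minimum \code{\link{focus_score}} of the brightfield image
#'   (dimensionless).
#' @param nucleus_threshold_frac fraction of the DRAQ5 maximum used to
#'   binarize the nuclear mask.
#' @param min_nucleus_area_px nuclear components smaller than this are ignored
#'   (noise specks).
#' @param cell_threshold_frac fraction of the brightfield maximum used to
#'   binarize the cell mask.
#' @param aspect_max maximum bounding-box aspect ratio of the cell mask for
#'   the singlet gate.
#' @param cell_area_px optional length-2 numeric c(min, max) bounds on the
#'   cell-mask area (px); NULL disables the bound.
#' @return list of class \code{"gate_config"}.
#' @export
gate_config <- function(draq5_min_total = 1e4,
                        focus_min = 0.003,
                        nucleus_threshold_frac = 0.5,
                        min_nucleus_area_px = 25,
                        cell_threshold_frac = 0.2,
                        aspect_max = 2.5,
                        cell_area_px = NULL) {
  check_number(draq5_min_total, "draq5_min_total", lower = 0)
  check_number(focus_min, "focus_min", lower = 0)
  check_number(nucleus_threshold_frac, "nucleus_threshold_frac",
               lower = 1e-6, upper = 1)
  check_number(min_nucleus_area_px, "min_nucleus_area_px", lower = 0)
  check_number(cell_threshold_frac, "cell_threshold_frac",
               lower = 1e-6, upper = 1)
  check_number(aspect_max, "aspect_max", lower = 1)
  if (!is.null(cell_area_px) &&
      (length(cell_area_px) != 2L || any(cell_area_px < 0) ||
       cell_area_px[1] > cell_area_px[2]))
    stop("'cell_area_px' must be c(min, max) with min <= max", call. = FALSE)
  structure(list(draq5_min_total = draq5_min_total, focus_min = focus_min,
                 nucleus_threshold_frac = nucleus_threshold_frac,
                 min_nucleus_area_px = min_nucleus_area_px,
                 cell_threshold_frac = cell_threshold_frac,
                 aspect_max = aspect_max, cell_area_px = cell_area_px),
            class = "gate_config")
}

## Internal: count nuclear components above the speck threshold.
nuclear_components <- function(draq5, cfg) {
  mx <- max(draq5)
  if (mx <= 0) return(0L)
  lab <- label_components(draq5 > cfg$nucleus_threshold_frac * mx, 8)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= cfg$min_nucleus_area_px)
}

cell_mask_of <- function(bf, frac) {
  mx <- max(bf)
  if (mx <= 0) return(matrix(FALSE, nrow(bf), ncol(bf)))
  bf > frac * mx
}

## Normalize gate/extract input to a list of pairs list(untreated=, fccp=);
## a bare cell_image becomes an unpaired untreated member.
as_event_pairs <- function(cells) {
  if (inherits(cells, "cell_image")) cells <- list(cells)
  lapply(cells, function(ev) {
    if (inherits(ev, "cell_image")) {
      if (identical(ev$treatment, "fccp")) list(untreated = NULL, fccp = ev)
      else list(untreated = ev, fccp = NULL)
    } else if (is.list(ev) && !is.null(ev$untreated)) {
      list(untreated = ev$untreated, fccp = ev$fccp)
    } else stop("events must be cell_image objects or untreated/fccp pairs",
                call. = FALSE)
  })
}

#' Gate IFC events
#'
#' Applies the study's three gates in order — (1) nucleated: integrated DRAQ5
#' above threshold with at least one nuclear component; (2) in focus:
#' brightfield gradient-energy score above threshold; (3) singlet: exactly one
#' nuclear component, cell-mask aspect ratio (and optionally area) within
#' bounds — and reports how many events each gate removed. Gates are evaluated
#' on the untreated member of each pair.
#'
#' @param cells list of \code{cell_image} objects or untreated/FCCP pairs
#'   (e.g. from \code{\link{generate_sample}}).
#' @param config a \code{\link{gate_config}}.
#' @return list of class \code{"ifc_gating"}: \code{events} (the retained
#'   pairs), \code{report} (data frame: gate, n_removed), and \code{flags}
#'   (per-event gate booleans).
#' @export
gate_events <- function(cells, config = gate_config()) {
  pairs <- as_event_pairs(cells)
  if (length(pairs) == 0L) stop("no events to gate", call. = FALSE)
  flags <- data.frame(event_id = character(length(pairs)),
                      nucleated = NA, in_focus = NA, singlet = NA,
                      stringsAsFactors = FALSE)
  for (e in seq_along(pairs)) {
    img <- pairs[[e]]$untreated %||% pairs[[e]]$fccp
    flags$event_id[e] <- img$event_id
    ncomp <- nuclear_components(img$channels$draq5, config)
    flags$nucleated[e] <- sum(img$channels$draq5) >= config$draq5_min_total &&
      ncomp >= 1L
    flags$in_focus[e] <- focus_score(img$channels$brightfield) >= config$focus_min
    cm <- cell_mask_of(img$channels$brightfield, config$cell_threshold_frac)
    aspect_ok <- TRUE
    area_ok <- TRUE
    if (any(cm)) {
      rr <- range(which(rowSums(cm) > 0))
      cc <- range(which(colSums(cm) > 0))
      ext <- c(diff(rr) + 1, diff(cc) + 1)
      aspect_ok <- max(ext) / min(ext) <= config$aspect_max
      if (!is.null(config$cell_area_px))
        area_ok <- sum(cm) >= config$cell_area_px[1] &&
          sum(cm) <= config$cell_area_px[2]
    }
    flags$singlet[e] <- ncomp == 1L && aspect_ok && area_ok
  }
  ## sequential removal in the stated order
  alive <- rep(TRUE, length(pairs))
  removed <- integer(3)
  for (g in 1:3) {
    gf <- flags[[c("nucleated", "in_focus", "singlet")[g]]]
    removed[g] <- sum(alive & !gf)
    alive <- alive & gf
  }
  if (!any(alive))
    warning("all events removed by gating", call. = FALSE)
  list(events = structure(pairs[alive], class = c("ifc_sample", "list")),
       report = data.frame(gate = c("nucleated", "in_focus", "singlet"),
                           n_removed = removed, stringsAsFactors = FALSE),
       flags = flags) |>
    structure(class = "ifc_gating")
}

#' @export
print.ifc_gating <- function(x, ...) {
  n_in <- nrow(x$flags)
  cat(sprintf("<ifc_gating> %d events in, %d passed\n", n_in,
              length(x$events)))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Spot-mask parameters
#'
#' Defaults echo the bright-spot mask used for the mitochondrial form factor:
#' brightness threshold 10, minimal area 0, maximal area 2 (interpreted in
#' µm² per component; set \code{max_area = 0} to disable the upper bound, as
#' done for the total-TMRM-area mask).
#'
#' @param brightness_threshold_pct percent in (0, 100]: the mask keeps in-cell
#'   pixels above the (100 - threshold)-th intensity percentile.
#' @param min_area,max_area per-component area bounds (µm²); `max_area = 0`
#'   means unbounded.
#' @param connectivity 4 or 8 (default 8).
#' @return list of class \code{"spot_mask_params"}.
#' @export
spot_mask_params <- function(brightness_threshold_pct = 10,
                             min_area = 0, max_area = 2,
                             connectivity = 8) {
  check_number(brightness_threshold_pct, "brightness_threshold_pct",
               lower = 1e-9, upper = 100)
  check_number(min_area, "min_area", lower = 0)
  check_number(max_area, "max_area", lower = 0)
  if (max_area > 0 && min_area > max_area)
    stop("'min_area' must not exceed 'max_area' when the bound is active",
         call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  structure(list(brightness_threshold_pct = brightness_threshold_pct,
                 min_area = min_area, max_area = max_area,
                 connectivity = as.integer(connectivity)),
            class = "spot_mask_params")
}

#' Bright-spot mask of a fluorescence channel
#'
#' Re-implementation of the "Bright" spot mask: a pixel belongs to the mask if
#' its intensity strictly exceeds both (a) the (100 - threshold)-th percentile
#' of the in-cell intensity distribution and (b) a background floor (by
#' default the robust in-cell floor median + 5 * MAD). Connected components
#' are labelled at the configured connectivity in scanline order, components
#' outside the [min_area, max_area] bound (µm², when bounded) are removed,
#' and per-component areas and sub-pixel perimeters are returned.
#'
#' @param intensity numeric matrix (one channel of one event).
#' @param params a \code{\link{spot_mask_params}}.
#' @param pixel_size µm per pixel.
#' @param cell_mask optional logical matrix restricting the in-cell
#'   distribution and the mask; default uses the whole frame.
#' @param background_floor optional absolute floor overriding the robust
#'   estimate.
#' @param compute_perimeters set FALSE to skip per-component perimeters (the
#'   total-area mask does not need them).
#' @return list of class \code{"ifc_spot_mask"}: \code{mask} (logical),
#'   \code{labels} (integer matrix), \code{n_components},
#'   \code{areas_um2}, \code{perimeters_um}, \code{threshold} (the intensity
#'   cutoff actually applied).
#' @export
spot_mask <- function(intensity, params = spot_mask_params(),
                      pixel_size = 0.33, cell_mask = NULL,
                      background_floor = NULL, compute_perimeters = TRUE) {
  if (!all(is.finite(intensity)))
    stop("'intensity' must be finite", call. = FALSE)
  if (!inherits(params, "spot_mask_params"))
    stop("'params' must be created by spot_mask_params()", call. = FALSE)
  check_number(pixel_size, "pixel_size", lower = 1e-9)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  vals <- intensity[cell_mask]
  q <- stats::quantile(vals, 1 - params$brightness_threshold_pct / 100,
                       names = FALSE)
  ## robust background floor: median plus 6 sd of the sub-90th-percentile
  ## values (the MAD collapses when zero-clamped noise puts >50% of pixels at
  ## exactly zero)
  floorv <- background_floor %||% {
    lower <- vals[vals <= stats::quantile(vals, 0.9, names = FALSE)]
    bg_sd <- if (length(lower) > 1) stats::sd(lower) else 0
    stats::median(vals) + 6 * bg_sd
  }
  thr <- max(q, floorv)
  mask <- intensity > thr & cell_mask
  lab <- label_components(mask, params$connectivity)
  n <- max(lab)
  keep <- seq_len(n)
  areas_um2 <- numeric(0)
  perims_um <- numeric(0)
  if (n > 0L) {
    areas_px <- tabulate(lab[lab > 0], nbins = n)
    areas_um2 <- areas_px * pixel_size^2
    sel <- areas_um2 >= params$min_area &
      (params$max_area <= 0 | areas_um2 <= params$max_area)
    keep <- which(sel)
    ## relabel surviving components consecutively, preserving scanline order
    remap <- match(lab, keep)
    remap[is.na(remap)] <- 0L
    lab <- matrix(as.integer(remap), nrow(lab), ncol(lab))
    mask <- lab > 0L
    areas_um2 <- areas_um2[keep]
    if (compute_perimeters)
      perims_um <- vapply(seq_along(keep), function(i)
        mask_perimeter(lab == i, pixel_size), numeric(1))
    else perims_um <- rep(NA_real_, length(keep))
  }
  structure(list(mask = mask, labels = lab, n_components = length(keep),
                 areas_um2 = areas_um2, perimeters_um = perims_um,
                 threshold = thr, pixel_size = pixel_size),
            class = "ifc_spot_mask")
}

#' Mitochondrial form factor
#'
#' Computes (median perimeter)^2 / (4 * pi * median area) from per-spot areas
#' and perimeters. A form factor of 1 corresponds to a circular spot
#' (isoperimetric identity); fragmentation lowers it, elongation and branching
#' raise it.
#'
#' @param spot_areas numeric vector of spot areas (µm²), at least one.
#' @param spot_perimeters numeric vector of spot perimeters (µm), same length.
#' @return dimensionless scalar; \code{NA} (flagged via a warning-free missing
#'   value) when there are no spots or the median area is zero.
#' @export
form_factor <- function(spot_areas, spot_perimeters) {
  if (length(spot_areas) != length(spot_perimeters))
    stop("'spot_areas' and 'spot_perimeters' must have equal length",
         call. = FALSE)
  if (length(spot_areas) == 0L) return(NA_real_)
  ma <- stats::median(spot_areas)
  if (!is.finite(ma) || ma <= 0) return(NA_real_)
  stats::median(spot_perimeters)^2 / (4 * pi * ma)
}

#' Total TMRM area (mitochondrial swelling)
#'
#' Pixel count of the TMRM mask converted to µm². Accepts an
#' \code{ifc_spot_mask} or a plain logical/numeric mask plus pixel size.
#'
#' @param mask an \code{\link{spot_mask}} result or a matrix.
#' @param pixel_size µm per pixel (ignored when `mask` carries its own).
#' @return area in µm² (0 for an empty mask).
#' @export
tmrm_area <- function(mask, pixel_size = 0.33) {
  if (inherits(mask, "ifc_spot_mask"))
    return(sum(mask$mask) * mask$pixel_size^2)
  sum(mask > 0) * pixel_size^2
}

#' Cytoplasmic (nucleus-excluded) MitoSox intensity
#'
#' Integrates MitoSox over the cell morphology mask (from brightfield) minus
#' the nuclear morphology mask (from DRAQ5) dilated by a safety margin, which
#' removes the nonspecific nucleic-acid-bound MitoSox signal.
#'
#' @param cell a \code{cell_image} with brightfield, draq5 and mitosox
#'   channels.
#' @param nucleus_dilation_px dilation margin of the nuclear mask before
#'   exclusion (default 2 px, suppressing nuclear-edge bleed).
#' @param cell_threshold_frac,nucleus_threshold_frac binarization fractions of
#'   the channel maxima.
#' @return integrated intensity (a.u.); \code{NA} with a warning when the
#'   dilated nuclear mask covers the whole cell.
#' @export
cytoplasmic_mitosox <- function(cell, nucleus_dilation_px = 2,
                                cell_threshold_frac = 0.2,
                                nucleus_threshold_frac = 0.5) {
  stopifnot(inherits(cell, "cell_image"))
  bf <- cell$channels$brightfield
  dq <- cell$channels$draq5
  ms <- cell$channels$mitosox
  if (is.null(bf) || is.null(dq) || is.null(ms))
    stop("brightfield, draq5 and mitosox channels are required", call. = FALSE)
  cm <- cell_mask_of(bf, cell_threshold_frac)
  nm <- if (max(dq) > 0) dq > nucleus_threshold_frac * max(dq)
        else matrix(FALSE, nrow(dq), ncol(dq))
  nm <- dilate_mask(nm, as.integer(round(nucleus_dilation_px)))
  cyto <- cm & !nm
  if (!any(cyto)) {
    warning("nuclear mask covers the whole cell; cytoplasmic MitoSox is NA",
            call. = FALSE)
    return(NA_real_)
  }
  sum(ms[cyto])
}

#' Extract per-cell mitochondrial features
#'
#' Computes the five-feature readout for every (gated) event pair. TMRM-based
#' features (intensity, total area, spots/form factor) come from the untreated
#' member; TMRM intensity is additionally read from the FCCP member (for the
#' membrane-potential background subtraction and the FCCP response), and NAO
#' intensity is read from the FCCP member to decouple mass from membrane
#' potential. MitoSox is read from the untreated member. Missing values
#' propagate; they are never silently zero-filled.
#'
#' @param events an \code{"ifc_gating"} result, an \code{"ifc_sample"}, or a
#'   plain list of pairs. Events must be consistently paired: a mixture of
#'   paired and unpaired events is an error naming the offending event.
#' @param spot_params \code{\link{spot_mask_params}} for the form-factor spot
#'   mask.
#' @param nucleus_dilation_px margin for the MitoSox nuclear exclusion.
#' @param background_floor optional absolute background floor passed to
#'   \code{\link{spot_mask}}.
#' @return data frame of class \code{"cell_features"}, one row per event:
#'   gating identifiers, TMRM integrated/mean intensity (untreated and FCCP),
#'   TMRM area (µm²), spot count and median spot area/perimeter, per-cell
#'   form factor, NAO intensity (FCCP member), cytoplasmic MitoSox intensity.
#' @export
extract_features <- function(events, spot_params = spot_mask_params(),
                             nucleus_dilation_px = 2,
                             background_floor = NULL) {
  if (inherits(events, "ifc_gating")) events <- events$events
  pairs <- as_event_pairs(events)
  if (length(pairs) == 0L) stop("no events to extract", call. = FALSE)
  has_fccp <- vapply(pairs, function(p) !is.null(p$fccp), logical(1))
  has_untr <- vapply(pairs, function(p) !is.null(p$untreated), logical(1))
  if (!all(has_untr)) {
    bad <- which(!has_untr)[1]
    stop(sprintf("event %d has no untreated member", bad), call. = FALSE)
  }
  if (any(has_fccp) && !all(has_fccp)) {
    bad <- pairs[[which(!has_fccp)[1]]]$untreated$event_id
    stop(sprintf("unpaired treatment conditions: event '%s' lacks its FCCP member",
                 bad), call. = FALSE)
  }
  ## unbounded mask for total area / integrated intensity
  area_params <- spot_mask_params(spot_params$brightness_threshold_pct,
                                  min_area = 0, max_area = 0,
                                  connectivity = spot_params$connectivity)
  rows <- vector("list", length(pairs))
  for (e in seq_along(pairs)) {
    u <- pairs[[e]]$untreated
    f <- pairs[[e]]$fccp
    ps <- u$pixel_size
    cmask <- cell_mask_of(u$channels$brightfield, 0.2)
    full <- spot_mask(u$channels$tmrm, area_params, ps, cmask,
                      background_floor, compute_perimeters = FALSE)
    spots <- spot_mask(u$channels$tmrm, spot_params, ps, cmask,
                       background_floor)
    tm_px <- u$channels$tmrm[full$mask]
    row <- data.frame(
      event_id = u$event_id,
      tmrm_intensity = if (length(tm_px)) sum(tm_px) else NA_real_,
      tmrm_pixel_mean = if (length(tm_px)) mean(tm_px) else NA_real_,
      tmrm_area_um2 = tmrm_area(full),
      n_spots = spots$n_components,
      spot_area_um2 = if (spots$n_components) stats::median(spots$areas_um2)
                      else NA_real_,
      spot_perimeter_um = if (spots$n_components)
        stats::median(spots$perimeters_um) else NA_real_,
      form_factor = form_factor(spots$areas_um2, spots$perimeters_um),
      mitosox_cyto_intensity = cytoplasmic_mitosox(
        u, nucleus_dilation_px = nucleus_dilation_px),
      tmrm_intensity_fccp = NA_real_,
      tmrm_pixel_mean_fccp = NA_real_,
      nao_intensity = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(f)) {
      fmask <- cell_mask_of(f$channels$brightfield, 0.2)
      ffull <- spot_mask(f$channels$tmrm, area_params, f$pixel_size, fmask,
                         background_floor, compute_perimeters = FALSE)
      ftm <- f$channels$tmrm[ffull$mask]
      row$tmrm_intensity_fccp <- if (length(ftm)) sum(ftm) else NA_real_
      row$tmrm_pixel_mean_fccp <- if (length(ftm)) mean(ftm) else NA_real_
      row$nao_intensity <- sum(f$channels$nao[fmask])
    }
    rows[[e]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cell_features", "data.frame")
  out
}
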
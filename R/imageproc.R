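# Image conditioning and segmentation: scan-line flattening, adaptive
# height thresholding, connected components, frame stitching.

#' Height image container
#'
#' @param heights numeric matrix of heights in nm (rows = scan lines).
#' @param pixel_size_nm isotropic pixel size (nm/px), must be > 0.
#' @param origin_nm physical xy offset of the image's (1,1) pixel corner,
#'   used when stitching frames.
#' @param metadata free-form list.
#' @return an object of class `height_image`.
#' @export
height_image <- function(heights, pixel_size_nm, origin_nm = c(0, 0),
                         metadata = list()) {
  heights <- as.matrix(heights)
  if (!is.numeric(heights) || !all(is.finite(heights)))
    stop("'heights' must be a finite numeric matrix")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a single positive number")
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm,
                 origin_nm = as.numeric(origin_nm), metadata = metadata),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("height_image: %d x %d px @ %g nm/px, origin (%g, %g) nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              x$origin_nm[1], x$origin_nm[2]))
  cat(sprintf("  height range [%.3g, %.3g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Flatten an AFM image by per-scan-line background removal
#'
#' Fits a polynomial of order `line_order` to the background (non-molecule)
#' pixels of each scan line and subtracts it; molecules are excluded from the
#' fit by a first-pass robust global threshold so their height does not bleed
#' into the background estimate.  Lines whose background is fully covered by
#' foreground fall back to the global background fit, with a warning.
#' Finally the global background median is removed so the background sits at
#' zero.
#'
#' @param img a [height_image()].
#' @param line_order polynomial order per line: 0 (offset), 1 (tilt) or 2.
#' @param fg_k robust threshold multiplier for the (smoothed) foreground
#'   exclusion mask; 2.5 excludes even the faint backbone from the fits.
#' @return the flattened [height_image()].
#' @export
flatten <- function(img, line_order = 1L, fg_k = 2.5) {
  stopifnot(inherits(img, "height_image"))
  if (!line_order %in% 0:2) stop("'line_order' must be 0, 1 or 2")
  h <- img$heights
  nr <- nrow(h); nc <- ncol(h)
  # provisional all-pixel per-line detrend so scan-line offsets and tilt do
  # not leak into the molecule classification, then a smoothed robust
  # threshold that separates even the 0.3 nm backbone from the noise floor
  xs0 <- seq_len(nc) / nc
  X0 <- outer(xs0, 0:max(line_order, 1L), "^")
  Q0 <- qr(X0)
  prov <- h - t(apply(h, 1, function(row) drop(X0 %*% qr.coef(Q0, row))))
  sm <- gauss_blur(prov, 1)
  fg <- sm > stats::median(sm) + fg_k * max(stats::mad(sm), 0.01)
  xs <- seq_len(nc) / nc  # scaled abscissa for conditioning
  X <- outer(xs, 0:line_order, "^")
  bgv <- as.vector(t(!fg))  # row-major, matching as.vector(t(h))
  colidx <- rep(seq_len(nc), times = nr)
  glob_fit <- stats::lm.fit(X[colidx[bgv], , drop = FALSE],
                            as.vector(t(h))[bgv])$coefficients
  glob_fit[is.na(glob_fit)] <- 0
  warned <- FALSE
  for (i in seq_len(nr)) {
    use <- !fg[i, ]
    if (sum(use) >= (line_order + 2L)) {
      if (line_order == 0L) {
        bgline <- rep(stats::median(h[i, use]), nc)
      } else {
        cf <- stats::lm.fit(X[use, , drop = FALSE], h[i, use])$coefficients
        cf[is.na(cf)] <- 0
        bgline <- drop(X %*% cf)
      }
    } else {
      warned <- TRUE
      bgline <- drop(X %*% glob_fit)
    }
    h[i, ] <- h[i, ] - bgline
  }
  if (warned)
    warning("some scan lines had no background pixels; used global fit")
  h <- h - stats::median(h[!fg])
  img$heights <- h
  img
}

#' Segment molecules by adaptive height thresholding
#'
#' The flattened image is smoothed (Gaussian, `smooth_sigma_px`), a per-tile
#' robust background threshold `median + k * MAD` is computed, and
#' foreground is grown by hysteresis: seed pixels exceed `k_high * MAD`,
#' and connected pixels above `k_low * MAD` are attached to seeds.  A
#' morphological closing of radius `close_px` bridges short gaps along dim
#' backbone stretches; components smaller than `min_area_px` are dropped.
#'
#' @param img a flattened [height_image()].
#' @param min_area_px minimum component area; default corresponds to a
#'   50 bp backbone footprint at the 2.94 bp/nm calibration.
#' @param threshold_cfg list overriding `k_high` (5), `k_low` (2),
#'   `smooth_sigma_px` (1), `tile_px` (128), `close_px` (2, closing radius),
#'   `mad_floor_nm` (0.02, the minimum usable noise scale).
#' @return a `component_mask`: integer label matrix plus per-component area
#'   and bounding box.
#' @export
segment <- function(img, min_area_px = NULL, threshold_cfg = list()) {
  stopifnot(inherits(img, "height_image"))
  cfg <- utils::modifyList(list(k_high = 5, k_low = 2, smooth_sigma_px = 1,
                                tile_px = 128L, close_px = 2L,
                                mad_floor_nm = 0.02), threshold_cfg)
  if (is.null(min_area_px))
    min_area_px <- max(4L, ceiling((50 / 2.94) / img$pixel_size_nm) * 2L)
  h <- gauss_blur(img$heights, cfg$smooth_sigma_px)
  nr <- nrow(h); nc <- ncol(h)
  # per-tile robust background statistics, bilinearly blended is overkill for
  # flattened frames; a per-tile constant surface is adequate and simple
  med <- matrix(0, nr, nc); madv <- matrix(0, nr, nc)
  ti <- ceiling(seq_len(nr) / cfg$tile_px)
  tj <- ceiling(seq_len(nc) / cfg$tile_px)
  for (a in unique(ti)) for (b in unique(tj)) {
    rows <- which(ti == a); cols <- which(tj == b)
    tile <- h[rows, cols]
    med[rows, cols] <- stats::median(tile)
    madv[rows, cols] <- stats::mad(tile)
  }
  # floor the noise estimate at an instrument-scale minimum so noise-free
  # synthetic frames do not degenerate to a ~zero threshold (which would
  # pull the whole smoothing halo into the foreground)
  madv <- pmax(madv, cfg$mad_floor_nm)
  seeds <- h > med + cfg$k_high * madv
  grow <- h > med + cfg$k_low * madv
  if (!any(seeds)) {
    lab <- matrix(0L, nr, nc)
    return(structure(list(labels = lab, n = 0L,
                          areas = integer(0), bboxes = list(),
                          pixel_size_nm = img$pixel_size_nm),
                     class = "component_mask"))
  }
  lab_grow <- label_components(grow)
  keep_ids <- unique(lab_grow[seeds])
  keep_ids <- keep_ids[keep_ids > 0L]
  mask <- matrix(lab_grow %in% keep_ids, nr, nc)
  if (cfg$close_px > 0L) mask <- binary_close(mask, cfg$close_px)
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas < min_area_px)
    if (length(small)) lab[lab %in% small] <- 0L
    # relabel 1..K by decreasing area
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids)) {
      areas <- tabulate(lab[lab > 0L], nbins = max(ids))[ids]
      ord <- ids[order(areas, decreasing = TRUE)]
      relab <- integer(max(ids)); relab[ord] <- seq_along(ord)
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  n <- max(lab)
  areas <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  bboxes <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
      cmin = min(idx[, 2]), cmax = max(idx[, 2]))
  })
  structure(list(labels = lab, n = n, areas = areas, bboxes = bboxes,
                 pixel_size_nm = img$pixel_size_nm),
            class = "component_mask")
}

# Binary closing (dilation then erosion) with a square structuring element
# of radius r px; bridges ridge gaps up to ~2r px.
binary_close <- function(mask, r = 1L) {
  off <- -r:r
  dil <- mask
  for (dr in off) for (dc in off)
    if (dr || dc) dil <- dil | shift_mat(mask, dr, dc, fill = FALSE)
  ero <- dil
  for (dr in off) for (dc in off)
    if (dr || dc) ero <- ero & shift_mat(dil, dr, dc, fill = TRUE)
  # border fill TRUE keeps the frame edge from eroding; restrict to the
  # dilated support so closing cannot leak outside it
  ero & dil
}

#' @export
print.component_mask <- function(x, ...) {
  cat(sprintf("component_mask: %d component(s)", x$n))
  if (x$n > 0) cat(", areas:", paste(x$areas, collapse = ", "), "px")
  cat("\n")
  invisible(x)
}

#' Stitch overlapping frames into a composite image
#'
#' Frames are placed on the union canvas using their `origin_nm` metadata
#' (the known inter-frame displacement); overlapping pixels are averaged.
#'
#' @param frames list of [height_image()]s with identical pixel sizes.
#' @return a composite [height_image()] whose origin is the minimum corner.
#' @export
stitch <- function(frames) {
  if (inherits(frames, "height_image")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames to stitch")
  px <- vapply(frames, function(f) f$pixel_size_nm, numeric(1))
  if (max(px) - min(px) > 1e-9) stop("frames have mismatched pixel sizes")
  px <- px[1]
  x0 <- vapply(frames, function(f) f$origin_nm[1], numeric(1))
  y0 <- vapply(frames, function(f) f$origin_nm[2], numeric(1))
  x1 <- x0 + vapply(frames, function(f) ncol(f$heights), numeric(1)) * px
  y1 <- y0 + vapply(frames, function(f) nrow(f$heights), numeric(1)) * px
  ox <- min(x0); oy <- min(y0)
  nc <- round((max(x1) - ox) / px); nr <- round((max(y1) - oy) / px)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (f in frames) {
    ri <- round((f$origin_nm[2] - oy) / px)
    ci <- round((f$origin_nm[1] - ox) / px)
    rows <- (ri + 1L):(ri + nrow(f$heights))
    cols <- (ci + 1L):(ci + ncol(f$heights))
    acc[rows, cols] <- acc[rows, cols] + f$heights
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  out <- acc / pmax(cnt, 1)
  height_image(out, pixel_size_nm = px, origin_nm = c(ox, oy),
               metadata = list(stitched_from = length(frames)))
}
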
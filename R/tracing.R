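# Backbone tracing: morphological thinning of a segmented component, branch
# pruning to the longest end-to-end geodesic, smoothing-spline contour fit.

# Zhang-Suen 8-connected thinning of a logical mask, vectorized over the
# whole matrix.  Converges quickly on the thin ridges produced by DNA
# backbones (typical width 2-3 px).
thin_mask <- function(mask) {
  m <- mask
  # neighbour order P2..P9 clockwise from north; matrix rows grow downward so
  # "north" is row - 1
  offs <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, o[1], o[2], fill = FALSE))
      B <- Reduce(`+`, nb)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (!nb[[i]] & nb[[j]])
      }
      if (pass == 1) {
        cond <- (!nb[[1]] | !nb[[3]] | !nb[[5]]) & (!nb[[3]] | !nb[[5]] | !nb[[7]])
      } else {
        cond <- (!nb[[1]] | !nb[[3]] | !nb[[7]]) & (!nb[[1]] | !nb[[5]] | !nb[[7]])
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Build an igraph over skeleton pixels (8-connectivity), edge weights equal
# to the physical step length (1 or sqrt(2) pixels).
skeleton_graph <- function(skel, pixel_size_nm) {
  idx <- which(skel)
  nr <- nrow(skel)
  pos <- seq_along(idx)
  lookup <- integer(length(skel)); lookup[idx] <- pos
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  nc <- ncol(skel)
  inb <- function(i, j) i >= 1L & i <= nr & j >= 1L & j <= nc
  at <- function(i, j) {
    v <- logical(length(i)); ok <- inb(i, j)
    v[ok] <- skel[(j[ok] - 1L) * nr + i[ok]]
    v
  }
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- ii + off[1]; nj <- jj + off[2]
    ok <- inb(ni, nj)
    nidx <- (nj - 1L) * nr + ni
    ok[ok] <- skel[nidx[ok]]
    diag_off <- off[1] != 0L && off[2] != 0L
    if (diag_off) {
      # skip diagonal edges bridged by an orthogonal neighbour; this keeps
      # the graph triangle-free so junction/cycle detection is meaningful
      bridged <- at(ii + off[1], jj) | at(ii, jj + off[2])
      ok <- ok & !bridged
    }
    if (any(ok)) {
      from <- c(from, pos[ok]); to <- c(to, lookup[nidx[ok]])
      w <- c(w, rep(sqrt(sum(off^2)) * pixel_size_nm, sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(g = g, row = ii, col = jj)
}

#' Trace the backbone of a segmented component
#'
#' The component mask is thinned to a 1-px skeleton; spurious branches are
#' pruned by keeping the maximum-length geodesic path between skeleton
#' endpoints; line ends retracted by thinning are extended back to the
#' component boundary; the ordered skeleton pixels (in nm) are smoothed by a
#' short moving average and fit with an interpolating parametric cubic
#' spline.  When the source image is supplied, molecule ends are localized
#' sub-pixel at the half-height crossings of the backbone profile and
#' corrected for tip broadening by the measured ridge half-width, and the
#' contour length is the corrected spline arc length.
#'
#' Quality flags: `branched` (skeleton junctions present), `looped`
#' (skeleton contains a cycle), `edge_clipped` (backbone within 2 px of the
#' image border), `too_short` (component below the minimum size; no spline).
#'
#' @param comp a `component_mask` from [segment()].
#' @param comp_id which component to trace (default 1).
#' @param img the [height_image()] the mask came from.
#' @param min_skel_px minimum skeleton size for a measurable trace.
#' @param ma_window_px moving-average window (in half-pixel-spaced samples)
#'   applied to the re-centered backbone before the final interpolating
#'   spline; removes residual jitter without cutting real curvature.
#'   `NULL` (default) selects 3 or 5 from the image noise level.
#' @return a `molecule_trace`.
#' @export
trace_molecule <- function(comp, comp_id = 1L, img = NULL,
                           min_skel_px = 5L, ma_window_px = NULL) {
  stopifnot(inherits(comp, "component_mask"))
  if (comp_id < 1L || comp_id > comp$n) stop("no such component")
  mask <- comp$labels == comp_id
  px <- comp$pixel_size_nm
  if (is.null(ma_window_px)) {
    # smoothing bandwidth matched to the image noise level: quiet images
    # keep more real curvature, noisy ones need the wider window to keep
    # refinement jitter from inflating the arc length
    noise <- if (!is.null(img)) stats::mad(img$heights) else 0.1
    ma_window_px <- if (noise < 0.05) 4L else 5L
  }
  skel <- thin_mask(mask)
  flags <- character(0)
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) < min_skel_px)
    return(new_trace(NULL, NULL, NA_real_, flags = "too_short", px = px))
  sg <- skeleton_graph(skel, px)
  deg <- igraph::degree(sg$g)
  comps <- igraph::components(sg$g)
  main <- which.max(comps$csize)
  in_main <- comps$membership == main
  # looped: a cycle of meaningful size (2-core component > 8 px); tiny
  # 2x2 thinning artifacts are ignored
  core <- which(igraph::coreness(sg$g) >= 2 & in_main)
  if (length(core) > 0L) {
    cc <- igraph::components(igraph::induced_subgraph(sg$g, core))
    if (max(cc$csize) > 8L) flags <- c(flags, "looped")
  }
  ends <- which(deg == 1 & in_main)
  if (length(ends) < 2L) {
    # closed loop or point: no end-to-end path
    flags <- unique(c(flags, "looped"))
    return(new_trace(NULL, NULL, NA_real_, flags = flags, px = px))
  }
  path_v <- longest_end_path(sg, ends)
  # branched: an off-path side branch longer than a spur (> 6 px), after
  # pruning to the longest end-to-end geodesic
  off_path <- setdiff(which(in_main), path_v)
  if (length(off_path) > 0L) {
    oc <- igraph::components(igraph::induced_subgraph(sg$g, off_path))
    if (max(oc$csize) > 6L) flags <- c(flags, "branched")
  }
  bb_px <- cbind(sg$col[path_v], sg$row[path_v])        # (x, y) in pixels
  # endpoint A = lexicographically smaller coordinate
  a <- bb_px[1, ]; b <- bb_px[nrow(bb_px), ]
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2]))
    bb_px <- bb_px[nrow(bb_px):1, , drop = FALSE]
  origin <- if (!is.null(img)) img$origin_nm else c(0, 0)
  bb_nm <- cbind((bb_px[, 1] - 0.5) * px + origin[1],
                 (bb_px[, 2] - 0.5) * px + origin[2])
  nr_img <- nrow(comp$labels); nc_img <- ncol(comp$labels)
  comp_px <- which(mask, arr.ind = TRUE)
  if (any(comp_px[, 1] <= 2 | comp_px[, 1] >= nr_img - 1 |
          comp_px[, 2] <= 2 | comp_px[, 2] >= nc_img - 1))
    flags <- c(flags, "edge_clipped")
  if (nrow(bb_nm) < min_skel_px)
    return(new_trace(bb_nm, NULL, NA_real_, flags = c(flags, "too_short"),
                     px = px))
  spl0 <- fit_backbone_spline(bb_nm, ma_window = ma_window_px)
  if (!is.null(img)) {
    # thinning retracts free line ends; recover them by following the
    # image ridge beyond each end down to half the backbone height
    path_pts <- spline_points(spl0, spacing = px)
    plateau <- stats::median(
      interp_bilinear(img$heights, path_pts[, 1], path_pts[, 2],
                      img$pixel_size_nm, img$origin_nm))
    if (is.finite(plateau) && plateau > 0) {
      extA <- ridge_follow(spl0, img, plateau / 2, from_end = FALSE,
                           px = px, avoid = path_pts)
      extB <- ridge_follow(spl0, img, plateau / 2, from_end = TRUE,
                           px = px, avoid = path_pts)
      pts <- rbind(extA, path_pts, extB)
      spl1 <- fit_backbone_spline(pts, ma_window = 0L)
      # sub-pixel transverse re-centering on the height crest, then a short
      # moving average: recovers real curvature that grid quantization and
      # thinning distort, without inflating arc length with jitter
      pts2 <- spline_points(spl1, spacing = px / 2)
      pts2 <- refine_to_ridge(pts2, img, px)
      spl <- fit_backbone_spline(pts2, ma_window = ma_window_px)
    } else spl <- spl0
  } else spl <- spl0
  L_full <- spline_arclength(spl)
  tr <- new_trace(bb_nm, spl, L_full, flags = flags, px = px)
  if (!is.null(img)) tr <- trim_trace_ends(tr, img)
  tr
}

# Parabolic sub-pixel re-centering of path points onto the height crest
# along the local normal; two passes with the offset capped at 0.6 px.
refine_to_ridge <- function(pts, img, px, iters = 2L, max_shift = 0.6,
                            d_frac = 0.8) {
  if (nrow(pts) < 4L) return(pts)
  for (it in seq_len(iters)) {
    n <- nrow(pts)
    tx <- c(pts[2, 1] - pts[1, 1], pts[3:n, 1] - pts[1:(n - 2), 1],
            pts[n, 1] - pts[n - 1, 1])
    ty <- c(pts[2, 2] - pts[1, 2], pts[3:n, 2] - pts[1:(n - 2), 2],
            pts[n, 2] - pts[n - 1, 2])
    nr <- sqrt(tx^2 + ty^2); nr[nr == 0] <- 1
    nx <- -ty / nr; ny <- tx / nr
    d <- d_frac * px
    h0 <- interp_bilinear(img$heights, pts[, 1], pts[, 2],
                          img$pixel_size_nm, img$origin_nm)
    hm <- interp_bilinear(img$heights, pts[, 1] - nx * d, pts[, 2] - ny * d,
                          img$pixel_size_nm, img$origin_nm)
    hp <- interp_bilinear(img$heights, pts[, 1] + nx * d, pts[, 2] + ny * d,
                          img$pixel_size_nm, img$origin_nm)
    den <- hm - 2 * h0 + hp
    sh <- ifelse(abs(den) > 1e-12, 0.5 * (hm - hp) / den * d, 0)
    sh <- pmin(pmax(sh, -max_shift * px), max_shift * px)
    pts[, 1] <- pts[, 1] + nx * sh
    pts[, 2] <- pts[, 2] + ny * sh
  }
  pts
}

# Sample the spline at roughly regular parameter spacing.
spline_points <- function(spl, spacing = 1) {
  t0 <- spl$t_range[1]; t1 <- spl$t_range[2]
  tt <- seq(t0, t1, length.out = max(8L, ceiling((t1 - t0) / spacing) + 1L))
  spline_xy(spl, tt)
}

# Follow the height ridge beyond a backbone end: step outward along the
# current direction, re-centre laterally on the crest, stop when the crest
# height falls below `h_stop` or after `max_nm` of extension.  Handles ends
# that curve away from the straight tangent.
ridge_follow <- function(spl, img, h_stop, from_end, px,
                         step_nm = 1, max_nm = 20, avoid = NULL) {
  t_end <- if (from_end) spl$t_range[2] else spl$t_range[1]
  p <- drop(spline_xy(spl, t_end))
  if (!is.null(avoid)) {
    # points of the existing backbone away from this end; stepping onto
    # them means the follower u-turned back along the molecule
    d_end <- sqrt((avoid[, 1] - p[1])^2 + (avoid[, 2] - p[2])^2)
    avoid <- avoid[d_end > 2.5 * px, , drop = FALSE]
  }
  u0 <- NULL
  u <- c(spl$fx(t_end, deriv = 1), spl$fy(t_end, deriv = 1))
  if (!from_end) u <- -u
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(NULL)
  u <- u / nu
  offs <- seq(-1.2 * px, 1.2 * px, by = px / 5)
  pts <- NULL
  for (k in seq_len(ceiling(max_nm / step_nm))) {
    cand <- p + u * step_nm
    nv <- c(-u[2], u[1])
    hh <- interp_bilinear(img$heights, cand[1] + nv[1] * offs,
                          cand[2] + nv[2] * offs, img$pixel_size_nm,
                          img$origin_nm)
    b <- which.max(hh)
    cand <- cand + nv * offs[b]
    below <- hh[b] < h_stop
    if (!is.null(avoid) && nrow(avoid) > 0) {
      if (min((avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2) <
          (1.5 * px)^2) break
    }
    u2 <- cand - p
    nu2 <- sqrt(sum(u2^2))
    if (nu2 < 1e-9) break
    u <- u2 / nu2
    if (is.null(u0)) u0 <- u
    # an extension that has turned back past ~110 degrees is re-tracing
    # the molecule, not its end
    if (sum(u * u0) < cos(110 * pi / 180)) break
    p <- cand
    pts <- rbind(pts, p)
    # keep one point past the half-height crossing so the sub-pixel end
    # localization can bracket it, then stop
    if (below) break
  }
  if (is.null(pts)) return(NULL)
  if (from_end) pts else pts[nrow(pts):1, , drop = FALSE]
}

# Sub-pixel end localization.  The apparent height of a pixel near the
# backbone is a fixed function T(d) of its distance d to the backbone curve
# (DNA cross-section convolved with the tip); beyond a molecule end the same
# T applies with d measured to the truncated curve.  T is estimated
# super-resolved from the phase diversity of raw pixels along the molecule
# interior, then each end position is fit by sliding the truncation point to
# best explain the raw pixels around that end.  Falls back to a half-height
# crossing corrected by the measured ridge half-width when the template fit
# is not possible (very short or low-contrast molecules).
trim_trace_ends <- function(trace, img, step_nm = 0.25) {
  spl <- trace$spline
  par <- spline_arc_param(spl)
  L_full <- max(par$s)
  if (!is.finite(L_full) || L_full < 20 * step_nm) return(trace)
  s <- seq(0, L_full, by = step_nm)
  tt <- par$t_of_s(s)
  xy <- spline_xy(spl, tt)
  h <- interp_bilinear(img$heights, xy[, 1], xy[, 2], img$pixel_size_nm,
                       img$origin_nm)
  plateau <- stats::median(h)
  if (!is.finite(plateau) || plateau <= 0) return(trace)
  half <- plateau / 2
  above <- which(h >= half)
  if (length(above) < 8L) return(trace)
  i0 <- above[1]; i1 <- above[length(above)]
  cross_at <- function(i_out, i_in) {
    if (i_out < 1 || i_out > length(h) || h[i_in] == h[i_out]) return(s[i_in])
    s[i_out] + (half - h[i_out]) / (h[i_in] - h[i_out]) * (s[i_in] - s[i_out])
  }
  s_low <- if (i0 > 1) cross_at(i0 - 1L, i0) else s[i0]
  s_high <- if (i1 < length(h)) cross_at(i1 + 1L, i1) else s[i1]
  tmpl <- profile_template(trace, img, par, s_low, s_high, plateau)
  ok_template <- !is.null(tmpl) && (s_high - s_low) > 40
  if (ok_template) {
    eA <- fit_end_position(trace, img, par, tmpl, s_low, from_end = FALSE)
    eB <- fit_end_position(trace, img, par, tmpl, s_high, from_end = TRUE)
  } else {
    eA <- eB <- NA_real_
  }
  if (!is.finite(eA) || !is.finite(eB)) {
    w_half <- ridge_half_width(trace, img, par, s_low, s_high, half)
    eA <- s_low + w_half
    eB <- s_high - w_half
  }
  L <- eB - eA
  if (!is.finite(L) || L <= 0) return(trace)
  trace$trim <- c(eA, eB)
  trace$contour_length_nm <- L
  trace
}

# Super-resolved cross-section template T(d): raw pixel heights binned by
# their exact distance to the backbone, using interior anchor points only
# (away from ends and labels).  The local backbone is replaced by its
# straight-line fit so lateral spline jitter does not blur the template;
# anchors where the backbone bends appreciably are skipped.  Returns an
# interpolating function or NULL when too few clean pixels are available.
profile_template <- function(trace, img, par, s_low, s_high, plateau,
                             reach_nm = 8, n_anchor = 120L) {
  px <- img$pixel_size_nm
  lo <- s_low + 6; hi <- s_high - 6
  if (hi - lo < 20) return(NULL)
  anchors <- seq(lo, hi, length.out = max(4L, min(n_anchor,
                                                  floor((hi - lo) / 2))))
  d_all <- numeric(0); h_all <- numeric(0)
  nr <- nrow(img$heights); nc <- ncol(img$heights)
  seen <- integer(0)
  r_px <- ceiling(reach_nm / px)
  for (a in anchors) {
    seg_s <- seq(max(0, a - reach_nm - 4), min(max(par$s), a + reach_nm + 4),
                 by = 0.5)
    seg <- spline_xy(trace$spline, par$t_of_s(seg_s))
    ctr <- colMeans(seg)
    sc <- sweep(seg, 2, ctr)
    sv <- svd(sc, nu = 0, nv = 2)
    u <- sv$v[, 1]                       # local axis direction
    perp_res <- sc %*% sv$v[, 2]
    if (max(abs(perp_res)) > 0.5) next   # bent stretch: skip
    p <- spline_xy(trace$spline, par$t_of_s(a))
    ic <- round((p[2] - img$origin_nm[2]) / px + 0.5)
    jc <- round((p[1] - img$origin_nm[1]) / px + 0.5)
    rows <- max(1L, ic - r_px):min(nr, ic + r_px)
    cols <- max(1L, jc - r_px):min(nc, jc + r_px)
    idx <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
    idx <- setdiff(idx, seen)
    if (!length(idx)) next
    seen <- c(seen, idx)
    pi_ <- ((idx - 1L) %% nr) + 1L
    pj_ <- ((idx - 1L) %/% nr) + 1L
    rel <- cbind((pj_ - 0.5) * px + img$origin_nm[1] - ctr[1],
                 (pi_ - 0.5) * px + img$origin_nm[2] - ctr[2])
    d <- abs(rel[, 1] * (-u[2]) + rel[, 2] * u[1])
    hh <- img$heights[idx]
    use <- d <= reach_nm & hh < plateau * 2   # exclude label pixels
    d_all <- c(d_all, d[use]); h_all <- c(h_all, hh[use])
  }
  if (length(d_all) < 60) return(NULL)
  br <- seq(0, reach_nm, by = 0.25)
  mids <- (br[-1] + br[-length(br)]) / 2
  bin <- cut(d_all, br, labels = FALSE)
  med <- vapply(seq_along(mids), function(b) {
    v <- h_all[which(bin == b)]
    if (length(v) >= 2) stats::median(v) else NA_real_
  }, numeric(1))
  okb <- is.finite(med)
  if (sum(okb) < 8) return(NULL)
  stats::approxfun(mids[okb], med[okb], rule = 2)
}

# Slide the end truncation point along the local end axis to best explain
# the raw pixels around one end with the template; grid search at 0.1 nm
# over +/- 3 nm about the half-height crossing estimate.  The end region is
# modelled as a ray (straight at this scale), so the fit is not disturbed
# by lateral spline jitter.
fit_end_position <- function(trace, img, par, tmpl, s_cross, from_end,
                             reach_nm = 7) {
  px <- img$pixel_size_nm
  s_in <- if (from_end) seq(s_cross - 12, s_cross, by = 0.5)
          else seq(s_cross, s_cross + 12, by = 0.5)
  s_in <- s_in[s_in >= 0 & s_in <= max(par$s)]
  if (length(s_in) < 8) return(NA_real_)
  seg <- spline_xy(trace$spline, par$t_of_s(s_in))
  ctr <- colMeans(seg)
  sc <- sweep(seg, 2, ctr)
  sv <- svd(sc, nu = 0, nv = 2)
  if (max(abs(sc %*% sv$v[, 2])) > 0.6)   # bent end: fit against the curve
    return(fit_end_position_curve(trace, img, par, tmpl, s_cross, from_end,
                                  reach_nm))
  u <- sv$v[, 1]
  # orient u to point outward (from molecule interior toward the end)
  p_cross <- spline_xy(trace$spline, par$t_of_s(s_cross))
  if (sum((p_cross - ctr) * u) < 0) u <- -u
  p0 <- drop(p_cross)
  nr <- nrow(img$heights); nc <- ncol(img$heights)
  r_px <- ceiling((reach_nm + 3) / px)
  ic <- round((p0[2] - img$origin_nm[2]) / px + 0.5)
  jc <- round((p0[1] - img$origin_nm[1]) / px + 0.5)
  rows <- max(1L, ic - r_px):min(nr, ic + r_px)
  cols <- max(1L, jc - r_px):min(nc, jc + r_px)
  idx <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
  pi_ <- ((idx - 1L) %% nr) + 1L
  pj_ <- ((idx - 1L) %/% nr) + 1L
  relx <- (pj_ - 0.5) * px + img$origin_nm[1] - p0[1]
  rely <- (pi_ - 0.5) * px + img$origin_nm[2] - p0[2]
  ax <- relx * u[1] + rely * u[2]        # axial, positive beyond s_cross
  pp <- abs(relx * (-u[2]) + rely * u[1])
  hh <- img$heights[idx]
  keep <- abs(ax) <= reach_nm & pp <= reach_nm
  ax <- ax[keep]; pp <- pp[keep]; hh <- hh[keep]
  if (length(ax) < 10) return(NA_real_)
  cand <- seq(-3, 3, by = 0.1)           # candidate end, axial offset
  sse <- vapply(cand, function(a0) {
    beyond <- pmax(ax - a0, 0)           # axial distance past the end
    d <- sqrt(beyond^2 + pp^2)
    sum((hh - tmpl(d))^2)
  }, numeric(1))
  b <- which.min(sse)
  a_hat <- cand[b]
  if (b > 1 && b < length(cand)) {
    den <- sse[b - 1] - 2 * sse[b] + sse[b + 1]
    if (is.finite(den) && den > 0)
      a_hat <- cand[b] + 0.5 * (sse[b - 1] - sse[b + 1]) / den * 0.1
  }
  if (from_end) s_cross + a_hat else s_cross - a_hat
}

# Template end fit for bent ends: slide the truncation point along the
# spline itself and measure pixel distances to the truncated curve.  Slower
# and slightly jitter-biased compared with the ray fit, but far better than
# a half-height fallback when the molecule end curls.
fit_end_position_curve <- function(trace, img, par, tmpl, s_cross, from_end,
                                   reach_nm = 7) {
  px <- img$pixel_size_nm
  p0 <- drop(spline_xy(trace$spline, par$t_of_s(s_cross)))
  nr <- nrow(img$heights); nc <- ncol(img$heights)
  r_px <- ceiling((reach_nm + 3) / px)
  ic <- round((p0[2] - img$origin_nm[2]) / px + 0.5)
  jc <- round((p0[1] - img$origin_nm[1]) / px + 0.5)
  rows <- max(1L, ic - r_px):min(nr, ic + r_px)
  cols <- max(1L, jc - r_px):min(nc, jc + r_px)
  idx <- as.vector(outer(rows, (cols - 1L) * nr, "+"))
  pi_ <- ((idx - 1L) %% nr) + 1L
  pj_ <- ((idx - 1L) %/% nr) + 1L
  pxx <- (pj_ - 0.5) * px + img$origin_nm[1]
  pyy <- (pi_ - 0.5) * px + img$origin_nm[2]
  hh <- img$heights[idx]
  near <- (pxx - p0[1])^2 + (pyy - p0[2])^2 <= reach_nm^2 * 2
  if (sum(near) < 10) return(NA_real_)
  pxx <- pxx[near]; pyy <- pyy[near]; hh <- hh[near]
  s_sup <- seq(max(0, s_cross - 16), min(max(par$s), s_cross + 16), by = 0.25)
  sup <- spline_xy(trace$spline, par$t_of_s(s_sup))
  cand <- seq(s_cross - 3, s_cross + 3, by = 0.2)
  sse <- vapply(cand, function(se) {
    keep <- if (from_end) s_sup <= se else s_sup >= se
    if (sum(keep) < 8) return(Inf)
    seg <- sup[keep, , drop = FALSE]
    d <- vapply(seq_along(pxx), function(k)
      sqrt(min((seg[, 1] - pxx[k])^2 + (seg[, 2] - pyy[k])^2)), numeric(1))
    sum((hh - tmpl(d))^2)
  }, numeric(1))
  b <- which.min(sse)
  if (!is.finite(sse[b])) return(NA_real_)
  a_hat <- cand[b]
  if (b > 1 && b < length(cand) && is.finite(sse[b - 1]) &&
      is.finite(sse[b + 1])) {
    den <- sse[b - 1] - 2 * sse[b] + sse[b + 1]
    if (den > 0) a_hat <- cand[b] + 0.5 * (sse[b - 1] - sse[b + 1]) / den * 0.2
  }
  a_hat
}

# Median half-width at half height of the backbone cross-section, sampled
# along normals at interior arc positions (labels are rare enough along the
# profile that the median is unaffected).
ridge_half_width <- function(trace, img, par, s_low, s_high, half,
                             n_sections = 15L, reach_nm = 8, step_nm = 0.25) {
  qs <- s_low + (s_high - s_low) * seq(0.2, 0.8, length.out = n_sections)
  tt <- par$t_of_s(qs)
  xy <- spline_xy(trace$spline, tt)
  dx <- trace$spline$fx(tt, deriv = 1); dy <- trace$spline$fy(tt, deriv = 1)
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  ux <- -dy / nrm; uy <- dx / nrm
  offs <- seq(-reach_nm, reach_nm, by = step_nm)
  widths <- vapply(seq_along(qs), function(k) {
    hh <- interp_bilinear(img$heights, xy[k, 1] + ux[k] * offs,
                          xy[k, 2] + uy[k] * offs, img$pixel_size_nm,
                          img$origin_nm)
    ctr <- which.min(abs(offs))
    if (hh[ctr] < half) return(NA_real_)
    l <- ctr; while (l > 1 && hh[l - 1] >= half) l <- l - 1
    r <- ctr; while (r < length(offs) && hh[r + 1] >= half) r <- r + 1
    (offs[r] - offs[l]) / 2
  }, numeric(1))
  w <- stats::median(widths, na.rm = TRUE)
  if (!is.finite(w)) 0 else w
}

new_trace <- function(backbone, spline, contour, flags, px) {
  ep <- if (!is.null(backbone) && nrow(backbone) >= 2)
    list(A = backbone[1, ], B = backbone[nrow(backbone), ]) else NULL
  structure(list(backbone = backbone, spline = spline,
                 contour_length_nm = contour, endpoints = ep,
                 flags = flags, pixel_size_nm = px),
            class = "molecule_trace")
}

#' @export
print.molecule_trace <- function(x, ...) {
  cat(sprintf("molecule_trace: contour %.1f nm, %d backbone px%s\n",
              x$contour_length_nm,
              if (is.null(x$backbone)) 0L else nrow(x$backbone),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

# Maximum-geodesic end-to-end path.  On (near-)tree skeletons the weighted
# shortest path between the farthest endpoint pair is the longest end-to-end
# backbone; ties (< 1 px) are broken by smaller mean curvature, then by
# lexicographic endpoint coordinates for determinism.
longest_end_path <- function(sg, ends) {
  d <- igraph::distances(sg$g, v = ends, to = ends)
  d[!is.finite(d)] <- -Inf
  best <- max(d)
  cand <- which(d >= best - 1 * min(igraph::E(sg$g)$weight) &
                  is.finite(d), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) == 0) cand <- which(d == best, arr.ind = TRUE)[1, , drop = FALSE]
  paths <- lapply(seq_len(nrow(cand)), function(k) {
    igraph::shortest_paths(sg$g, from = ends[cand[k, 1]],
                           to = ends[cand[k, 2]], output = "vpath"
    )$vpath[[1]]
  })
  if (length(paths) == 1L) return(as.integer(paths[[1]]))
  score <- vapply(seq_along(paths), function(k) {
    v <- as.integer(paths[[k]])
    xy <- cbind(sg$col[v], sg$row[v])
    mean_curvature(xy)
  }, numeric(1))
  lens <- vapply(seq_along(paths), function(k) d[cand[k, 1], cand[k, 2]],
                 numeric(1))
  # prefer longer; among near-ties prefer smaller curvature, then lexicographic
  ord <- order(-lens, score, vapply(paths, function(p) {
    v <- as.integer(p); min(sg$col[v[1]], sg$col[v[length(v)]])
  }, numeric(1)))
  as.integer(paths[[ord[1]]])
}

mean_curvature <- function(xy) {
  if (nrow(xy) < 3) return(0)
  v <- diff(xy)
  a <- atan2(v[, 2], v[, 1])
  da <- diff(a)
  da <- atan2(sin(da), cos(da))
  mean(abs(da))
}

# Parametric cubic spline x(t), y(t) with t = cumulative chord length,
# through the ordered backbone pixels after a short centered moving average.
# Averaging over ~3 px removes the pixel staircase (quantization s.d.
# px/sqrt(12)) with negligible shortening of real curvature at the
# persistence lengths of deposited DNA; a smoothing spline with
# RMS-targeted stiffness was tried first and systematically cut corners on
# wiggly molecules.
fit_backbone_spline <- function(bb_nm, ma_window = 3L) {
  n <- nrow(bb_nm)
  ma_window <- as.integer(ma_window)
  if (ma_window >= 2L && n >= ma_window + 2L) {
    k <- rep(1 / ma_window, ma_window)
    xs <- stats::filter(bb_nm[, 1], k, sides = 2)
    ys <- stats::filter(bb_nm[, 2], k, sides = 2)
    ok <- !is.na(xs)
    sm <- bb_nm
    sm[ok, 1] <- xs[ok]; sm[ok, 2] <- ys[ok]
    bb_nm <- sm
  }
  # drop near-duplicate points so chord steps stay positive
  keep <- c(TRUE, sqrt(diff(bb_nm[, 1])^2 + diff(bb_nm[, 2])^2) > 1e-6)
  bb_nm <- bb_nm[keep, , drop = FALSE]
  t <- path_arclength(bb_nm)
  fx <- stats::splinefun(t, bb_nm[, 1], method = "natural")
  fy <- stats::splinefun(t, bb_nm[, 2], method = "natural")
  structure(list(fx = fx, fy = fy, t_range = range(t), type = "interp"),
            class = "backbone_spline")
}

# Evaluate spline point(s) at parameter values.
spline_xy <- function(spl, tt) {
  if (spl$type == "interp")
    cbind(spl$fx(tt), spl$fy(tt))
  else
    cbind(spl$fx(tt), spl$fy(tt))
}

# Arc length of the fitted spline by composite Simpson quadrature on the
# speed |r'(t)|; the parameter grid is refined to ~0.25 nm so the value is
# stable to re-parameterization well below 0.01%.
spline_arclength <- function(spl, upto = NULL) {
  t0 <- spl$t_range[1]; t1 <- upto %||% spl$t_range[2]
  n <- max(64L, 2L * ceiling((t1 - t0) / 0.5))  # even panel count
  tt <- seq(t0, t1, length.out = n + 1L)
  if (spl$type == "interp") {
    dx <- spl$fx(tt, deriv = 1); dy <- spl$fy(tt, deriv = 1)
  } else {
    dx <- spl$fx(tt, deriv = 1); dy <- spl$fy(tt, deriv = 1)
  }
  sp <- sqrt(dx^2 + dy^2)
  hh <- (t1 - t0) / n
  w <- rep(c(4, 2), length.out = n - 1L)
  (hh / 3) * (sp[1] + sp[n + 1L] + sum(w * sp[2:n]))
}

# Cumulative arc length s(t) on a dense grid; returns interpolators both ways.
spline_arc_param <- function(spl) {
  t0 <- spl$t_range[1]; t1 <- spl$t_range[2]
  n <- max(128L, 2L * ceiling((t1 - t0) / 0.5))
  tt <- seq(t0, t1, length.out = n + 1L)
  dx <- spl$fx(tt, deriv = 1); dy <- spl$fy(tt, deriv = 1)
  sp <- sqrt(dx^2 + dy^2)
  # trapezoid cumulative integral
  s <- c(0, cumsum((sp[-1] + sp[-(n + 1L)]) / 2 * diff(tt)))
  list(t = tt, s = s,
       t_of_s = stats::approxfun(s, tt, rule = 2),
       s_of_t = stats::approxfun(tt, s, rule = 2))
}

#' Contour length of a traced molecule
#'
#' Arc length of the fitted backbone spline by adaptive-order quadrature.
#'
#' @param trace a `molecule_trace` from [trace_molecule()].
#' @return contour length in nm.
#' @export
contour_length <- function(trace) {
  stopifnot(inherits(trace, "molecule_trace"))
  if ("too_short" %in% trace$flags || is.null(trace$spline))
    stop("trace is too short to measure")
  spline_arclength(trace$spline)
}

#' Quality flags of a trace
#'
#' Returns the automated exclusion flags; molecules with any flag are
#' excluded from label calling by default, standing in for the manual
#' curation of automation errors.
#'
#' @param trace a `molecule_trace`.
#' @return character vector of flags (empty when the molecule is clean).
#' @export
quality_flags <- function(trace) {
  stopifnot(inherits(trace, "molecule_trace"))
  trace$flags
}
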
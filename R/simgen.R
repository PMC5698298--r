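# Synthetic HS-AFM frame generator: worm-like-chain DNA conformations,
# Cas9 label bumps, tip dilation, scan-line offsets and pixel noise.
# Every downstream stage is validated against the ground truth produced here.

#' Simulation configuration
#'
#' Bundles the physical and instrument parameters of the synthetic frame
#' generator. Defaults reflect typical HS-AFM imaging of Cas9-labeled DNA on
#' mica: a 0.3 nm apparent backbone height, 3 nm tall Cas9 particles,
#' 2.5 nm pixels and the canonical solution calibration of 2.94 bp/nm.
#'
#' @param bp_per_nm calibration, base pairs per nanometer of contour (2.94).
#' @param persistence_length_nm worm-like-chain persistence length (nm).
#' @param pixel_size_nm isotropic pixel size (nm/px).
#' @param frame_size_px integer pair, frame size as c(columns, rows).
#' @param tip_radius_nm AFM tip radius for the spherical-cap dilation model.
#' @param dna_height_nm apparent height of the bare DNA backbone.
#' @param dna_radius_nm lateral half-width of the backbone cylinder (nm);
#'   with the tip model this sets the rendered ridge width.
#' @param label_height_nm apparent height of a bound Cas9 particle.
#' @param label_footprint_nm full width at half maximum of a label bump
#'   before tip dilation.
#' @param noise_sd_nm per-pixel additive Gaussian height noise s.d.
#' @param line_offset_sd_nm per-scan-line additive offset s.d. (fast-scan
#'   line registration error).
#' @param labeling_efficiency Bernoulli occupancy probability of a perfect
#'   protospacer match site (~0.9 under standard conditions).
#' @param mismatch_efficiency occupancy probability of a single-mismatch site
#'   (~0.5).
#' @param off_target_rate expected number of off-target labels per molecule
#'   (Poisson); positions uniform along the molecule.
#' @param wlc_convention `"2d"` (tangent correlation `exp(-s / (2 lp))`, the
#'   convention for chains equilibrated on a surface) or `"3d"`
#'   (`exp(-s / lp)`).
#' @param align_corr_nm optional flow-alignment correlation length (nm).
#'   `NULL` (default) samples free 2D worm-like chains.  A finite value
#'   adds a mean-reverting pull of the tangent toward the deposition flow
#'   direction, emulating the flow-elongation protocol used to deposit
#'   molecules much longer than a few persistence lengths; without it long
#'   chains almost surely self-cross and would be rejected by tracing.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(bp_per_nm = 2.94,
                       persistence_length_nm = 50,
                       pixel_size_nm = 2.5,
                       frame_size_px = c(400L, 400L),
                       tip_radius_nm = 5,
                       dna_height_nm = 0.3,
                       dna_radius_nm = 1,
                       label_height_nm = 3,
                       label_footprint_nm = 10,
                       noise_sd_nm = 0.1,
                       line_offset_sd_nm = 0.1,
                       labeling_efficiency = 0.9,
                       mismatch_efficiency = 0.5,
                       off_target_rate = 0,
                       wlc_convention = c("2d", "3d"),
                       align_corr_nm = NULL,
                       seed = 1L) {
  wlc_convention <- match.arg(wlc_convention)
  cfg <- list(bp_per_nm = bp_per_nm,
              persistence_length_nm = persistence_length_nm,
              pixel_size_nm = pixel_size_nm,
              frame_size_px = as.integer(frame_size_px),
              tip_radius_nm = tip_radius_nm,
              dna_height_nm = dna_height_nm,
              dna_radius_nm = dna_radius_nm,
              label_height_nm = label_height_nm,
              label_footprint_nm = label_footprint_nm,
              noise_sd_nm = noise_sd_nm,
              line_offset_sd_nm = line_offset_sd_nm,
              labeling_efficiency = labeling_efficiency,
              mismatch_efficiency = mismatch_efficiency,
              off_target_rate = off_target_rate,
              wlc_convention = wlc_convention,
              align_corr_nm = align_corr_nm,
              seed = as.integer(seed))
  for (f in c("bp_per_nm", "persistence_length_nm", "pixel_size_nm",
              "tip_radius_nm", "dna_height_nm", "dna_radius_nm",
              "label_height_nm",
              "label_footprint_nm"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("'%s' must be a single positive number", f))
  for (f in c("noise_sd_nm", "line_offset_sd_nm", "off_target_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("'%s' must be non-negative", f))
  for (f in c("labeling_efficiency", "mismatch_efficiency"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", f))
  if (length(cfg$frame_size_px) != 2L || any(cfg$frame_size_px < 8L))
    stop("'frame_size_px' must be two integers >= 8")
  if (!is.null(align_corr_nm) && (!is.numeric(align_corr_nm) || align_corr_nm <= 0))
    stop("'align_corr_nm' must be NULL or a positive length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%g bp/nm, lp %g nm, px %g nm, frame %dx%d px",
              x$bp_per_nm, x$persistence_length_nm, x$pixel_size_nm,
              x$frame_size_px[1], x$frame_size_px[2]), "\n")
  cat(sprintf("  heights: DNA %g nm, label %g nm; tip %g nm; noise %g nm\n",
              x$dna_height_nm, x$label_height_nm, x$tip_radius_nm,
              x$noise_sd_nm))
  invisible(x)
}

#' Sample a 2D worm-like-chain conformation
#'
#' Generates a discrete worm-like chain in the plane: tangent angle performs a
#' Gaussian random walk with per-step variance `step / lp` (the `"2d"`
#' convention, giving tangent-tangent correlation `exp(-s / (2 lp))`) or
#' `2 * step / lp` (`"3d"` convention, `exp(-s / lp)`).  With
#' `cfg$align_corr_nm` set, the tangent angle is additionally mean-reverted
#' toward the flow axis with that correlation length, which keeps long chains
#' extended the way the flow-elongation deposition does.
#'
#' The total arc length is exactly `length_bp / bp_per_nm` (the final step is
#' shortened as needed).
#'
#' @param length_bp molecule length in base pairs (>= 1).
#' @param cfg a [sim_config()].
#' @param step_nm discretization step; must not exceed the pixel size.
#' @return an n x 2 matrix of xy coordinates (nm), starting at the origin.
#' @export
sample_wlc_chain <- function(length_bp, cfg = sim_config(), step_nm = 1) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1)
    stop("'length_bp' must be a positive number of base pairs (>= 1)")
  if (step_nm > cfg$pixel_size_nm)
    stop("'step_nm' must not exceed the pixel size")
  L <- length_bp / cfg$bp_per_nm
  n <- max(1L, ceiling(L / step_nm))
  ds <- rep(step_nm, n)
  ds[n] <- L - step_nm * (n - 1)   # exact arc length
  var_fac <- if (cfg$wlc_convention == "2d") 1 else 2
  sd_bend <- sqrt(var_fac * ds / cfg$persistence_length_nm)
  dtheta <- stats::rnorm(n, 0, sd_bend)
  if (is.null(cfg$align_corr_nm)) {
    theta0 <- stats::runif(1, 0, 2 * pi)
    theta <- theta0 + cumsum(dtheta) - dtheta[1]  # theta[1] = initial heading
  } else {
    # Ornstein-Uhlenbeck tangent angle about the flow axis
    gamma <- pmin(1, ds / cfg$align_corr_nm)
    theta <- numeric(n)
    th <- 0
    for (i in seq_len(n)) {
      theta[i] <- th
      th <- th * (1 - gamma[i]) + dtheta[i]
    }
  }
  x <- cumsum(ds * cos(theta))
  y <- cumsum(ds * sin(theta))
  rbind(c(0, 0), cbind(x, y))
}

#' Construct a simulated molecule
#'
#' @param id molecule identifier.
#' @param length_bp length in base pairs.
#' @param cfg a [sim_config()].
#' @param path optional precomputed backbone path; when omitted, sampled
#'   with [sample_wlc_chain()] and rejection-sampled to be self-avoiding at
#'   the pixel scale (adsorbed strands cannot overlap on the surface, and
#'   sub-pixel near-contacts are unresolvable by construction).
#' @param max_tries rejection-sampling budget for a self-avoiding path.
#' @return a `sim_molecule`: id, length_bp, path (nm), and an empty
#'   `truth_labels` table.
#' @export
sim_molecule <- function(id, length_bp, cfg = sim_config(), path = NULL,
                         max_tries = 200L) {
  if (is.null(path)) {
    # adsorbed molecules are self-avoiding on the surface, and stretches
    # closer than the tip-broadened footprint plus one pixel are not
    # resolvable as separate ridges; resample until the conformation is
    # imageable
    gap <- min_resolvable_gap(cfg)
    for (k in seq_len(max_tries)) {
      path <- sample_wlc_chain(length_bp, cfg)
      if (!path_self_proximal(path, gap)) break
      if (k == max_tries)
        warning("no self-avoiding conformation found in ", max_tries,
                " tries; using the last draw")
    }
  }
  structure(list(id = id, length_bp = length_bp, path = path,
                 truth_labels = data.frame(pos_bp = numeric(0),
                                           kind = character(0),
                                           bound = logical(0))),
            class = "sim_molecule")
}

#' Apply Cas9 labels to a simulated molecule
#'
#' Site occupancy is Bernoulli: perfect protospacer matches bind with
#' probability `labeling_efficiency`, single-mismatch sites with
#' `mismatch_efficiency`.  Off-target labels are added with a Poisson count
#' of mean `off_target_rate` at uniform positions.
#'
#' @param mol a [sim_molecule()].
#' @param map a [reference_map()] of the same length.
#' @param cfg a [sim_config()].
#' @return the molecule with `truth_labels` populated (one row per site plus
#'   any off-targets; `bound` records occupancy).
#' @export
apply_labels <- function(mol, map, cfg = sim_config()) {
  stopifnot(inherits(mol, "sim_molecule"))
  if (map$length_bp != mol$length_bp)
    stop(sprintf("map length (%d bp) does not match molecule length (%d bp)",
                 map$length_bp, mol$length_bp))
  sites <- map$sites
  p <- ifelse(sites$match_type == "perfect",
              cfg$labeling_efficiency, cfg$mismatch_efficiency)
  bound <- stats::runif(nrow(sites)) < p
  lab <- data.frame(pos_bp = sites$pos_bp,
                    kind = sites$match_type,
                    bound = bound,
                    stringsAsFactors = FALSE)
  n_off <- stats::rpois(1, cfg$off_target_rate)
  if (n_off > 0) {
    lab <- rbind(lab, data.frame(pos_bp = stats::runif(n_off, 1, mol$length_bp),
                                 kind = "off_target", bound = TRUE))
  }
  mol$truth_labels <- lab[order(lab$pos_bp), , drop = FALSE]
  rownames(mol$truth_labels) <- NULL
  mol
}

# Spherical-cap grayscale dilation: the image a spherical tip of radius R
# records over a surface h is max_u [ h(u) + sqrt(R^2 - d^2) - R ].
tip_dilate <- function(heights, tip_radius_nm, pixel_size_nm) {
  r_px <- floor(tip_radius_nm / pixel_size_nm)
  if (r_px < 1L) return(heights)
  out <- heights
  for (dr in -r_px:r_px) for (dc in -r_px:r_px) {
    if (dr == 0 && dc == 0) next
    d <- sqrt(dr^2 + dc^2) * pixel_size_nm
    if (d > tip_radius_nm) next
    cap <- sqrt(tip_radius_nm^2 - d^2) - tip_radius_nm
    out <- pmax(out, shift_mat(heights, dr, dc, fill = -Inf) + cap)
  }
  out
}

# Tip-contact rendering of the bare backbone: the DNA is a cylinder of
# height dna_height_nm and lateral half-width dna_radius_nm; a spherical tip
# of radius R touching the surface at perpendicular distance d from the axis
# records height dna_height + sqrt(R^2 - max(0, d - r0)^2) - R (clipped at
# zero).  This reproduces the finite apparent width of DNA on-pixel without
# a separate grid dilation of the backbone.
rasterize_backbone <- function(heights, path, cfg) {
  px <- cfg$pixel_size_nm
  R <- cfg$tip_radius_nm; r0 <- cfg$dna_radius_nm; hD <- cfg$dna_height_nm
  reach <- sqrt(max(R^2 - (R - min(hD, R))^2, 0)) + r0
  dense <- resample_path(path, min(0.5, px / 3))
  nr <- nrow(heights); nc <- ncol(heights)
  ic <- round(dense[, 2] / px + 0.5); jc <- round(dense[, 1] / px + 0.5)
  rpx <- as.integer(ceiling(reach / px)) + 1L
  mind <- matrix(Inf, nr, nc)
  for (dr in -rpx:rpx) for (dc in -rpx:rpx) {
    i <- ic + dr; j <- jc + dc
    ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
    if (!any(ok)) next
    cx <- (j[ok] - 0.5) * px; cy <- (i[ok] - 0.5) * px
    d <- sqrt((cx - dense[ok, 1])^2 + (cy - dense[ok, 2])^2)
    idx <- (j[ok] - 1L) * nr + i[ok]
    o <- order(idx, d)
    idxo <- idx[o]; d_o <- d[o]
    first <- !duplicated(idxo)
    tgt <- idxo[first]
    mind[tgt] <- pmin(mind[tgt], d_o[first])
  }
  hit <- is.finite(mind)
  d_eff <- pmax(0, mind[hit] - r0)
  hb <- hD + sqrt(pmax(R^2 - d_eff^2, 0)) - R
  hb[d_eff > reach - r0] <- 0
  hb <- pmax(hb, 0)
  heights[hit] <- pmax(heights[hit], hb)
  heights
}

# Rasterize one placed molecule onto the height grid (modifies and returns
# the matrix): tip-contact backbone profile plus Gaussian label bumps.
rasterize_molecule <- function(heights, path, truth_labels, cfg) {
  px <- cfg$pixel_size_nm
  heights <- rasterize_backbone(heights, path, cfg)
  bound <- truth_labels[truth_labels$bound, , drop = FALSE]
  if (nrow(bound) > 0) {
    pts <- point_at_arc(path, bound$pos_bp / cfg$bp_per_nm)
    sigma <- cfg$label_footprint_nm / (2 * sqrt(2 * log(2)))
    r_px <- ceiling(3 * sigma / px)
    for (k in seq_len(nrow(pts))) {
      jc <- pmin(pmax(ceiling(pts[k, 1] / px), 1L), ncol(heights))
      ic <- pmin(pmax(ceiling(pts[k, 2] / px), 1L), nrow(heights))
      rows <- max(1L, ic - r_px):min(nrow(heights), ic + r_px)
      cols <- max(1L, jc - r_px):min(ncol(heights), jc + r_px)
      cx <- (cols - 0.5) * px; cy <- (rows - 0.5) * px
      d2 <- outer((cy - pts[k, 2])^2, (cx - pts[k, 1])^2, "+")
      bump <- cfg$label_height_nm * exp(-d2 / (2 * sigma^2))
      heights[rows, cols] <- pmax(heights[rows, cols], bump)
      heights[ic, jc] <- cfg$label_height_nm  # apex exactly at label height
    }
  }
  heights
}

# Rigid transform: rotate path about its centroid then translate so the
# bounding-box center of the rotated path lands on `center`.
transform_path <- function(path, center, angle) {
  c0 <- colMeans(path)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  rot <- sweep(path, 2, c0) %*% t(R)
  bb_mid <- (apply(rot, 2, max) + apply(rot, 2, min)) / 2
  sweep(rot, 2, center - bb_mid, "+")
}

# Minimum center-to-center distance at which two backbone stretches remain
# separable ridges: twice the tip-broadened half-footprint plus one pixel.
min_resolvable_gap <- function(cfg) {
  reach <- cfg$dna_radius_nm +
    sqrt(max(cfg$tip_radius_nm^2 -
               (cfg$tip_radius_nm - min(cfg$dna_height_nm,
                                        cfg$tip_radius_nm))^2, 0))
  2 * reach + cfg$pixel_size_nm
}

# TRUE if two non-adjacent stretches of the path come within `thr_nm` of
# each other (arc separation > gap_nm).  Such conformations are below the
# imaging resolution: two strands closer than a pixel merge into one ridge.
path_self_proximal <- function(path, thr_nm, gap_nm = 5 * thr_nm) {
  dense <- resample_path(path, thr_nm / 2)
  arc <- path_arclength(dense)
  n <- nrow(dense)
  cx <- floor(dense[, 1] / thr_nm); cy <- floor(dense[, 2] / thr_nm)
  key <- paste(cx, cy)
  by_cell <- split(seq_len(n), key)
  for (dx in -1:1) for (dy in -1:1) {
    nb <- by_cell[paste(cx + dx, cy + dy)]
    cnt <- lengths(nb)
    if (sum(cnt) == 0L) next
    ii <- rep.int(seq_len(n), cnt)
    jj <- unlist(nb, use.names = FALSE)
    far <- abs(arc[ii] - arc[jj]) > gap_nm
    if (!any(far)) next
    d2 <- (dense[ii[far], 1] - dense[jj[far], 1])^2 +
      (dense[ii[far], 2] - dense[jj[far], 2])^2
    if (any(d2 < thr_nm^2)) return(TRUE)
  }
  FALSE
}

#' Render a synthetic AFM frame
#'
#' Places molecules into the frame (random rotation and offset, rejection
#' sampling to keep molecules inside the frame and non-overlapping),
#' rasterizes backbones at `dna_height_nm` and bound labels as Gaussian bumps
#' reaching `label_height_nm`, dilates by a spherical tip of
#' `tip_radius_nm`, then adds per-scan-line offsets and per-pixel Gaussian
#' noise.
#'
#' @param mols list of [sim_molecule()]s (labels already applied).
#' @param cfg a [sim_config()].
#' @param placements optional list of `list(center = c(x, y), angle = a)` per
#'   molecule; random when omitted.
#' @param max_tries placement rejection-sampling budget per molecule.
#' @return `list(image = height_image, truth = frame_truth)` where the truth
#'   table has one row per molecule-label (plus label-free molecules) with
#'   true contour lengths and true label arc positions, and
#'   `truth$paths` holds the placed backbone paths.
#' @export
render_frame <- function(mols, cfg = sim_config(), placements = NULL,
                         max_tries = 200L) {
  if (inherits(mols, "sim_molecule")) mols <- list(mols)
  nx <- cfg$frame_size_px[1]; ny <- cfg$frame_size_px[2]
  px <- cfg$pixel_size_nm
  W <- nx * px; H <- ny * px
  heights <- matrix(0, ny, nx)
  margin <- cfg$tip_radius_nm + 2 * px
  occupied <- character(0)
  cell <- 2 * px
  placed_paths <- vector("list", length(mols))
  rows <- list()
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    span <- max(apply(mol$path, 2, function(v) diff(range(v))))
    if (span > sqrt(W^2 + H^2))
      stop(sprintf("molecule %s does not fit the frame diagonal", mol$id))
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      if (!is.null(placements)) {
        pl <- placements[[m]]
        tp <- transform_path(mol$path, pl$center, pl$angle)
      } else {
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- c(stats::runif(1, margin, W - margin),
                 stats::runif(1, margin, H - margin))
        tp <- transform_path(mol$path, ctr, ang)
      }
      inside <- all(tp[, 1] > margin & tp[, 1] < W - margin &
                    tp[, 2] > margin & tp[, 2] < H - margin)
      if (!inside) { if (!is.null(placements)) stop("fixed placement leaves the frame"); next }
      dense <- resample_path(tp, cell / 2)
      keys <- unique(paste(floor(dense[, 1] / cell), floor(dense[, 2] / cell)))
      if (any(keys %in% occupied)) { if (!is.null(placements)) stop("fixed placements overlap"); next }
      occupied <- c(occupied, keys)
      placed_paths[[m]] <- tp
      ok <- TRUE
      break
    }
    if (!ok) stop(sprintf("could not place molecule %s after %d tries",
                          mol$id, max_tries))
    heights <- rasterize_molecule(heights, placed_paths[[m]],
                                  mol$truth_labels, cfg)
    arc <- path_arclength(placed_paths[[m]])
    L_nm <- arc[length(arc)]
    lab <- mol$truth_labels
    if (nrow(lab) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol$id, length_bp = mol$length_bp, contour_nm = L_nm,
        label_kind = NA_character_, label_pos_bp = NA_real_,
        label_arc_nm = NA_real_, bound = NA)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol$id, length_bp = mol$length_bp, contour_nm = L_nm,
        label_kind = lab$kind, label_pos_bp = lab$pos_bp,
        label_arc_nm = lab$pos_bp / cfg$bp_per_nm, bound = lab$bound)
    }
  }
  heights <- tip_dilate(heights, cfg$tip_radius_nm, px)
  if (cfg$line_offset_sd_nm > 0)
    heights <- heights + stats::rnorm(ny, 0, cfg$line_offset_sd_nm)
  if (cfg$noise_sd_nm > 0)
    heights <- heights + matrix(stats::rnorm(ny * nx, 0, cfg$noise_sd_nm), ny, nx)
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(0), length_bp = numeric(0),
               contour_nm = numeric(0), label_kind = character(0),
               label_pos_bp = numeric(0), label_arc_nm = numeric(0),
               bound = logical(0))
  img <- height_image(heights, pixel_size_nm = px)
  structure(list(image = img,
                 truth = list(table = truth, paths = placed_paths)),
            class = "sim_frame")
}

#' Draw a measurement-level ladder sample
#'
#' Shortcut for sizing experiments: per-molecule measured lengths are drawn
#' as `Normal(true length, sizing_sd_bp)` for each species, emulating the
#' pooled single-molecule length measurements of an amplicon ladder.
#'
#' @param lengths_bp true species lengths (bp).
#' @param n_per molecules per species.
#' @param sizing_sd_bp per-molecule sizing error s.d. (bp).
#' @return data.frame with columns `species`, `true_bp`, `measured_bp`.
#' @export
make_ladder_sample <- function(lengths_bp, n_per, sizing_sd_bp) {
  if (length(lengths_bp) < 1L) stop("'lengths_bp' must be non-empty")
  if (n_per < 1L) stop("'n_per' must be >= 1")
  if (sizing_sd_bp < 0) stop("'sizing_sd_bp' must be >= 0")
  do.call(rbind, lapply(seq_along(lengths_bp), function(i) {
    data.frame(species = sprintf("L%03d", lengths_bp[i]),
               true_bp = lengths_bp[i],
               measured_bp = stats::rnorm(n_per, lengths_bp[i], sizing_sd_bp))
  }))
}
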
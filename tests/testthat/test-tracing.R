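# Skeletonization, pruning, spline contours, quality flags.

# Build a component_mask directly from a logical matrix.
mask_as_component <- function(mask, px = 2.5) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  structure(list(labels = lab, n = 1L, areas = sum(mask),
                 bboxes = list(c(1, nrow(mask), 1, ncol(mask))),
                 pixel_size_nm = px),
            class = "component_mask")
}

test_that("straight noise-free molecules measure at truth within 2%", {
  res <- render_single(680, seed = 201, noise = 0, line_sd = 0)
  expect_equal(res$comps$n, 1L)
  expect_length(res$trace$flags, 0L)
  expect_lt(abs(res$trace$contour_length_nm / (680 / 2.94) - 1), 0.02)
})

test_that("branch pruning keeps the longest arm and flags the branch", {
  # T shape: 100 px horizontal bar, 20 px vertical stem
  m <- matrix(FALSE, 60, 120)
  m[30, 10:109] <- TRUE
  m[31:50, 60] <- TRUE
  comp <- mask_as_component(m)
  tr <- trace_molecule(comp, 1)
  expect_true("branched" %in% tr$flags)
  # pruned path follows the long bar: brute-force longest-geodesic oracle
  skel <- nanomapr:::thin_mask(m)
  oracle <- brute_longest_path_length(skel, 2.5)
  chord <- sum(sqrt(rowSums(diff(tr$backbone)^2)))
  expect_lt(abs(chord - oracle), 2 * 2.5)
  # the stem (y-extent) is not part of the backbone
  expect_lt(max(tr$backbone[, 2]) - min(tr$backbone[, 2]), 5 * 2.5)
})

test_that("pruning matches exhaustive search on small junction masks", {
  set.seed(202)
  shapes <- list(
    { m <- matrix(FALSE, 40, 40); m[20, 5:35] <- TRUE; m[5:20, 12] <- TRUE
      m[20:36, 28] <- TRUE; m },                       # two junctions
    { m <- matrix(FALSE, 40, 40); m[10, 5:35] <- TRUE; m[10:30, 20] <- TRUE
      m },                                             # one junction
    { m <- matrix(FALSE, 40, 40); m[25, 3:37] <- TRUE; m[5:25, 8] <- TRUE
      m[5:25, 30] <- TRUE; m }                         # three arms up
  )
  for (m in shapes) {
    skel <- nanomapr:::thin_mask(m)
    oracle <- brute_longest_path_length(skel, 2.5)
    tr <- trace_molecule(mask_as_component(m), 1)
    chord <- sum(sqrt(rowSums(diff(tr$backbone)^2)))
    expect_lt(abs(chord - oracle), 2 * 2.5)
  }
})

test_that("rings are flagged looped and excluded from measurement", {
  th <- seq(0, 2 * pi, length.out = 200)
  m <- matrix(FALSE, 60, 60)
  idx <- unique(cbind(round(30 + 18 * sin(th)), round(30 + 18 * cos(th))))
  m[idx] <- TRUE
  tr <- trace_molecule(mask_as_component(m), 1)
  expect_true("looped" %in% tr$flags)
})

test_that("contour length quadrature is accurate and validated", {
  # horizontal 100 px path at 2 nm/px: ~198-200 nm
  bb <- cbind(seq_len(100) * 2 - 1, rep(10, 100))
  spl <- nanomapr:::fit_backbone_spline(bb, ma_window = 0)
  L <- nanomapr:::spline_arclength(spl)
  expect_gt(L, 197); expect_lt(L, 200)
  # semicircle radius 100 nm: pi * r within 1%
  th <- seq(0, pi, length.out = 150)
  bb2 <- cbind(100 * cos(th) + 120, 100 * sin(th) + 20)
  spl2 <- nanomapr:::fit_backbone_spline(bb2, ma_window = 0)
  expect_lt(abs(nanomapr:::spline_arclength(spl2) / (pi * 100) - 1), 0.01)
  # re-parameterization stability: doubling quadrature density
  t1 <- nanomapr:::spline_arclength(spl2)
  t2 <- nanomapr:::spline_arclength(spl2, upto = spl2$t_range[2])
  expect_lt(abs(t1 - t2) / t1, 1e-4)
  # degenerate trace errors
  tiny <- mask_as_component(matrix(c(TRUE, rep(FALSE, 24)), 5, 5))
  tr <- trace_molecule(tiny, 1)
  expect_true("too_short" %in% tr$flags)
  expect_error(contour_length(tr), "short")
})

test_that("contour length is invariant under 90-degree rotation", {
  # smooth shapes isolate grid anisotropy (sub-pixel kinks of a wiggly
  # chain re-grid differently and add ~1% conformational re-trace noise,
  # which is a resolution effect, not anisotropy)
  cfg <- sim_config(noise_sd_nm = 0, line_offset_sd_nm = 0,
                    frame_size_px = c(300, 300))
  L <- 680 / 2.94
  shapes <- list(
    straight = cbind(unique(c(seq(0, L, by = 0.5), L)), 0),
    arc = { th <- seq(0, L / 150, by = 0.5 / 150)
            cbind(150 * cos(th), 150 * sin(th)) })
  for (p in shapes) {
    mol <- sim_molecule("m", 680, cfg, path = p)
    Ls <- vapply(c(0, pi / 2), function(a) {
      set.seed(1)
      fr <- render_frame(mol, cfg,
                         placements = list(list(center = c(375, 375),
                                                angle = a + 0.2)))
      flat <- flatten(fr$image)
      trace_molecule(segment(flat), 1, flat)$contour_length_nm
    }, numeric(1))
    expect_lt(abs(Ls[2] / Ls[1] - 1), 0.005)
  }
  # wiggly chains: re-gridding noise stays within the tracing error budget
  set.seed(204)
  cfgw <- sim_config(noise_sd_nm = 0, line_offset_sd_nm = 0,
                     frame_size_px = c(400, 400), align_corr_nm = 25)
  mol <- sim_molecule("m", 2000, cfgw)
  Ls <- vapply(c(0, pi / 2), function(a) {
    fr <- render_frame(mol, cfgw, placements = list(list(center = c(500, 500),
                                                         angle = a)))
    flat <- flatten(fr$image)
    trace_molecule(segment(flat), 1, flat)$contour_length_nm
  }, numeric(1))
  expect_lt(abs(Ls[2] / Ls[1] - 1), 0.02)
})

test_that("noise-free contours are within 2% of truth across sizes", {
  # panel of molecules drawn log-uniformly across the stated size range;
  # flagged molecules are excluded from measurement, as in the real pipeline
  sizes <- round(exp(seq(log(300), log(13000), length.out = 24)))
  errs <- c()
  for (i in seq_along(sizes)) {
    bp <- sizes[i]
    res <- render_single(bp, seed = 3000 + i, noise = 0, line_sd = 0,
                         align = if (bp > 1500) 25 else NULL)
    if (is.null(res) || res$comps$n != 1 || length(res$trace$flags)) next
    errs <- c(errs, res$trace$contour_length_nm /
                res$frame$truth$table$contour_nm[1] - 1)
  }
  expect_gt(length(errs), 20)
  expect_gte(mean(abs(errs) <= 0.02), 0.95)
})

test_that("edge-clipped and crossing molecules are flagged", {
  # molecule rendered to the frame border
  cfg <- sim_config(frame_size_px = c(60, 40), noise_sd_nm = 0,
                    line_offset_sd_nm = 0)
  path <- cbind(seq(0, 200, by = 0.5), 0)
  h <- matrix(0, 40, 60)
  img <- nanomapr:::rasterize_backbone(h, cbind(seq(-10, 160, by = 0.5), 50),
                                       cfg)
  im <- height_image(img, 2.5)
  comps <- segment(im)
  expect_gte(comps$n, 1L)
  tr <- trace_molecule(comps, 1, im)
  expect_true("edge_clipped" %in% tr$flags)

  # two crossing molecules -> branched/looped flag on the merged component
  cfg2 <- sim_config(frame_size_px = c(120, 120), noise_sd_nm = 0,
                     line_offset_sd_nm = 0)
  p1 <- cbind(seq(50, 250, by = 0.5), 150)
  p2 <- cbind(150, seq(50, 250, by = 0.5))
  h2 <- matrix(0, 120, 120)
  h2 <- nanomapr:::rasterize_backbone(h2, p1, cfg2)
  h2 <- nanomapr:::rasterize_backbone(h2, p2, cfg2)
  im2 <- height_image(h2, 2.5)
  tr2 <- trace_molecule(segment(im2), 1, im2)
  expect_true(any(c("branched", "looped") %in% tr2$flags))
  expect_identical(quality_flags(tr2), tr2$flags)

  # clean molecule: no flags
  res <- render_single(680, seed = 205, noise = 0, line_sd = 0)
  expect_length(quality_flags(res$trace), 0L)
})
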
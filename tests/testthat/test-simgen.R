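# Synthetic generator: chain geometry, label occupancy, rendering, ladder.

test_that("worm-like chains have exact arc length and reject bad input", {
  cfg <- sim_config()
  set.seed(1)
  # 680 bp at 2.94 bp/nm -> 231.2925 nm, arithmetic oracle
  p <- sample_wlc_chain(680, cfg)
  arc <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(arc, 680 / 2.94, tolerance = 1e-3)
  # single base pair: two-point path of one rise
  p1 <- sample_wlc_chain(1, cfg)
  expect_equal(nrow(p1), 2L)
  expect_equal(sum(sqrt(rowSums(diff(p1)^2))), 1 / 2.94, tolerance = 1e-9)
  expect_error(sample_wlc_chain(0, cfg), "positive")
  expect_error(sample_wlc_chain(680, cfg, step_nm = 10), "pixel")
})

test_that("tangent correlation decays with the 2D convention", {
  # Monte-Carlo oracle: mean cos(angle between tangents s apart) over many
  # chains, compared with exp(-s / (2 lp)) at s = 50 nm, lp = 50 nm
  cfg <- sim_config(persistence_length_nm = 50)
  set.seed(42)
  n_chain <- 1000L
  s_gap <- 50L   # nm; step_nm = 1 so index gap = arc gap
  cors <- vapply(seq_len(n_chain), function(i) {
    p <- sample_wlc_chain(1200, cfg, step_nm = 1)
    v <- diff(p)
    a <- atan2(v[, 2], v[, 1])
    mean(cos(a[(1 + s_gap):length(a)] - a[1:(length(a) - s_gap)]))
  }, numeric(1))
  expected <- exp(-s_gap / (2 * 50))
  se <- sd(cors) / sqrt(n_chain)
  expect_lt(abs(mean(cors) - expected), 3 * se + 1e-3)
})

test_that("label occupancy follows the configured Bernoulli/Poisson model", {
  map <- reference_map("M", 1000, c(100, 300, 500, 700, 900))
  cfg1 <- sim_config(labeling_efficiency = 1, off_target_rate = 0)
  set.seed(7)
  m <- apply_labels(sim_molecule("a", 1000, cfg1), map, cfg1)
  expect_true(all(m$truth_labels$bound))
  expect_equal(nrow(m$truth_labels), 5L)

  # binomial oracle: 10,000 molecules x 5 sites at p = 0.9
  cfg2 <- sim_config(labeling_efficiency = 0.9, off_target_rate = 0)
  set.seed(8)
  n_mol <- 10000L
  path <- cbind(c(0, 1000 / 2.94), c(0, 0))  # reuse one trivial path
  bound <- vapply(seq_len(n_mol), function(i) {
    mm <- apply_labels(sim_molecule(i, 1000, cfg2, path = path), map, cfg2)
    sum(mm$truth_labels$bound)
  }, numeric(1))
  p_hat <- sum(bound) / (5 * n_mol)
  se <- sqrt(0.9 * 0.1 / (5 * n_mol))
  expect_lt(abs(p_hat - 0.9), 3 * se)
  # chi-square goodness of fit of per-molecule bound counts vs Binomial(5, .9)
  obs <- tabulate(bound + 1L, nbins = 6L)
  expp <- dbinom(0:5, 5, 0.9) * n_mol
  grp <- expp >= 5
  chi <- sum((obs[grp] - expp[grp])^2 / expp[grp]) +
    (sum(obs[!grp]) - sum(expp[!grp]))^2 / max(sum(expp[!grp]), 1e-9)
  expect_lt(chi, qchisq(0.999, df = sum(grp)))

  # Poisson oracle for off-targets
  cfg3 <- sim_config(labeling_efficiency = 0, off_target_rate = 0.5)
  set.seed(9)
  offs <- vapply(seq_len(10000), function(i) {
    mm <- apply_labels(sim_molecule(i, 1000, cfg3, path = path), map, cfg3)
    sum(mm$truth_labels$kind == "off_target")
  }, numeric(1))
  expect_lt(abs(mean(offs) - 0.5), 3 * sqrt(0.5 / 10000))

  # length mismatch rejected
  expect_error(apply_labels(sim_molecule("x", 900, cfg1, path = path),
                            map, cfg1), "length")
})

test_that("rendering produces the stated heights", {
  # empty frame: mean ~ 0, no pixel above 6 sigma
  cfg <- sim_config(frame_size_px = c(120, 120), noise_sd_nm = 0.1,
                    line_offset_sd_nm = 0)
  set.seed(11)
  fr <- render_frame(list(), cfg)
  expect_lt(abs(mean(fr$image$heights)), 0.01)
  expect_lt(max(fr$image$heights), 0.6)

  # one labeled straight molecule, no noise: label apex exactly 3 nm,
  # backbone ridge at 0.3 nm along the truth path
  cfg0 <- sim_config(frame_size_px = c(160, 80), noise_sd_nm = 0,
                     line_offset_sd_nm = 0)
  map <- reference_map("T", 680, 340)
  path <- cbind(unique(c(seq(0, 680 / 2.94, by = 0.5), 680 / 2.94)), 0)
  mol <- sim_molecule("m", 680, cfg0, path = path)
  cfg_all <- sim_config(labeling_efficiency = 1)
  set.seed(3)
  mol <- apply_labels(mol, map, cfg_all)
  fr0 <- render_frame(mol, cfg0,
                      placements = list(list(center = c(200, 100),
                                             angle = 0)))
  expect_equal(max(fr0$image$heights), 3.0)
  # ridge height along the placed path away from the label
  tp <- fr0$truth$paths[[1]]
  mid <- tp[abs(nanomapr:::path_arclength(tp) - 40) < 10, , drop = FALSE]
  ii <- ceiling(mid[, 2] / 2.5); jj <- ceiling(mid[, 1] / 2.5)
  expect_true(all(abs(fr0$image$heights[cbind(ii, jj)] - 0.3) < 0.05))
  # truth bookkeeping
  expect_equal(fr0$truth$table$label_arc_nm[1], 340 / 2.94)
  expect_equal(fr0$truth$table$contour_nm[1], 680 / 2.94, tolerance = 1e-6)
})

test_that("rendering is deterministic and idempotent without noise", {
  map <- reference_map("T", 680, c(200, 338))
  mk <- function() {
    cfg <- sim_config(frame_size_px = c(200, 200), seed = 5)
    set.seed(cfg$seed)
    mol <- apply_labels(sim_molecule("m", 680, cfg), map, cfg)
    render_frame(mol, cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$image$heights, b$image$heights)
  expect_identical(a$truth$table, b$truth$table)
  # no-noise render of the same placed molecule is reproducible exactly
  cfg0 <- sim_config(frame_size_px = c(200, 200), noise_sd_nm = 0,
                     line_offset_sd_nm = 0)
  set.seed(6)
  mol <- sim_molecule("m", 680, cfg0)
  pl <- list(list(center = c(250, 250), angle = 1))
  expect_identical(render_frame(mol, cfg0, placements = pl)$image$heights,
                   render_frame(mol, cfg0, placements = pl)$image$heights)
})

test_that("oversized molecules and failed placements are rejected", {
  cfg <- sim_config(frame_size_px = c(40, 40))
  path <- cbind(seq(0, 500, by = 1), 0)   # 500 nm in a 100 nm frame
  mol <- sim_molecule("big", 1470, cfg, path = path)
  expect_error(render_frame(mol, cfg), "diagonal|fit|place")
})

test_that("ladder samples match their normal sampling oracles", {
  set.seed(21)
  lad <- make_ladder_sample(140, 15000, 20)
  # mean within 4 sd/sqrt(n) of truth
  expect_lt(abs(mean(lad$measured_bp) - 140), 4 * 20 / sqrt(15000))
  # zero sizing error: measurements equal truth
  lad0 <- make_ladder_sample(c(140, 150), 10, 0)
  expect_equal(lad0$measured_bp, lad0$true_bp)
  # two-species difference of sample means: 2 +/- 1 bp
  set.seed(22)
  lad2 <- make_ladder_sample(c(140, 142), 15000, 20)
  d <- diff(tapply(lad2$measured_bp, lad2$species, mean))
  expect_lt(abs(d - 2), 1)
  expect_error(make_ladder_sample(numeric(0), 10, 20), "empty|non-empty")
  expect_error(make_ladder_sample(140, 0, 20), "n_per")
})

test_that("self-proximal conformations are resampled away", {
  cfg <- sim_config()
  set.seed(33)
  gap <- nanomapr:::min_resolvable_gap(cfg)
  for (i in 1:10) {
    mol <- sim_molecule(i, 2000, cfg)
    expect_false(nanomapr:::path_self_proximal(mol$path, gap))
  }
})
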
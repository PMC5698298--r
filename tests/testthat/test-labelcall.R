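# Backbone profiles, peak detection, molecule measurement.

test_that("profiles report the rendered heights along the backbone", {
  # unlabeled noise-free molecule: profile ~ 0.3 nm everywhere
  res <- render_single(680, seed = 301, noise = 0, line_sd = 0)
  prof <- backbone_profile(res$flat, res$trace)
  inner <- prof$height_nm[prof$arc_nm > 5 & prof$arc_nm < max(prof$arc_nm) - 5]
  expect_true(all(abs(inner - 0.3) < 0.06))
  expect_equal(prof$arc_nm[1], 0)
  expect_equal(max(prof$arc_nm), res$trace$contour_length_nm,
               tolerance = 1e-3)
  expect_error(backbone_profile(res$flat, res$trace,
                                sampling_step_nm = 1e5), "step")

  # one label mid-molecule: single ~3 nm peak near L/2
  map <- reference_map("mid", 680, 340)
  res2 <- render_single(680, seed = 302, map = map, noise = 0, line_sd = 0)
  prof2 <- backbone_profile(res2$flat, res2$trace)
  pk <- which.max(prof2$height_nm)
  expect_gt(prof2$height_nm[pk], 2.7)
  expect_lt(abs(prof2$arc_nm[pk] - res2$trace$contour_length_nm / 2), 15)
})

test_that("detect_labels matches stated thresholds and localization", {
  # flat profile with no excursion > 1 nm: empty
  flatp <- structure(data.frame(arc_nm = 0:200,
                                height_nm = 0.3 + 0.2 * sin(0:200 / 7)),
                     class = c("backbone_profile", "data.frame"))
  expect_equal(nrow(detect_labels(flatp)), 0L)

  # two Gaussian bumps 46.9 nm apart (TERT-like): two calls at that spacing
  s <- seq(0, 231.3, by = 0.5)
  h <- 0.3 + 2.7 * exp(-(s - 90)^2 / (2 * 4^2)) +
    2.7 * exp(-(s - 136.9)^2 / (2 * 4^2))
  prof <- structure(data.frame(arc_nm = s, height_nm = h),
                    class = c("backbone_profile", "data.frame"))
  calls <- detect_labels(prof)
  expect_equal(nrow(calls), 2L)
  expect_lt(abs(diff(calls$arc_pos_nm) - 46.9), 3)

  # two distinct maxima closer than min_sep merge into one flagged call
  h2 <- 0.3 + 2.7 * exp(-(s - 100)^2 / (2 * 2^2)) +
    2.2 * exp(-(s - 108)^2 / (2 * 2^2))
  prof2 <- structure(data.frame(arc_nm = s, height_nm = h2),
                     class = c("backbone_profile", "data.frame"))
  calls2 <- detect_labels(prof2, min_sep_nm = 10)
  expect_equal(nrow(calls2), 1L)
  expect_true(calls2$merged[1])
})

test_that("position symmetry: reversing the profile maps x to L - x", {
  s <- seq(0, 200, by = 0.5)
  set.seed(303)
  h <- 0.3 + 2.7 * exp(-(s - 57.3)^2 / (2 * 4^2)) +
    2.5 * exp(-(s - 140.8)^2 / (2 * 4^2)) + rnorm(length(s), 0, 0.02)
  fwd <- structure(data.frame(arc_nm = s, height_nm = h),
                   class = c("backbone_profile", "data.frame"))
  rev <- structure(data.frame(arc_nm = s, height_nm = base::rev(h)),
                   class = c("backbone_profile", "data.frame"))
  cf <- detect_labels(fwd); cr <- detect_labels(rev)
  expect_equal(nrow(cf), nrow(cr))
  expect_equal(sort(200 - cr$arc_pos_nm), sort(cf$arc_pos_nm),
               tolerance = 1e-9)
})

test_that("measure_molecule composes profile, detection and calibration", {
  map <- reference_map("B5", 2000, c(300, 800, 1200, 1600, 1900))
  res <- render_single(2000, seed = 304, map = map, noise = 0, line_sd = 0,
                       align = 25)
  mm <- measure_molecule(res$flat, res$trace)
  expect_s3_class(mm, "molecule_measurement")
  expect_equal(nrow(mm$labels), 5L)
  # calibration consistency is exact by construction
  expect_equal(mm$contour_length_bp / mm$contour_length_nm, 2.94)
  expect_equal(mm$labels$arc_pos_bp / mm$labels$arc_pos_nm,
               rep(2.94, 5))
  expect_identical(mm$orientation, "unresolved")
  # truth positions recovered within 100 bp (up to molecule orientation)
  truth <- sort(res$frame$truth$table$label_pos_bp)
  got <- sort(mm$labels$arc_pos_bp)
  err_f <- max(abs(got - truth))
  err_r <- max(abs(sort(mm$contour_length_bp - got) - truth))
  expect_lt(min(err_f, err_r), 100)

  # unlabeled molecule: zero calls, contour still measured
  res0 <- render_single(680, seed = 305, noise = 0, line_sd = 0)
  mm0 <- measure_molecule(res0$flat, res0$trace)
  expect_equal(nrow(mm0$labels), 0L)
  expect_gt(mm0$contour_length_nm, 200)
})

test_that("label detection is sensitive and specific on rendered frames", {
  # ROC at defaults: 3 nm labels, 0.1 nm noise
  map <- reference_map("B3", 2000, c(400, 1000, 1600))
  n_mol <- 25L
  found <- 0L; total <- 0L; false_calls <- 0L; used <- 0L
  for (i in seq_len(n_mol)) {
    res <- render_single(2000, seed = 310 + i, map = map, align = 25)
    if (is.null(res) || res$comps$n < 1 || length(res$trace$flags)) next
    mm <- measure_molecule(res$flat, res$trace)
    truth <- res$frame$truth$table
    truth_arcs <- truth$label_arc_nm[truth$bound]
    L <- res$trace$contour_length_nm
    used <- used + 1L
    for (ta in truth_arcs) {
      total <- total + 1L
      d <- min(abs(mm$labels$arc_pos_nm - ta),
               abs(mm$labels$arc_pos_nm - (L - ta)))
      if (length(d) && d < 30) found <- found + 1L
    }
    false_calls <- false_calls + max(0L, nrow(mm$labels) - length(truth_arcs))
  }
  expect_gt(used, 15)
  expect_gte(found / total, 0.99)
  expect_lte(false_calls / used, 0.01)
})

test_that("single-label localization is unbiased", {
  # signed error of the detected position vs truth across molecules
  map <- reference_map("one", 680, 250)
  errs <- c()
  for (i in 1:20) {
    res <- render_single(680, seed = 340 + i, map = map)
    if (is.null(res) || res$comps$n < 1 || length(res$trace$flags)) next
    mm <- measure_molecule(res$flat, res$trace)
    if (nrow(mm$labels) != 1) next
    ta <- res$frame$truth$table$label_arc_nm[1]
    L <- res$trace$contour_length_nm
    # resolve orientation by picking the closer end assignment
    e <- c(mm$labels$arc_pos_nm - ta, (L - mm$labels$arc_pos_nm) - ta)
    errs <- c(errs, e[which.min(abs(e))])
  }
  expect_gt(length(errs), 12)
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 1)
})
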
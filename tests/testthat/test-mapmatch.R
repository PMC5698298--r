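# Guide-site search, orientation/assignment, translocation calling.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Naive O(n*m) both-strand scan used as the independent oracle.
naive_guide_scan <- function(sequence, guide, max_mm = 0L) {
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  scan1 <- function(seqstr, strand) {
    n <- nchar(seqstr); g <- strsplit(guide, "")[[1]]
    hits <- NULL
    for (st in seq_len(n - 22)) {
      win <- substr(seqstr, st, st + 22)
      if (grepl("[^ACGT]", win)) next
      pam <- substr(win, 21, 23)
      if (substr(pam, 2, 3) != "GG") next
      mm <- sum(strsplit(substr(win, 1, 20), "")[[1]] != g)
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(start_local = st, strand = strand,
                                       mismatches = mm))
    }
    hits
  }
  f <- scan1(sequence, "+")
  r <- scan1(revcomp(sequence), "-")
  n <- nchar(sequence)
  out <- NULL
  if (!is.null(f)) out <- rbind(out, data.frame(pos_bp = f$start_local + 10L,
                                                strand = "+",
                                                mismatches = f$mismatches))
  if (!is.null(r)) out <- rbind(out, data.frame(
    pos_bp = n - (r$start_local + 10L) + 1L, strand = "-",
    mismatches = r$mismatches))
  if (is.null(out)) return(data.frame(pos_bp = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  out[order(out$pos_bp), ]
}

test_that("guide-site search handles embedded sites on both strands", {
  g <- "ACGTACGTACGTACGTACGA"
  # one perfect site with AGG PAM
  s1 <- paste0(strrep("T", 50), g, "AGG", strrep("C", 30))
  hit <- find_guide_sites(s1, g)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$pos_bp, 61L)       # start 51 + 10
  # one substituted position found only with max_mismatches = 1
  g_mut <- paste0(substr(g, 1, 9), "T", substr(g, 11, 20))
  s2 <- paste0(strrep("T", 20), g_mut, "TGG", strrep("A", 20))
  expect_equal(nrow(find_guide_sites(s2, g, max_mismatches = 0)), 0L)
  hit2 <- find_guide_sites(s2, g, max_mismatches = 1)
  expect_equal(nrow(hit2), 1L)
  expect_identical(hit2$match_type, "mismatch")
  # guide present but no NGG: nothing
  s3 <- paste0(strrep("T", 20), g, "ATT", strrep("A", 20))
  expect_equal(nrow(find_guide_sites(s3, g)), 0L)
  # ambiguous bases skipped with warning
  s4 <- paste0(strrep("T", 20), substr(g, 1, 10), "N",
               substr(g, 12, 20), "AGG")
  expect_warning(res4 <- find_guide_sites(s4, g, max_mismatches = 1),
                 "ambig")
  expect_equal(nrow(res4), 0L)
  expect_error(find_guide_sites(s1, "SHORT"), "20")
})

test_that("guide-site search agrees with the naive scan on random 10 kb", {
  g <- "GATTACAGATTACAGGATTA"
  for (seed in 1:3) {
    set.seed(seed)
    # random sequence plus a few planted sites to guarantee hits
    s <- random_dna(10000)
    plant <- function(s, pos, core) paste0(substr(s, 1, pos - 1), core,
                                           substr(s, pos + nchar(core),
                                                  nchar(s)))
    s <- plant(s, 1200, paste0(g, "AGG"))
    s <- plant(s, 5800, paste0(chartr("ACGT", "TGCA",
                                      paste(rev(strsplit(paste0(g, "TGG"),
                                                         "")[[1]]),
                                            collapse = "")), ""))
    got <- find_guide_sites(s, g, max_mismatches = 1)
    oracle <- naive_guide_scan(s, g, max_mm = 1)
    expect_equal(got$pos_bp, oracle$pos_bp)
    expect_equal(got$mismatches, oracle$mismatches)
    expect_equal(got$strand, oracle$strand)
  }
})

test_that("assignment cost equals the exhaustive-search minimum", {
  set.seed(501)
  for (rep in 1:40) {
    ns <- sample(1:6, 1); nl <- sample(1:6, 1)
    sites <- sort(sample(200:9800, ns))
    labels <- sort(sample(1:10000, nl))
    w <- runif(ns, 0.4, 1)
    tol <- 500
    dp <- nanomapr:::match_labels_dp(labels, sites, w, tol)
    oracle <- exhaustive_match_cost(labels, sites, w, tol)
    expect_equal(dp$cost, oracle, tolerance = 1e-9)
  }
})

test_that("orientation is recovered from asymmetric label patterns", {
  map <- reference_map("A3", 10000, c(1000, 2500, 7000))
  fwd <- orient_and_assign(mk_measurement(c(1000, 2500, 7000), 10000), map)
  expect_identical(fwd$orientation, "A-first")
  expect_equal(fwd$cost, 0)
  expect_equal(nrow(fwd$matches), 3L)
  rev <- orient_and_assign(mk_measurement(10000 - c(1000, 2500, 7000), 10000),
                           map)
  expect_identical(rev$orientation, "B-first")
  expect_lt(max(abs(rev$matches$residual_bp)), 10)
  # palindromic layout: ambiguous
  pal <- reference_map("P", 10000, c(2000, 8000))
  amb <- orient_and_assign(mk_measurement(c(2000, 8000), 10000), pal)
  expect_identical(amb$orientation, "ambiguous")
  # incompatible length: explicit signal
  inc <- orient_and_assign(mk_measurement(1000, 6000), map)
  expect_identical(inc$orientation, "incompatible")
  expect_error(orient_and_assign(mk_measurement(numeric(0), 10000), map),
               "label")
})

test_that("orientation recovery rate exceeds 99% on 5-site maps", {
  # asymmetric Alu-like 5-perfect-site map, occupancy 0.9, exact positions
  map <- reference_map("B5", 12900, c(1200, 2500, 5600, 8400, 11800))
  set.seed(502)
  n <- 400L
  ok <- 0L
  for (i in seq_len(n)) {
    bound <- runif(5) < 0.9
    if (!any(bound)) { ok <- ok + 1L; next }   # nothing to orient
    pos <- map$sites$pos_bp[bound]
    reversed <- runif(1) < 0.5
    labs <- if (reversed) 12900 - pos else pos
    a <- orient_and_assign(mk_measurement(labs, 12900), map)
    want <- if (reversed) "B-first" else "A-first"
    if (identical(a$orientation, want)) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.99)
})

test_that("translocations are called with breakpoint intervals", {
  # fusion: 1500-bp BCL2-like prefix with sites straddling a 300-bp MBR,
  # IGH-like partner with a J-proximal site near its distal end
  map_A <- reference_map("BCL2", 1500, c(500, 800))
  map_B <- reference_map("IGH", 4000, c(3300))
  bA <- 950; bB <- 1500                      # truth breakpoints
  L <- bA + (4000 - bB)                      # 3450 bp fusion molecule
  set.seed(503)
  ms <- lapply(1:20, function(i) {
    labs <- c(500, 800, bA + (3300 - bB)) + rnorm(3, 0, 50)
    if (i %% 2 == 0) labs <- L - labs        # half the molecules reversed
    mk_measurement(labs, L + rnorm(1, 0, 60))
  })
  call <- call_translocation(ms, map_A, map_B)
  expect_true(call$called)
  expect_gte(call$support, 10)
  iA <- call$breakpoint_interval_A_bp
  expect_true(iA[1] <= bA && bA <= iA[2])
  iB <- call$breakpoint_interval_B_bp
  expect_true(iB[1] <= bB && bB <= iB[2])

  # wild-type A molecules only: no call
  wt <- lapply(1:15, function(i) mk_measurement(c(500, 800) +
                                                  rnorm(2, 0, 40), 1500))
  call_wt <- call_translocation(wt, map_A, map_B)
  expect_false(call_wt$called)

  # 9 supporting molecules with min_support 10: low confidence, no call
  call9 <- call_translocation(ms[1:9], map_A, map_B, min_support = 10)
  expect_false(call9$called)
  expect_equal(call9$support, 9L)
  expect_true(call_translocation(ms[1:10], map_A, map_B,
                                 min_support = 10)$called)
})

test_that("breakpoint intervals contain the truth across noisy repetitions", {
  map_A <- reference_map("A", 2000, c(600, 1100))
  map_B <- reference_map("B", 3000, c(2400))
  set.seed(504)
  hits <- vapply(1:50, function(rep) {
    bA <- 1400; bB <- 900
    L <- bA + (3000 - bB)
    ms <- lapply(1:12, function(i) {
      labs <- c(600, 1100, bA + (2400 - bB)) + rnorm(3, 0, 80)
      if (i %% 2 == 0) labs <- L - labs
      mk_measurement(labs, L + rnorm(1, 0, 80))
    })
    call <- call_translocation(ms, map_A, map_B)
    iA <- call$breakpoint_interval_A_bp
    call$called && iA[1] <= bA && bA <= iA[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("reference maps validate and round-trip through TSV", {
  expect_error(reference_map("x", 100, 200), "1, length")
  expect_error(reference_map("x", 1000, 100, "weird"), "match_type")
  m <- reference_map("locus", 5000, c(400, 2100, 4700),
                     c("perfect", "mismatch", "perfect"), c("+", "-", "+"))
  path <- tempfile(fileext = ".tsv")
  write_reference_map(m, path)
  m2 <- read_reference_map(path)
  expect_equal(m2$sites, m$sites)
  expect_equal(m2$length_bp, m$length_bp)
  unlink(path)
})
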
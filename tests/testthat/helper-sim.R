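# Shared fixtures: all synthetic inputs are generated in code at test time.

# Render one molecule in an auto-sized frame and run the imaging pipeline up
# to tracing.  Returns NULL when rendering fails (placement), otherwise a
# list with frame, flattened image, component mask and trace.
render_single <- function(length_bp, seed, map = NULL, noise = 0.1,
                          line_sd = 0.1, align = NULL, label_eff = 1,
                          margin_px = 40L) {
  set.seed(seed)
  cfg <- sim_config(noise_sd_nm = noise, line_offset_sd_nm = line_sd,
                    align_corr_nm = align, labeling_efficiency = label_eff)
  mol <- sim_molecule("m", length_bp, cfg)
  if (!is.null(map)) mol <- apply_labels(mol, map, cfg)
  span <- apply(mol$path, 2, function(v) diff(range(v)))
  fpx <- as.integer(pmax(80L, ceiling(span / cfg$pixel_size_nm) + margin_px))
  cfg$frame_size_px <- fpx
  ctr <- fpx * cfg$pixel_size_nm / 2
  fr <- tryCatch(
    render_frame(mol, cfg, placements = list(list(center = ctr, angle = 0))),
    error = function(e) NULL)
  if (is.null(fr)) return(NULL)
  flat <- flatten(fr$image)
  comps <- segment(flat)
  tr <- if (comps$n >= 1) trace_molecule(comps, 1L, flat) else NULL
  list(cfg = cfg, mol = mol, frame = fr, flat = flat, comps = comps,
       trace = tr)
}

# A synthetic measurement object at the measurement level (positions in bp).
mk_measurement <- function(labels_bp, length_bp, bp_per_nm = 2.94) {
  labels_bp <- sort(labels_bp)
  n <- length(labels_bp)
  structure(list(trace = NULL,
                 labels = data.frame(arc_pos_nm = labels_bp / bp_per_nm,
                                     prominence_nm = rep(2.5, n),
                                     width_nm = rep(10, n),
                                     merged = rep(FALSE, n),
                                     arc_pos_bp = labels_bp),
                 contour_length_nm = length_bp / bp_per_nm,
                 contour_length_bp = length_bp,
                 orientation = "unresolved", bp_per_nm = bp_per_nm),
            class = "molecule_measurement")
}

# Exhaustive minimum-cost one-to-one matching oracle (any subset of labels
# to any subset of sites, bijectively), with the same cost structure as the
# DP matcher: matched |residual| (gated at tol), skipped site w * tol,
# skipped label tol.  Feasible for <= 6 x 6.
exhaustive_match_cost <- function(labels, sites, w, tol) {
  nl <- length(labels); ns <- length(sites)
  best <- Inf
  subsets <- function(n) {
    if (n == 0) return(list(integer(0)))
    unlist(lapply(0:(2^n - 1), function(m) list(which(bitwAnd(m, 2^(0:(n - 1))) > 0))),
           recursive = FALSE)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (ls in subsets(nl)) for (ss in subsets(ns)) {
    if (length(ls) != length(ss)) next
    base <- sum(w[setdiff(seq_len(ns), ss)]) * tol +
      (nl - length(ls)) * tol
    if (length(ls) == 0) { best <- min(best, base); next }
    for (p in perms(ss)) {
      r <- abs(labels[ls] - sites[p])
      if (any(r > tol)) next
      best <- min(best, base + sum(r))
    }
  }
  best
}

# Brute-force longest endpoint-to-endpoint path on a skeleton graph built
# from a logical mask, by enumerating simple paths (tiny masks only).
brute_longest_path_length <- function(skel, px) {
  sg <- nanomapr:::skeleton_graph(skel, px)
  deg <- igraph::degree(sg$g)
  ends <- which(deg == 1)
  best <- 0
  for (i in ends) for (j in ends) {
    if (i >= j) next
    ap <- igraph::all_simple_paths(sg$g, from = i, to = j)
    for (p in ap) {
      ei <- igraph::E(sg$g, path = p)
      best <- max(best, sum(ei$weight))
    }
  }
  best
}
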
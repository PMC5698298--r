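# Reference maps, guide-site search, molecule orientation and label-to-site
# assignment, translocation breakpoint calling.

#' Reference label map
#'
#' Expected Cas9 site positions on a locus.  Site positions are 1-based
#' centers of the 20-bp protospacer; sites found on either strand are merged
#' into one map, since a bound Cas9 bump is strand-agnostic in a height
#' image.
#'
#' @param name map name (unique within a map set).
#' @param length_bp locus length in bp.
#' @param pos_bp site positions (1-based protospacer centers).
#' @param match_type `"perfect"` or `"mismatch"` per site.
#' @param strand optional strand per site (`"+"`/`"-"`).
#' @return a `reference_map` with sites sorted by position.
#' @export
reference_map <- function(name, length_bp, pos_bp,
                          match_type = rep("perfect", length(pos_bp)),
                          strand = rep("+", length(pos_bp))) {
  if (any(pos_bp < 1 | pos_bp > length_bp))
    stop("site positions must lie in [1, length_bp]")
  if (!all(match_type %in% c("perfect", "mismatch")))
    stop("match_type must be 'perfect' or 'mismatch'")
  ord <- order(pos_bp)
  structure(list(name = name, length_bp = as.integer(length_bp),
                 sites = data.frame(pos_bp = pos_bp[ord],
                                    match_type = match_type[ord],
                                    strand = strand[ord],
                                    stringsAsFactors = FALSE)),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("reference_map '%s': %d bp, %d site(s)\n", x$name, x$length_bp,
              nrow(x$sites)))
  if (nrow(x$sites)) {
    cat(sprintf("  %s\n", paste(sprintf("%g(%s)", x$sites$pos_bp,
                                        substr(x$sites$match_type, 1, 1)),
                                collapse = " ")))
  }
  invisible(x)
}

#' Write / read a reference map as BED-like TSV
#'
#' Columns: name, length_bp, site_pos_bp (1-based), match_type, strand.
#' @param map a [reference_map()].
#' @param path file path.
#' @return `read_reference_map` returns a `reference_map`.
#' @export
write_reference_map <- function(map, path) {
  df <- data.frame(name = map$name, length_bp = map$length_bp,
                   site_pos_bp = map$sites$pos_bp,
                   match_type = map$sites$match_type,
                   strand = map$sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_map
#' @export
read_reference_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  reference_map(df$name[1], df$length_bp[1], df$site_pos_bp,
                df$match_type, df$strand)
}

iupac_regex <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[GC]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

iupac_char_match <- function(base, code) {
  grepl(iupac_regex[[code]], base, fixed = FALSE)
}

#' Find guide-RNA binding sites in a sequence
#'
#' Scans both strands for 20-bp protospacers matching the guide with at most
#' `max_mismatches` substitutions, immediately followed (3') by a PAM
#' matching the IUPAC pattern (default `"NGG"`, which must match exactly —
#' mismatches are only tolerated in the protospacer).  Windows containing
#' ambiguous bases are skipped with a warning.
#'
#' @param sequence DNA string over A/C/G/T (ambiguity codes are skipped).
#' @param guide 20-character guide (protospacer) sequence.
#' @param pam IUPAC PAM pattern, default `"NGG"`.
#' @param max_mismatches maximum protospacer mismatches.
#' @return data.frame: `pos_bp` (1-based protospacer center, forward-strand
#'   coordinates), `strand`, `mismatches`, `match_type`, `start` (forward
#'   strand start of the protospacer).
#' @export
find_guide_sites <- function(sequence, guide, pam = "NGG",
                             max_mismatches = 0L) {
  sequence <- toupper(as.character(sequence))
  guide <- toupper(as.character(guide))
  if (nchar(guide) != 20L) stop("'guide' must be 20 bases long")
  if (grepl("[^ACGT]", guide)) stop("'guide' must be over A/C/G/T")
  has_ambig <- grepl("[^ACGT]", sequence)
  if (has_ambig)
    warning("sequence contains ambiguous bases; windows covering them are skipped")
  n <- nchar(sequence)
  glen <- 20L; plen <- nchar(pam)
  scan_strand <- function(seqstr, strand) {
    s <- Biostrings::DNAString(gsub("[^ACGT]", "N", seqstr))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(guide), s,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE)
    if (length(hits) == 0) return(NULL)
    starts <- Biostrings::start(hits)
    out <- lapply(starts, function(st) {
      if (st + glen + plen - 1L > n) return(NULL)
      window <- substr(seqstr, st, st + glen + plen - 1L)
      if (grepl("[^ACGT]", window)) return(NULL)   # ambiguous base: skip
      pam_seq <- substr(seqstr, st + glen, st + glen + plen - 1L)
      pam_ok <- all(vapply(seq_len(plen), function(k)
        iupac_char_match(substr(pam_seq, k, k), substr(pam, k, k)),
        logical(1)))
      if (!pam_ok) return(NULL)
      mm <- sum(strsplit(substr(seqstr, st, st + glen - 1L), "")[[1]] !=
                  strsplit(guide, "")[[1]])
      data.frame(start_local = st, strand = strand, mismatches = mm)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- scan_strand(sequence, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("[^ACGT]", "N", sequence))))
  rev <- scan_strand(rc, "-")
  rows <- list()
  if (!is.null(fwd)) {
    fwd$start <- fwd$start_local
    fwd$pos_bp <- fwd$start + 10L   # center = 11th base of the protospacer
    rows[[length(rows) + 1L]] <- fwd
  }
  if (!is.null(rev)) {
    # map reverse-strand local coordinates back to forward strand
    rev$start <- n - (rev$start_local + glen - 1L) + 1L
    rev$pos_bp <- n - (rev$start_local + 10L) + 1L
    rows[[length(rows) + 1L]] <- rev
  }
  if (!length(rows))
    return(data.frame(pos_bp = integer(0), strand = character(0),
                      mismatches = integer(0), match_type = character(0),
                      start = integer(0)))
  df <- do.call(rbind, rows)
  df$match_type <- ifelse(df$mismatches == 0L, "perfect", "mismatch")
  df <- df[order(df$pos_bp), c("pos_bp", "strand", "mismatches",
                               "match_type", "start")]
  rownames(df) <- NULL
  df
}

# Monotone one-to-one matching of sorted label positions to sorted site
# positions by dynamic programming.  Costs: matched pair |residual| (only if
# within tol), skipped site w_j * tol (w_j = expected occupancy, so missing
# an often-labeled perfect site is more surprising than a mismatch site),
# skipped label tol (off-target candidate).  For L1 costs on the line the
# optimal matching is non-crossing, so the DP over sorted sequences attains
# the global minimum.
match_labels_dp <- function(labels_bp, sites_bp, site_w, tol) {
  nl <- length(labels_bp); ns <- length(sites_bp)
  C <- matrix(Inf, nl + 1L, ns + 1L)
  choice <- matrix(0L, nl + 1L, ns + 1L)  # 1 match, 2 skip site, 3 skip label
  C[1, 1] <- 0
  for (j in seq_len(ns)) {
    C[1, j + 1] <- C[1, j] + site_w[j] * tol
    choice[1, j + 1] <- 2L
  }
  for (i in seq_len(nl)) {
    C[i + 1, 1] <- C[i, 1] + tol
    choice[i + 1, 1] <- 3L
    for (j in seq_len(ns)) {
      r <- abs(labels_bp[i] - sites_bp[j])
      m <- if (r <= tol) C[i, j] + r else Inf
      ss <- C[i + 1, j] + site_w[j] * tol
      sl <- C[i, j + 1] + tol
      best <- min(m, ss, sl)
      C[i + 1, j + 1] <- best
      choice[i + 1, j + 1] <- if (best == m) 1L else if (best == ss) 2L else 3L
    }
  }
  # traceback
  i <- nl; j <- ns
  site_of_label <- rep(NA_integer_, nl)
  while (i > 0 || j > 0) {
    ch <- choice[i + 1, j + 1]
    if (ch == 1L) { site_of_label[i] <- j; i <- i - 1; j <- j - 1 }
    else if (ch == 2L) j <- j - 1
    else i <- i - 1
  }
  list(cost = C[nl + 1, ns + 1], site_of_label = site_of_label)
}

#' Orient a measured molecule against a reference map and assign labels
#'
#' Both orientations of the molecule (positions measured from endpoint A, or
#' from endpoint B after reflection `x -> L - x`) are scored by the optimal
#' one-to-one matching of sorted label positions to sorted expected site
#' positions (tolerance-gated L1 assignment; unmatched perfect sites are
#' penalized more than unmatched single-mismatch sites, reflecting their
#' higher expected occupancy).  The lower-cost orientation wins; if the costs
#' differ by less than the tie margin (2 x `tol_bp`) the molecule is
#' `"ambiguous"`.
#'
#' @param meas a `molecule_measurement` with at least one label.
#' @param map a [reference_map()]; the measured molecule length must be
#'   within `length_tol` (default 15%) of the map length.
#' @param cal a [calibration()].
#' @param tol_bp per-site residual tolerance (default 300 bp, about 3x the
#'   single-molecule precision of long-amplicon label localization).
#' @param occupancy expected occupancy by match type, used as skip weights.
#' @param length_tol relative molecule/map length tolerance.
#' @return a `site_assignment`: orientation, per-site matched label indices,
#'   residuals, unassigned labels and total cost.  Orientation is
#'   `"incompatible"` when the lengths disagree.
#' @export
orient_and_assign <- function(meas, map, cal = calibration(), tol_bp = 300,
                              occupancy = c(perfect = 0.9, mismatch = 0.5),
                              length_tol = 0.15) {
  stopifnot(inherits(meas, "molecule_measurement"),
            inherits(map, "reference_map"))
  L <- meas$contour_length_bp
  if (nrow(meas$labels) < 1L) stop("measurement has no labels to assign")
  if (abs(L - map$length_bp) > length_tol * map$length_bp) {
    return(structure(list(orientation = "incompatible", matches = NULL,
                          cost = Inf, map_name = map$name),
                     class = "site_assignment"))
  }
  labs <- sort(meas$labels$arc_pos_bp)
  sites <- map$sites$pos_bp
  w <- unname(occupancy[map$sites$match_type])
  fwd <- match_labels_dp(labs, sites, w, tol_bp)
  rev_labs <- sort(L - labs)
  rev <- match_labels_dp(rev_labs, sites, w, tol_bp)
  # tie margin: 2x the per-site tolerance; a genuinely wrong orientation of
  # an asymmetric map misses whole sites and clears this easily
  tie <- abs(fwd$cost - rev$cost) < 2 * tol_bp
  pick_fwd <- fwd$cost <= rev$cost
  res <- if (pick_fwd) fwd else rev
  used_labs <- if (pick_fwd) labs else rev_labs
  orientation <- if (tie) "ambiguous" else if (pick_fwd) "A-first" else "B-first"
  matched <- !is.na(res$site_of_label)
  matches <- data.frame(site_idx = res$site_of_label[matched],
                        label_idx = which(matched),
                        residual_bp = used_labs[matched] -
                          sites[res$site_of_label[matched]])
  # ensure one row per site for downstream per-site tables
  structure(list(orientation = orientation,
                 matches = matches,
                 unassigned_labels = which(!matched),
                 oriented_labels_bp = used_labs,
                 cost = res$cost,
                 cost_other = if (pick_fwd) rev$cost else fwd$cost,
                 map_name = map$name),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("site_assignment vs '%s': %s, cost %.1f\n", x$map_name,
              x$orientation, x$cost))
  if (!is.null(x$matches) && nrow(x$matches))
    cat(sprintf("  %d matched site(s), max |residual| %.1f bp, %d unassigned label(s)\n",
                nrow(x$matches), max(abs(x$matches$residual_bp)),
                length(x$unassigned_labels)))
  invisible(x)
}

#' Call a translocation from hybrid label patterns
#'
#' Each measured molecule is tested as a fusion of a prefix of partner A and
#' a suffix of partner B: for every split of its ordered labels (and both
#' molecule orientations), the prefix labels are matched to A sites
#' (positions from the molecule start) and the suffix labels to B sites
#' (positions from the molecule end), and the minimum-cost split is kept.
#' Molecules with at least one matched site on each side support the fusion;
#' their per-molecule breakpoint bounds (between the innermost matched A and
#' B sites) are intersected.  A call is emitted only with
#' `support >= min_support` molecules.
#'
#' @param measurements list of `molecule_measurement`s.
#' @param map_A,map_B partner [reference_map()]s (A contributes the prefix).
#' @param cal a [calibration()].
#' @param min_support minimum supporting molecules for a confident call
#'   (default 10).
#' @param tol_bp per-site matching tolerance.
#' @param occupancy expected occupancy weights as in [orient_and_assign()].
#' @return a `translocation_call`: partners, support, per-partner breakpoint
#'   interval (bp), `called` flag, and per-molecule fits.
#' @export
call_translocation <- function(measurements, map_A, map_B, cal = calibration(),
                               min_support = 10L, tol_bp = 300,
                               occupancy = c(perfect = 0.9, mismatch = 0.5)) {
  sitesA <- map_A$sites$pos_bp; wA <- unname(occupancy[map_A$sites$match_type])
  sitesB <- map_B$sites$pos_bp; wB <- unname(occupancy[map_B$sites$match_type])
  dB <- sort(map_B$length_bp - sitesB)           # B sites as distance from B end
  wB_sorted <- wB[order(map_B$length_bp - sitesB)]
  per_mol <- list()
  for (m in measurements) {
    if (nrow(m$labels) < 2L) next
    L <- m$contour_length_bp
    labs0 <- sort(m$labels$arc_pos_bp)
    # wild-type gate: a molecule fully explained by one partner map alone
    # (its labels are not a hybrid pattern) must not support a fusion
    single_cost <- min(vapply(list(map_A, map_B), function(mp) {
      a <- tryCatch(orient_and_assign(m, mp, cal, tol_bp = tol_bp,
                                      occupancy = occupancy),
                    error = function(e) NULL)
      if (is.null(a) || identical(a$orientation, "incompatible")) Inf
      else a$cost
    }, numeric(1)))
    best <- NULL
    for (orient in c("fwd", "rev")) {
      labs <- if (orient == "fwd") labs0 else sort(L - labs0)
      nl <- length(labs)
      for (k in 1:(nl - 1)) {
        a_side <- match_labels_dp(labs[1:k], sitesA, wA, tol_bp)
        q <- sort(L - labs[(k + 1):nl])           # suffix as distance from end
        b_side <- match_labels_dp(q, dB, wB_sorted, tol_bp)
        if (all(is.na(a_side$site_of_label)) ||
            all(is.na(b_side$site_of_label)))
          next
        cost <- a_side$cost + b_side$cost
        if (is.null(best) || cost < best$cost) {
          # molecule = A[1..bA] + B[bB..LB]; with pA the innermost matched
          # A site, d the innermost matched B site's distance from the B end
          # (pB = LB - d):  pA <= bA <= L - d  and  LB - (L - pA) <= bB <= pB
          pA <- max(sitesA[stats::na.omit(a_side$site_of_label)])
          d <- min(dB[stats::na.omit(b_side$site_of_label)])
          best <- list(cost = cost, orient = orient, split = k,
                       bA_low = pA,
                       bA_high = L - d,
                       bB_low = map_B$length_bp - (L - pA),
                       bB_high = map_B$length_bp - d)
        }
      }
    }
    if (!is.null(best) && best$cost < single_cost)
      per_mol[[length(per_mol) + 1L]] <- best
  }
  support <- length(per_mol)
  interval <- function(lows, highs) {
    lo <- max(lows); hi <- min(highs)
    if (lo > hi) { lo <- stats::median(lows); hi <- stats::median(highs) }
    c(lo, hi)
  }
  if (support > 0) {
    iA <- interval(vapply(per_mol, `[[`, numeric(1), "bA_low"),
                   vapply(per_mol, `[[`, numeric(1), "bA_high"))
    iB <- interval(vapply(per_mol, `[[`, numeric(1), "bB_low"),
                   vapply(per_mol, `[[`, numeric(1), "bB_high"))
  } else {
    iA <- c(NA_real_, NA_real_); iB <- c(NA_real_, NA_real_)
  }
  structure(list(partner_A = map_A$name, partner_B = map_B$name,
                 support = support, called = support >= min_support,
                 breakpoint_interval_A_bp = iA,
                 breakpoint_interval_B_bp = iB,
                 min_support = min_support,
                 per_molecule = per_mol),
            class = "translocation_call")
}

#' @export
print.translocation_call <- function(x, ...) {
  cat(sprintf("translocation_call %s::%s — support %d (min %d): %s\n",
              x$partner_A, x$partner_B, x$support, x$min_support,
              if (x$called) "CALLED" else "low confidence, no call"))
  if (x$support > 0)
    cat(sprintf("  breakpoint %s: [%.0f, %.0f] bp; %s: [%.0f, %.0f] bp\n",
                x$partner_A, x$breakpoint_interval_A_bp[1],
                x$breakpoint_interval_A_bp[2], x$partner_B,
                x$breakpoint_interval_B_bp[1], x$breakpoint_interval_B_bp[2]))
  invisible(x)
}
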
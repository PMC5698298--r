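# File formats, run configuration, pipeline driver and command-line entry
# point binding the stages into reproducible runs.

#' Read / write a height image
#'
#' Images are stored as whitespace-delimited ASCII matrices of heights in nm
#' with a JSON sidecar `<path>.json` carrying `pixel_size_nm` and
#' `origin_nm`.  A missing pixel size is an error — it is never guessed.
#' (Binary TIFF I/O is intentionally not supported in this build; no TIFF
#' reader is part of the declared dependency set.)
#'
#' @param path image file path.
#' @param img a [height_image()].
#' @return `read_height_image` returns a [height_image()];
#'   `write_height_image` returns `path` invisibly.
#' @export
read_height_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("TIFF input is not supported; supply an ASCII matrix with a ",
         "'.json' sidecar (see write_height_image)")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar '", sidecar, "' with pixel_size_nm; ",
         "the pixel size is never guessed")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_nm))
    stop("sidecar lacks 'pixel_size_nm'")
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  height_image(m, pixel_size_nm = meta$pixel_size_nm,
               origin_nm = meta$origin_nm %||% c(0, 0),
               metadata = meta$metadata %||% list())
}

#' @rdname read_height_image
#' @export
write_height_image <- function(img, path) {
  stopifnot(inherits(img, "height_image"))
  utils::write.table(format(img$heights, digits = 9, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size_nm,
                            origin_nm = img$origin_nm,
                            metadata = img$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Nested stage parameters with defaults; unknown keys are rejected so typos
#' cannot silently fall back to defaults.  Round-trips losslessly through
#' JSON.
#'
#' @param ... overrides as nested lists: `sim`, `flatten`, `segment`,
#'   `trace`, `detect`, `cal`, plus top-level `seed`.
#' @return a validated `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    sim = list(),                     # sim_config() overrides
    flatten = list(line_order = 1L),
    segment = list(min_area_px = NULL, threshold_cfg = list()),
    trace = list(min_skel_px = 5L, ma_window_px = NULL),
    detect = list(prominence_min_nm = 1, min_sep_nm = 10,
                  sampling_step_nm = 1),
    cal = list(bp_per_nm = 2.94)
  )
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(ov)) {
    if (is.list(defaults[[k]]) && k != "sim") {
      bad <- setdiff(names(ov[[k]]), names(defaults[[k]]))
      if (length(bad))
        stop("unknown key(s) in '", k, "': ", paste(bad, collapse = ", "))
      defaults[[k]] <- utils::modifyList(defaults[[k]], ov[[k]])
    } else defaults[[k]] <- ov[[k]]
  }
  structure(defaults, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Analyze one height image end to end
#'
#' Flatten, segment, trace every component, and measure unflagged molecules.
#'
#' @param img a [height_image()].
#' @param cfg a [run_config()].
#' @return list with `measurements` (data.frame, one row per molecule-label,
#'   label-free molecules included with NA label fields), `traces`,
#'   `measure_objs`, and `n_flagged`.
#' @export
analyze_image <- function(img, cfg = run_config()) {
  cal <- calibration(cfg$cal$bp_per_nm)
  flat <- flatten(img, line_order = cfg$flatten$line_order)
  comps <- segment(flat, min_area_px = cfg$segment$min_area_px,
                   threshold_cfg = cfg$segment$threshold_cfg)
  traces <- list(); measures <- list(); rows <- list(); n_flagged <- 0L
  for (k in seq_len(comps$n)) {
    tr <- tryCatch(trace_molecule(comps, k, flat,
                                  min_skel_px = cfg$trace$min_skel_px,
                                  ma_window_px = cfg$trace$ma_window_px),
                   error = function(e) NULL)
    if (is.null(tr)) next
    traces[[length(traces) + 1L]] <- tr
    if (length(tr$flags) > 0) { n_flagged <- n_flagged + 1L; next }
    mm <- measure_molecule(flat, tr, cal,
                           prominence_min_nm = cfg$detect$prominence_min_nm,
                           min_sep_nm = cfg$detect$min_sep_nm,
                           sampling_step_nm = cfg$detect$sampling_step_nm)
    measures[[length(measures) + 1L]] <- mm
    lab <- mm$labels
    if (nrow(lab) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = k, contour_nm = mm$contour_length_nm,
        contour_bp = mm$contour_length_bp, label_index = NA_integer_,
        arc_nm = NA_real_, arc_bp = NA_real_, prominence_nm = NA_real_,
        merged = NA)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = k, contour_nm = mm$contour_length_nm,
        contour_bp = mm$contour_length_bp,
        label_index = seq_len(nrow(lab)), arc_nm = lab$arc_pos_nm,
        arc_bp = lab$arc_pos_bp, prominence_nm = lab$prominence_nm,
        merged = lab$merged)
    }
  }
  meas_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = integer(0), contour_nm = numeric(0),
               contour_bp = numeric(0), label_index = integer(0),
               arc_nm = numeric(0), arc_bp = numeric(0),
               prominence_nm = numeric(0), merged = logical(0))
  list(measurements = meas_df, traces = traces, measure_objs = measures,
       n_flagged = n_flagged, n_components = comps$n)
}

#' Run the full pipeline over a directory of frames
#'
#' Reads every ASCII frame in `input_dir`, optionally stitches frames into a
#' composite (using their origin metadata), analyzes each image, and writes
#' `measurements.tsv` and `report.json` (package version, config hash,
#' molecule counts) to `output_dir`.  Deterministic given the config seed;
#' refuses to overwrite existing outputs unless `overwrite = TRUE`.
#'
#' @param cfg a [run_config()].
#' @param input_dir directory of frame files (`*.txt` + `.json` sidecars).
#' @param output_dir output directory (created if needed).
#' @param stitch_frames stitch all input frames into one composite first.
#' @param overwrite allow replacing existing outputs.
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(cfg, input_dir, output_dir, stitch_frames = FALSE,
                         overwrite = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  files <- sort(list.files(input_dir, pattern = "\\.txt$", full.names = TRUE))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  meas_path <- file.path(output_dir, "measurements.tsv")
  rep_path <- file.path(output_dir, "report.json")
  if (!overwrite && (file.exists(meas_path) || file.exists(rep_path)))
    stop("outputs exist in '", output_dir, "'; use overwrite = TRUE")
  set.seed(cfg$seed)
  if (length(files) == 0L) {
    warning("no input frames found in '", input_dir, "'")
    imgs <- list()
  } else {
    imgs <- lapply(files, read_height_image)
  }
  if (stitch_frames && length(imgs) > 1L) imgs <- list(stitch(imgs))
  all_rows <- list(); n_comp <- 0L; n_flag <- 0L
  for (fi in seq_along(imgs)) {
    res <- analyze_image(imgs[[fi]], cfg)
    if (nrow(res$measurements)) {
      res$measurements$frame <- fi
      all_rows[[length(all_rows) + 1L]] <- res$measurements
    }
    n_comp <- n_comp + res$n_components
    n_flag <- n_flag + res$n_flagged
  }
  meas <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(molecule_id = integer(0), contour_nm = numeric(0),
               contour_bp = numeric(0), label_index = integer(0),
               arc_nm = numeric(0), arc_bp = numeric(0),
               prominence_nm = numeric(0), merged = logical(0),
               frame = integer(0))
  utils::write.table(meas, meas_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- list(package = "nanomapr",
                 version = as.character(utils::packageVersion("nanomapr")),
                 config_hash = rlang::hash(unclass(cfg)),
                 seed = cfg$seed,
                 n_frames = length(imgs),
                 n_components = n_comp,
                 n_flagged = n_flag,
                 n_molecules_measured = length(unique(
                   paste(meas$frame, meas$molecule_id))))
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Simulate labeled molecules and write frames to disk
#'
#' One frame per molecule (frames auto-sized to the conformation when
#' `autosize`), written as ASCII + JSON sidecar along with a ground-truth
#' TSV (`truth.tsv`: frame, molecule_id, length_bp, contour_nm, label_kind,
#' label_pos_bp, label_arc_nm, bound).
#'
#' @param cfg a [sim_config()].
#' @param map a [reference_map()] defining molecule length and sites.
#' @param n_molecules number of molecules.
#' @param output_dir destination directory.
#' @param autosize size each frame to its molecule instead of
#'   `cfg$frame_size_px`.
#' @return invisibly, the truth table.
#' @export
simulate_frames <- function(cfg, map, n_molecules, output_dir,
                            autosize = TRUE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  truth_all <- list()
  for (i in seq_len(n_molecules)) {
    fr <- with_seed(derive_seed(cfg$seed, i), {
      mol <- sim_molecule(sprintf("mol%04d", i), map$length_bp, cfg)
      mol <- apply_labels(mol, map, cfg)
      fcfg <- cfg
      if (autosize) {
        pad <- ceiling((cfg$tip_radius_nm + 6 * cfg$pixel_size_nm) /
                         cfg$pixel_size_nm)
        span <- apply(mol$path, 2, function(v) diff(range(v)))
        fcfg$frame_size_px <- as.integer(
          pmax(64L, ceiling(span / cfg$pixel_size_nm) + 2L * pad))
        ctr <- c(fcfg$frame_size_px[1], fcfg$frame_size_px[2]) *
          cfg$pixel_size_nm / 2
        render_frame(mol, fcfg,
                     placements = list(list(center = ctr, angle = 0)))
      } else render_frame(mol, fcfg)
    })
    path <- file.path(output_dir, sprintf("frame%04d.txt", i))
    write_height_image(fr$image, path)
    tt <- fr$truth$table
    tt$frame <- i
    truth_all[[i]] <- tt
  }
  truth <- do.call(rbind, truth_all)
  utils::write.table(truth, file.path(output_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (frames from a map), `analyze` (frames to
#' measurements), `ladder` (pooled sizing of a ladder TSV), `map`
#' (guide-site search in a FASTA), `translocate` (breakpoint call from a
#' measurements TSV and two maps).  Intended to be called from the
#' `inst/cli/nanomap` wrapper via `Rscript`; returns the exit status.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
nanomap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nanomap <simulate|analyze|ladder|map|translocate> [options]",
    "  simulate    --map map.tsv --n N --out dir [--seed S]",
    "  analyze     --in dir --out dir [--config cfg.json] [--stitch]",
    "  ladder      --in measurements.tsv --truth l1,l2,... --out out.json",
    "  map         --fasta seq.fa --guide SEQ20 [--pam NGG] [--mm K] --out map.tsv --name NAME",
    "  translocate --in measurements.tsv --map-a a.tsv --map-b b.tsv --out out.json",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        map <- read_reference_map(req_opt(opt, "map"))
        cfg <- sim_config(seed = as.integer(opt$seed %||% 1))
        simulate_frames(cfg, map, as.integer(req_opt(opt, "n")),
                        req_opt(opt, "out"))
        0L
      },
      analyze = {
        cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
               else run_config()
        run_pipeline(cfg, req_opt(opt, "in"), req_opt(opt, "out"),
                     stitch_frames = isTRUE(opt$stitch), overwrite = TRUE)
        0L
      },
      ladder = {
        df <- utils::read.table(req_opt(opt, "in"), header = TRUE, sep = "\t")
        truths <- as.numeric(strsplit(req_opt(opt, "truth"), ",")[[1]])
        tabs <- split(df$measured_bp, df$species)
        res <- ladder_resolution(tabs, truths)
        jsonlite::write_json(list(resolved_step_bp =
                                    if (is.finite(res)) as.numeric(res) else "unresolved"),
                             req_opt(opt, "out"), auto_unbox = TRUE)
        0L
      },
      map = {
        seqs <- read_fasta_simple(req_opt(opt, "fasta"))
        sites <- find_guide_sites(seqs[[1]], req_opt(opt, "guide"),
                                  pam = opt$pam %||% "NGG",
                                  max_mismatches = as.integer(opt$mm %||% 0))
        m <- reference_map(opt$name %||% names(seqs)[1], nchar(seqs[[1]]),
                           sites$pos_bp, sites$match_type, sites$strand)
        write_reference_map(m, req_opt(opt, "out"))
        0L
      },
      translocate = {
        df <- utils::read.table(req_opt(opt, "in"), header = TRUE, sep = "\t")
        ms <- measurements_from_table(df)
        call <- call_translocation(ms, read_reference_map(req_opt(opt, "map-a")),
                                   read_reference_map(req_opt(opt, "map-b")))
        jsonlite::write_json(list(called = call$called,
                                  support = call$support,
                                  breakpoint_A_bp = call$breakpoint_interval_A_bp,
                                  breakpoint_B_bp = call$breakpoint_interval_B_bp),
                             req_opt(opt, "out"), auto_unbox = TRUE)
        0L
      },
      { message(usage); 1L })
  }, error = function(e) { message("nanomap: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE; i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opt
}

req_opt <- function(opt, key) {
  if (is.null(opt[[key]])) stop("missing required option --", key)
  opt[[key]]
}

read_fasta_simple <- function(path) {
  x <- readLines(path)
  hdr <- grepl("^>", x)
  id <- cumsum(hdr)
  seqs <- tapply(x[!hdr], id[!hdr], paste, collapse = "")
  names(seqs) <- sub("^>", "", sub("\\s.*", "", x[hdr]))
  as.list(seqs)
}

# Rebuild minimal molecule_measurement objects from a measurements table
# (as written by run_pipeline) for downstream map matching.
measurements_from_table <- function(df, cal = calibration()) {
  if (is.null(df$frame)) df$frame <- 1L
  key <- paste(df$frame, df$molecule_id)
  lapply(split(df, key), function(d) {
    labs <- d[!is.na(d$label_index), , drop = FALSE]
    structure(list(trace = NULL,
                   labels = data.frame(arc_pos_nm = labs$arc_nm,
                                       prominence_nm = labs$prominence_nm,
                                       width_nm = NA_real_,
                                       merged = labs$merged,
                                       arc_pos_bp = labs$arc_bp),
                   contour_length_nm = d$contour_nm[1],
                   contour_length_bp = d$contour_bp[1],
                   orientation = "unresolved",
                   bp_per_nm = cal$bp_per_nm),
              class = "molecule_measurement")
  })
}
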
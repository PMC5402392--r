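# Configuration, file I/O and the command-line dispatcher binding the
# pipeline stages (simulate -> reconstruct -> quantify -> analyze) into
# reproducible runs.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @return Numeric array with the image data; voxel dimensions are attached
#'   as attribute `voxel` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel") <- RNifti::pixdim(img)
  out
}

#' Write a NIfTI volume
#'
#' @param vol Numeric array.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel Voxel size (mm), length matching `dim(vol)`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel = c(0.1, 0.1, 0.5)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Check that co-analyzed volumes share a grid
#'
#' @param ... Arrays to compare.
#' @return `TRUE` invisibly; error on mismatch.
#' @export
check_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  for (i in seq_along(dims)[-1])
    if (!identical(dims[[1]], dims[[i]]))
      stop("volume geometry mismatch: ", paste(dims[[1]], collapse = "x"),
           " vs ", paste(dims[[i]], collapse = "x"))
  invisible(TRUE)
}

#' Write an RGB section as PNG
#'
#' @param img Numeric array `h x w x 3`, 8-bit values 0..255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read an RGB section PNG as an 8-bit array
#'
#' @param path PNG file.
#' @return Numeric array `h x w x 3` with values 0..255.
#' @export
read_section_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Default run configuration
#'
#' Round-trippable configuration bundling the acquisition protocol, the
#' single-point constraint set, the phantom specification and seeds.
#'
#' @return Nested list suitable for [write_config()].
#' @export
default_config <- function() {
  pr <- default_protocols()
  list(
    constraints = list(R = 19, T2B_us = 10, T2F_R1F = 0.022, R1B = 1),
    protocol = list(
      mt = list(TR_ms = 1000 * pr$mt$TR, flip_deg = pr$mt$flip,
                pulse = list(shape = "gaussian", duration_ms = 10,
                             effective_flip_deg = 900, offset_hz = 4500)),
      t1w = list(TR_ms = 16, flip_deg = 16),
      pdw = list(TR_ms = 16, flip_deg = 3),
      b0 = list(TR_ms = 20, flip_deg = 8, TE_ms = c(2.4, 4.1)),
      afi = list(TR1_ms = 13, TR2_ms = 65, flip_deg = 60)),
    phantom = list(group = "control", dim = c(96L, 96L, 24L),
                   voxel_mm = c(0.1, 0.1, 0.5), jitter_sd = 0),
    noise = list(sigma_frac_wm = 0.01),
    seed = 1L)
}

#' Write / read a YAML run configuration
#'
#' @param config Nested configuration list.
#' @param path YAML file path.
#' @return `read_config` returns the configuration list; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

.constraints_from_config <- function(config) {
  cc <- config$constraints
  single_point_constraints(R = cc$R, T2B = cc$T2B_us * 1e-6,
                           T2F_R1F = cc$T2F_R1F, R1B = cc$R1B)
}

.protocols_from_config <- function(config) {
  pc <- config$protocol
  list(
    mt = spgr_protocol(pc$mt$TR_ms / 1000, pc$mt$flip_deg,
                       mt_pulse = mt_pulse(pc$mt$pulse$shape,
                                           pc$mt$pulse$duration_ms / 1000,
                                           pc$mt$pulse$effective_flip_deg,
                                           pc$mt$pulse$offset_hz),
                       label = "mt_w"),
    t1w = spgr_protocol(pc$t1w$TR_ms / 1000, pc$t1w$flip_deg, label = "t1_w"),
    pdw = spgr_protocol(pc$pdw$TR_ms / 1000, pc$pdw$flip_deg, label = "pd_w"),
    b0 = spgr_protocol(pc$b0$TR_ms / 1000, pc$b0$flip_deg,
                       TEs = pc$b0$TE_ms / 1000, label = "b0_gre"),
    afi = list(tr1 = pc$afi$TR1_ms / 1000, tr2 = pc$afi$TR2_ms / 1000,
               flip = pc$afi$flip_deg))
}

.write_manifest <- function(out_dir, stage, config, seed, inputs = list()) {
  man <- list(stage = stage, seed = seed, inputs = inputs,
              config_hash = sum(utf8ToInt(paste(
                utils::capture.output(utils::str(config)), collapse = ""))),
              package_version = as.character(utils::packageVersion("mpfkit")))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline on a synthetic session
#'
#' Simulates a phantom acquisition (one animal per group), reconstructs MPF
#' maps, renders and quantifies LFB sections, assembles the ROI table and
#' writes maps (NIfTI), sections (PNG), tables (CSV) and a statistics
#' summary (JSON) under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all stochastic stages derive from it.
#' @param config Configuration list (see [default_config()]).
#' @param n_per_group Animals per group in the statistics cohort.
#' @return Invisible list with the reconstructed `quant_maps` per group, the
#'   aggregated ROI table and the statistics report.
#' @export
run_end_to_end <- function(out_dir, seed = 1L, config = default_config(),
                           n_per_group = 7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  constraints <- .constraints_from_config(config)
  protocols <- .protocols_from_config(config)
  maps <- list()
  for (g in c("control", "cuprizone")) {
    ph <- make_phantom(phantom_spec(
      group = g, dim = config$phantom$dim, voxel = config$phantom$voxel_mm,
      jitter_sd = config$phantom$jitter_sd, seed = seed))
    sigma <- config$noise$sigma_frac_wm * reference_wm_signal(ph, protocols)
    acq <- simulate_acquisition(ph, protocols, sigma = sigma,
                                seed = seed + match(g, c("control", "cuprizone")),
                                constraints = constraints)
    qm <- reconstruct_session(acq, constraints, noise_floor = sigma)
    write_volume(qm$mpf, file.path(out_dir, paste0("mpf_", g, ".nii.gz")),
                 config$phantom$voxel_mm)
    sl <- qm$mpf[, , ceiling(dim(qm$mpf)[3] / 2)]
    secs <- render_lfb_sections(sl, noise_sd = 2, seed = seed + 10)
    for (s in seq_along(secs))
      write_section_png(secs[[s]],
                        file.path(out_dir, sprintf("lfb_%s_s%d.png", g, s)))
    maps[[g]] <- qm
  }
  raw <- simulate_cohort(n_per_group = n_per_group, seed = seed + 100)
  tbl <- aggregate_measurements(raw, collapse = "structure")
  utils::write.csv(tbl, file.path(out_dir, "roi_table.csv"),
                   row.names = FALSE)
  report <- analyze_roi_table(tbl)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "end-to-end", config, seed)
  invisible(list(maps = maps, table = tbl, report = report))
}

#' Statistical report from an aggregated ROI table
#'
#' Runs the validation statistics on per-animal structure means holding both
#' measures: group comparisons (MANOVA, t-tests, Cohen's d) per measure, and
#' MRI-histology correlation/regression on structure means, pooled and per
#' group, with Fisher r-to-z and ANCOVA group-equality tests.
#'
#' @param tbl Aggregated table with measures `mpf_percent` and
#'   `lfb_od_percent` (see [aggregate_measurements()]).
#' @return Nested list (JSON-ready) with elements `groups` (per measure) and
#'   `correlation` (pooled / per group regressions, comparisons).
#' @export
analyze_roi_table <- function(tbl) {
  out <- list()
  for (msr in unique(tbl$measure)) {
    cg <- compare_groups(tbl[tbl$measure == msr, ])
    out$groups[[msr]] <- list(
      manova = cg$manova,
      structures = cg$structures)
  }
  wide <- stats::reshape(tbl, idvar = c("animal_id", "group", "structure"),
                         timevar = "measure", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (all(c("mpf_percent", "lfb_od_percent") %in% names(wide))) {
    # structure means per group for the structure-averaged regressions
    sm <- stats::aggregate(cbind(mpf_percent, lfb_od_percent) ~
                             structure + group, data = wide, FUN = mean)
    regs <- list(
      pooled_structures = pearson_regression(sm$lfb_od_percent,
                                             sm$mpf_percent),
      pooled_individual = pearson_regression(wide$lfb_od_percent,
                                             wide$mpf_percent))
    for (g in unique(sm$group))
      regs[[paste0(g, "_structures")]] <-
        pearson_regression(sm$lfb_od_percent[sm$group == g],
                           sm$mpf_percent[sm$group == g])
    gs <- unique(sm$group)
    if (length(gs) == 2) {
      r1 <- regs[[paste0(gs[1], "_structures")]]
      r2 <- regs[[paste0(gs[2], "_structures")]]
      regs$fisher_r_comparison <-
        fisher_compare_correlations(r1$r, r1$n, r2$r, r2$n)
      regs$ancova <- ancova_compare_lines(sm$lfb_od_percent, sm$mpf_percent,
                                          sm$group)
    }
    out$correlation <- lapply(regs, unclass)
  }
  out
}

#' Command-line dispatcher
#'
#' Entry point behind the `mpfkit` command script.  Subcommands:
#' `simulate`, `reconstruct`, `quantify-histology`, `analyze`,
#' `repeatability`, `end-to-end`.  Flags are `--key value` pairs; every
#' stochastic stage takes `--seed`.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code: 0 success, 1 stage failure, 2 usage error.
#' @export
cli_dispatch <- function(argv) {
  usage <- function() {
    cat("usage: mpfkit <simulate|reconstruct|quantify-histology|analyze|",
        "repeatability|end-to-end> [--seed N] [--out DIR] [--config FILE]",
        "[--table FILE] [--mt/--t1w/--pdw/--b0/--b1 FILE]\n", sep = "")
    2L
  }
  if (length(argv) < 1) return(usage())
  cmd <- argv[1]
  known <- c("simulate", "reconstruct", "quantify-histology", "analyze",
             "repeatability", "end-to-end")
  if (!cmd %in% known) return(usage())
  opts <- list()
  rest <- argv[-1]
  i <- 1
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--") || i == length(rest)) return(usage())
    opts[[sub("^--", "", rest[i])]] <- rest[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opts$seed %||% 1)
  out <- opts$out %||% "."
  config <- if (!is.null(opts$config)) read_config(opts$config)
            else default_config()
  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        constraints <- .constraints_from_config(config)
        protocols <- .protocols_from_config(config)
        ph <- make_phantom(phantom_spec(group = config$phantom$group,
                                        dim = config$phantom$dim,
                                        voxel = config$phantom$voxel_mm,
                                        jitter_sd = config$phantom$jitter_sd,
                                        seed = seed))
        sigma <- config$noise$sigma_frac_wm *
          reference_wm_signal(ph, protocols)
        acq <- simulate_acquisition(ph, protocols, sigma, seed, constraints)
        vx <- config$phantom$voxel_mm
        for (nm in c("mt_w", "t1_w", "pd_w"))
          write_volume(acq[[nm]], file.path(out, paste0(nm, ".nii.gz")), vx)
        vx2 <- c(vx[1] * 2, vx[2] * 2, vx[3])
        for (nm in c("b0_phase1", "b0_phase2", "afi1", "afi2"))
          write_volume(acq[[nm]], file.path(out, paste0(nm, ".nii.gz")), vx2)
        truth <- structure_map_means(100 * ph$f, ph)
        utils::write.csv(truth, file.path(out, "ground_truth.csv"),
                         row.names = FALSE)
        .write_manifest(out, cmd, config, seed)
        0L
      },
      "reconstruct" = {
        dir.create(dirname(opts$outfile %||% file.path(out, "mpf.nii.gz")),
                   showWarnings = FALSE, recursive = TRUE)
        vols <- lapply(opts[c("mt", "t1w", "pdw")], read_volume)
        do.call(check_same_grid, vols)
        b0 <- if (!is.null(opts$b0)) read_volume(opts$b0)
        b1 <- if (!is.null(opts$b1)) read_volume(opts$b1)
        dxy <- dim(vols$mt)[1:2]
        if (!is.null(b0)) b0 <- upsample_xy(b0, dxy)
        if (!is.null(b1)) b1 <- upsample_xy(b1, dxy)
        qm <- reconstruct_mpf_map(vols$mt, vols$t1w, vols$pdw, b0, b1,
                                  .protocols_from_config(config),
                                  .constraints_from_config(config),
                                  noise_floor = as.numeric(opts$`noise-floor`
                                                           %||% 0))
        message(sprintf("invalid-voxel fraction: %.3f",
                        qm$invalid_fraction))
        write_volume(qm$mpf, opts$outfile %||% file.path(out, "mpf.nii.gz"),
                     config$phantom$voxel_mm)
        0L
      },
      "quantify-histology" = {
        imgs <- sort(list.files(opts$images, "\\.png$", full.names = TRUE))
        if (!length(imgs)) stop("no PNG sections in ", opts$images)
        sections <- lapply(imgs, read_section_png)
        rois <- lapply(sort(list.files(opts$rois, "\\.png$",
                                       full.names = TRUE)),
                       function(p) read_section_png(p)[, , 1] > 127)
        names(rois) <- sub("\\.png$", "",
                           basename(sort(list.files(opts$rois, "\\.png$"))))
        h <- dim(sections[[1]])[1]; w <- dim(sections[[1]])[2]
        corner <- function(ri, ci) {
          m <- matrix(FALSE, h, w); m[ri, ci] <- TRUE; m
        }
        bg <- list(corner(1:5, 1:5), corner(1:5, (w - 4):w),
                   corner((h - 4):h, 1:5), corner((h - 4):h, (w - 4):w))
        raw <- quantify_lfb_sections(sections, rois, bg)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(raw, file.path(out, "histology_raw.csv"),
                         row.names = FALSE)
        0L
      },
      "analyze" = {
        tbl <- utils::read.csv(opts$table, stringsAsFactors = FALSE)
        report <- analyze_roi_table(tbl)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(report, file.path(out, "report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        0L
      },
      "repeatability" = {
        rs <- simulate_rescan(seed = seed)
        res <- lapply(split(rs, rs$structure), function(d)
          unclass(bland_altman(d$scan1, d$scan2)))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(res, file.path(out, "repeatability.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        0L
      },
      "end-to-end" = {
        run_end_to_end(out, seed, config)
        0L
      })
  }, error = function(e) {
    message("mpfkit ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  status
}
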
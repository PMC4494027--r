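#' Default pipeline configuration
#'
#' Returns the full configuration of the simulation-and-analysis pipeline
#' as a nested list. Defaults describe the stated experimental world: TR
#' 2.5 s, 10 s blocks with 7.5 s fixation, 12 blocks/session, 7--11
#' invisible-experiment and 3--5 localizer sessions per subject, ~80%
#' "guessed" reports with objective accuracy at chance, 100-voxel ROIs with
#' a 50/100/150 sweep, C = 1 linear classification, and Bonferroni families
#' of 7 (temporal) and 4 (frontal).
#'
#' @param seed master seed (mandatory; every stochastic stage derives its
#'   seed from it).
#' @param n_subjects number of simulated subjects.
#' @param regions region names to simulate/analyse (subset of
#'   [language_region_names()]).
#' @param grid_dim spatial grid; must fit the regions' parcels.
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, n_subjects = 15L,
                           regions = language_region_names(),
                           grid_dim = c(27, 29, 12)) {
  cfg <- list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    grid_dim = as.integer(grid_dim),
    regions = regions,
    design = list(tr_s = 2.5, block_s = 10, fix_s = 7.5, initial_fix_s = 10,
                  blocks_per_cond = 6),
    sessions = list(main = c(7L, 11L), localizer = c(3L, 5L)),
    signal = list(
      baseline = 100,
      # visible localizer: strong region-level selectivity (drives the z-map)
      mean_amp_localizer = list(sentences = 1.5, nonwords = 0.6),
      # invisible main experiment: equal mean response across conditions
      # (the univariate control is null in this world), pattern only
      mean_amp_main = list(sentences = 0.3, nonwords = 0.3),
      pattern_sd = 0.035,
      signal_regions = c("L_post_STS", "L_mid_frontal_gyrus"),
      nonselective_regions = c("L_sup_frontal_gyrus"),
      global_offset = list(sentences = 0, nonwords = 0)),
    noise = list(white_sd = 1, ar1 = 0.3, drift_amp = 0.5,
                 drift_period_s = 128),
    awareness = list(p_guessed = list(sentences = 0.803, nonwords = 0.826),
                     p_correct_given_guessed = 0.517,
                     p_correct_given_knew = list(sentences = 0.624,
                                                 nonwords = 0.865)),
    preproc = list(discard_vols = 4L, smooth_localizer_fwhm_mm = 6,
                   smooth_main_fwhm_mm = 0, lag_trs = 3L),
    roi = list(main_size = 100L, sizes = c(50L, 100L, 150L),
               connectivity = 26L),
    classifier = list(C = 1),
    stats = list(alpha = 0.05, chance = 50))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' The file representation round-trips losslessly. `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must specify a seed")
  base <- default_config(seed = cfg$seed)
  cfg <- utils::modifyList(unclass(base), cfg)
  for (nm in c("grid_dim", "n_subjects", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  class(cfg) <- c("pipeline_config", "list")
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), cfg$n_subjects >= 1)
  if (max(cfg$roi$sizes, cfg$roi$main_size) < 1) stop("roi sizes must be >= 1")
  invisible(cfg)
}

# stable per-subject/stage seed derived from the master seed (< 2^31)
derive_seed <- function(master, subject, salt = 0L) {
  as.integer((as.numeric(master) * 48271 + subject * 1299721 +
                salt * 69621) %% 2147483647 + 1)
}

#' Simulate all sessions of one subject
#'
#' Builds the subject's fixed condition pattern maps (seeded, shared across
#' sessions), then simulates localizer sessions (visible: amplitudes scaled
#' by `localizer_gain`, no awareness reports needed) and main-experiment
#' sessions (invisible scale, awareness reports drawn from the behavioral
#' model).
#'
#' @param cfg a `pipeline_config`.
#' @param subject subject index (seeds derive from `cfg$seed` and this).
#' @param masks named mask list from [language_mask_set()] (built from the
#'   config when NULL).
#' @return list with `localizer` and `main`, each a list of `runs` and
#'   `events`, plus `masks`.
#' @export
simulate_subject <- function(cfg, subject = 1L, masks = NULL) {
  if (is.null(masks))
    masks <- language_mask_set(cfg$grid_dim, names = cfg$regions)
  params <- do.call(design_params, cfg$design)
  gd <- cfg$grid_dim

  # per-subject condition amplitude maps: region-level selectivity (strong
  # in the visible localizer, condition-equal in the invisible main
  # experiment) plus a fixed voxelwise pattern component in the signal
  # regions, shared between the two experiments
  amp_loc <- list(); amp_main <- list()
  pat_seed <- derive_seed(cfg$seed, subject, 1L)
  conds <- params$conditions
  pat <- withr_seed(pat_seed, {
    lapply(conds, function(cn)
      array(stats::rnorm(prod(gd), sd = 1), dim = gd))
  })
  names(pat) <- conds
  for (cn in conds) {
    al <- array(0, dim = gd); am <- array(0, dim = gd)
    for (rn in names(masks)) {
      m <- masks[[rn]]
      if (!(rn %in% cfg$signal$nonselective_regions)) {
        al[m] <- al[m] + cfg$signal$mean_amp_localizer[[cn]]
        am[m] <- am[m] + cfg$signal$mean_amp_main[[cn]]
      }
      if (rn %in% cfg$signal$signal_regions && cfg$signal$pattern_sd > 0) {
        al[m] <- al[m] + cfg$signal$pattern_sd * pat[[cn]][m]
        am[m] <- am[m] + cfg$signal$pattern_sd * pat[[cn]][m]
      }
    }
    amp_loc[[cn]] <- al; amp_main[[cn]] <- am
  }
  goff <- unlist(cfg$signal$global_offset)
  sig_loc <- signal_spec(baseline = cfg$signal$baseline, amplitude = amp_loc,
                         global_offset = goff * 0, localizer_gain = 1)
  sig_main <- signal_spec(baseline = cfg$signal$baseline,
                          amplitude = amp_main, global_offset = goff,
                          localizer_gain = 1)

  n_main <- session_count(cfg$sessions$main, derive_seed(cfg$seed, subject, 2L))
  n_loc <- session_count(cfg$sessions$localizer,
                         derive_seed(cfg$seed, subject, 3L))
  sim_session <- function(s, localizer) {
    salt <- if (localizer) 100L + s else 200L + s
    ev <- build_session_timeline(params, seed = derive_seed(cfg$seed, subject,
                                                            salt),
                                 session_id = s)
    if (!localizer) {
      am <- do.call(awareness_model,
                    c(lapply(cfg$awareness, function(x)
                        if (is.list(x)) unlist(x) else x),
                      list(seed = derive_seed(cfg$seed, subject, salt + 400L))))
      ev <- simulate_awareness(ev, am)
    }
    ns <- noise_spec(white_sd = cfg$noise$white_sd, ar1 = cfg$noise$ar1,
                     drift_amp = cfg$noise$drift_amp,
                     drift_period_s = cfg$noise$drift_period_s,
                     seed = derive_seed(cfg$seed, subject, salt + 800L))
    run <- simulate_bold(ev, if (localizer) sig_loc else sig_main, ns, gd)
    list(run = run, events = ev)
  }
  loc <- lapply(seq_len(n_loc), sim_session, localizer = TRUE)
  main <- lapply(seq_len(n_main), sim_session, localizer = FALSE)
  list(localizer = list(runs = lapply(loc, `[[`, "run"),
                        events = lapply(loc, `[[`, "events")),
       main = list(runs = lapply(main, `[[`, "run"),
                   events = lapply(main, `[[`, "events")),
       masks = masks)
}

# draw a session count from a fixed value or an inclusive [lo, hi] range
session_count <- function(spec, seed) {
  spec <- as.integer(spec)
  if (length(spec) == 1L) return(spec)
  withr_seed(seed, sample(seq(spec[1], spec[2]), 1L))
}

#' Run one subject through the full analysis
#'
#' Preprocess + localizer GLM, ROI growth at each configured size, pattern
#' preparation, multivariate LOSO decoding per ROI and size, and the
#' univariate control at the main ROI size.
#'
#' @param cfg a `pipeline_config`.
#' @param subject subject index.
#' @param masks optional precomputed mask set.
#' @return data.frame, one row per ROI x size x analysis kind.
#' @export
analyze_subject <- function(cfg, subject = 1L, masks = NULL) {
  dat <- simulate_subject(cfg, subject, masks)
  masks <- dat$masks
  pp <- cfg$preproc

  # localizer: discard, optional smoothing, concatenated GLM contrast z-map
  loc_runs <- dat$localizer$runs
  loc_events <- dat$localizer$events
  for (s in seq_along(loc_runs)) {
    de <- discard_initial_volumes(loc_runs[[s]], loc_events[[s]],
                                  pp$discard_vols)
    r <- de$run
    if (pp$smooth_localizer_fwhm_mm > 0)
      r <- smooth_bold(r, pp$smooth_localizer_fwhm_mm)
    loc_runs[[s]] <- r
    loc_events[[s]] <- de$events
  }
  zm <- fit_localizer(loc_runs, loc_events)

  main_runs <- dat$main$runs
  main_events <- dat$main$events
  if (pp$smooth_main_fwhm_mm > 0) {
    for (s in seq_along(main_runs))
      main_runs[[s]] <- smooth_bold(main_runs[[s]], pp$smooth_main_fwhm_mm)
  }
  bseed <- derive_seed(cfg$seed, subject, 7000L)

  rows <- list()
  for (rn in names(masks)) {
    for (sz in cfg$roi$sizes) {
      roi <- grow_roi(zm, masks[[rn]], sz,
                      connectivity = cfg$roi$connectivity, name = rn)
      bp <- prepare_patterns(main_runs, main_events, roi,
                             lag_trs = pp$lag_trs,
                             discard_vols = pp$discard_vols,
                             balance_seed = bseed)
      res <- loso_decode(bp, C = cfg$classifier$C, roi_size = sz)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, roi = rn, roi_size = sz, kind = "multivariate",
        accuracy = res$mean_accuracy, n_folds = res$n_folds, mean_z = roi$mean_z)
      if (sz == cfg$roi$main_size) {
        ures <- univariate_decode(main_runs, main_events, roi,
                                  lag_trs = pp$lag_trs,
                                  discard_vols = pp$discard_vols,
                                  balance_seed = bseed, C = cfg$classifier$C)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, roi = rn, roi_size = sz, kind = "univariate",
          accuracy = ures$mean_accuracy, n_folds = ures$n_folds,
          mean_z = roi$mean_z)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full multi-subject pipeline
#'
#' Simulates every subject, runs the per-subject analysis, and computes
#' group statistics (one-tailed t vs chance with family-wise Bonferroni
#' thresholds) for each ROI size and analysis kind. When `out_dir` is
#' given, writes the subject table, group tables and a JSON manifest
#' (seeds, config hash, file list).
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir optional output directory.
#' @param verbose print stage progress.
#' @return list with `subject_results` (data.frame) and `group` (list of
#'   group report data.frames keyed by `kind_size`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = FALSE) {
  validate_config(cfg)
  masks <- language_mask_set(cfg$grid_dim, names = cfg$regions)
  subj <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    if (verbose) message(sprintf("subject %d/%d", i, cfg$n_subjects))
    subj[[i]] <- analyze_subject(cfg, i, masks)
  }
  res <- do.call(rbind, subj)
  fams <- language_region_families(cfg$regions)
  group <- list()
  for (kind in unique(res$kind)) {
    for (sz in unique(res$roi_size[res$kind == kind])) {
      sub <- res[res$kind == kind & res$roi_size == sz, ]
      g <- group_report(sub, families = fams, alpha = cfg$stats$alpha,
                        chance = cfg$stats$chance)
      group[[sprintf("%s_%d", kind, sz)]] <- g
    }
  }
  out <- list(subject_results = res, group = group, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    f <- file.path(out_dir, "subject_results.tsv")
    write_table_tsv(res, f); files <- c(files, f)
    for (nm in names(group)) {
      f <- file.path(out_dir, sprintf("group_%s.tsv", nm))
      write_table_tsv(group[[nm]], f); files <- c(files, f)
    }
    f <- file.path(out_dir, "config.yaml")
    write_config(cfg, f); files <- c(files, f)
    manifest <- list(
      package = "blockmvpa",
      version = as.character(utils::packageVersion("blockmvpa")),
      seed = cfg$seed,
      config_hash = digest::digest(unclass(cfg)),
      files = basename(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
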
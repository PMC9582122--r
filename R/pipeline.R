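IMAGE_CLASSES <- c("first_of_experiment", "isi_to_image", "image_to_image")

#' Default run configuration
#'
#' One nested list drives the whole pipeline; it round-trips losslessly
#' through YAML ([read_run_config()]). A single integer seed is fanned out to
#' per-stage child seeds by fixed documented offsets (simulation +101, trial
#' split +202, encoding +303, decoding +404).
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      n_subjects = 13L,
      per_region = list(frontal = 2L, temporal = 2L, parietal = 1L,
                        insula = 1L)),
    schedule = list(n_series = 7L, images_per_series = 5L,
                    image_duration = 2000, isi_duration = 6000),
    effects = list(null = FALSE),
    coupling = list(enabled = TRUE),
    noise = list(exponent = 1, amplitude = 1, broadband_amplitude = 1,
                 band = c(10, 100), fs = 1000),
    analysis = list(alpha = 0.05, n_perm = 1000L, folds = 10L,
                    n_train = 17L, test_frac = 0.2, repeats = 10L,
                    gc_order = 5L, sizes = NULL))
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; keys present override [default_config()] values.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full pipeline: simulate, preprocess, spectra, PCA, encode,
#' decode, connectivity
#'
#' Executes every stage in order on synthetic data generated from the
#' configuration; identical configuration and seed give identical outputs.
#' Stage artifacts are written as CSVs under `out_dir` when given.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_run_config()].
#' @param out_dir Optional output directory for stage CSVs.
#' @param stages Character vector of optional later stages to run after the
#'   mandatory simulate/preprocess/spectra/pca stages; subset of
#'   `c("encode", "decode", "connectivity")`.
#' @return A run report list: per-stage row counts, encoding results,
#'   first-vs-rest contrast, decoding curve, connectivity contrast, seed.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         stages = c("encode", "decode", "connectivity")) {
  seed <- config$seed
  cfg_a <- config$analysis

  sched_cfg <- schedule_config(
    n_series = config$schedule$n_series,
    images_per_series = config$schedule$images_per_series,
    image_duration = config$schedule$image_duration,
    isi_duration = config$schedule$isi_duration)
  schedule <- generate_schedule(sched_cfg)

  sites <- make_sites(config$cohort$n_subjects,
                      unlist(config$cohort$per_region))
  effects <- effect_spec(null = isTRUE(config$effects$null))
  coupling <- if (isTRUE(config$coupling$enabled)) coupling_spec() else
    no_coupling()
  noise <- noise_spec(exponent = config$noise$exponent,
                      amplitude = config$noise$amplitude,
                      broadband_amplitude = config$noise$broadband_amplitude,
                      band = config$noise$band, fs = config$noise$fs)
  rec <- simulate_recording(sites, schedule, effects, coupling, noise,
                            seed = seed + 101L)
  rec <- common_average_reference(rec)

  epochs <- epoch_transitions(rec, classes = IMAGE_CLASSES)
  psds <- normalize_psd_set(compute_psds(epochs))
  main <- psds$meta$transition_class == "image_to_image"
  main_psds <- structure(list(values = psds$values[main, , drop = FALSE],
                              grid = psds$grid,
                              meta = psds$meta[main, ]),
                         class = "narr_psd")
  cond_avg <- condition_average(main_psds)
  projections <- loso_project_all(cond_avg, psds)
  main_proj <- projections[projections$transition_class == "image_to_image", ]

  trials <- unique(main_proj[, c("trial_id", "condition")])
  split <- trial_split(trials, test_frac = cfg_a$test_frac,
                       seed = seed + 202L)

  report <- list(
    seed = seed,
    counts = list(
      n_sites = nrow(sites), n_included = sum(!sites$excluded),
      n_image_events = sum(schedule$kind == "image"),
      n_epochs = nrow(epochs$data),
      n_trial_psds = nrow(psds$values),
      n_condition_avg_psds = nrow(cond_avg$values),
      n_trials = nrow(trials),
      n_pool = length(split$pool), n_test = length(split$test)),
    split = split)

  if ("encode" %in% stages) {
    enc <- encode_sites(main_proj, split$pool, n_perm = cfg_a$n_perm,
                        alpha = cfg_a$alpha, folds = cfg_a$folds,
                        n_train = cfg_a$n_train, seed = seed + 303L)
    report$encoding <- enc
    report$counts$n_significant <- sum(enc$significant)
    report$first_vs_rest <- first_vs_rest_contrast(projections)
  }
  if ("decode" %in% stages) {
    if (is.null(report$encoding))
      stop("decode stage requires the encode stage")
    ranking <- rank_sites(report$encoding)
    report$decoding <- accuracy_curve(main_proj, ranking, split$test,
                                      sizes = cfg_a$sizes,
                                      repeats = cfg_a$repeats,
                                      seed = seed + 404L)
  }
  if ("connectivity" %in% stages) {
    main_ep <- epoch_transitions(rec, classes = "image_to_image")
    gc <- gc_all_pairs(main_ep, order = cfg_a$gc_order)
    couplets <- identify_couplets(gc, alpha = cfg_a$alpha)
    tables <- region_contingency(couplets, sites)
    report$connectivity <- list(
      gc = gc, couplets = couplets, tables = tables,
      contrast = if (sum(tables$Seq) + sum(tables$Scr) > 0)
        chi_square_contrast(tables$Seq, tables$Scr) else NULL)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(schedule, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(sites, file.path(out_dir, "sites.csv"),
                     row.names = FALSE)
    if (!is.null(report$encoding))
      utils::write.csv(report$encoding,
                       file.path(out_dir, "encoding_results.csv"),
                       row.names = FALSE)
    if (!is.null(report$decoding))
      utils::write.csv(report$decoding,
                       file.path(out_dir, "decoding_curve.csv"),
                       row.names = FALSE)
    if (!is.null(report$connectivity)) {
      utils::write.csv(report$connectivity$couplets,
                       file.path(out_dir, "couplets.csv"), row.names = FALSE)
      for (cc in names(report$connectivity$tables))
        utils::write.csv(report$connectivity$tables[[cc]],
                         file.path(out_dir, paste0("contingency_", cc, ".csv")))
    }
  }
  report
}
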
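#' Pipeline run configuration
#'
#' One config drives a whole per-patient run: feature channels, subsample
#' size, grid-search settings, scaling target interval, and the seeds for
#' sampling, cross-validation and simulation. Every persisted artifact
#' records the seeds and a config fingerprint, so identical config + seeds
#' reproduce identical outputs.
#'
#' @param channels Feature channel names, or `NULL` for all channels of the
#'   diagnosis file.
#' @param n_sample Stratified-subsample size (default `1e4`).
#' @param grid A [grid_config()].
#' @param lo,hi Scaling target interval.
#' @param sample_seed,cv_seed Seeds for subsampling and CV folds.
#' @param out_dir Directory for persisted artifacts, or `NULL` to skip
#'   persistence.
#' @return A `run_config`.
#' @export
run_config <- function(channels = NULL, n_sample = 1e4, grid = grid_config(),
                       lo = -1, hi = 1, sample_seed = 1L, cv_seed = 1L,
                       out_dir = NULL) {
  structure(list(channels = channels, n_sample = n_sample, grid = grid,
                 lo = lo, hi = hi, sample_seed = as.integer(sample_seed),
                 cv_seed = as.integer(cv_seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

load_events <- function(x, what = "input") {
  if (inherits(x, "event_matrix")) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop_flowmrd("%s must be an event_matrix or a file path", what)
  if (grepl("\\.csv$", x, ignore.case = TRUE)) read_events_csv(x) else read_fcs(x)
}

#' Run the full per-patient MRD pipeline
#'
#' Executes the canonical stage sequence: training-file derivation
#' ([build_training_set()]), stratified subsampling ([stratified_sample()]),
#' range fitting and scaling ([fit_scaling()] / [apply_scaling()]),
#' `(C, gamma)` optimisation ([grid_search()]), model building
#' ([train_model()]), then [predict_mrd()] on every follow-up specimen.
#' Any stage error is re-raised with the stage name. When `cfg$out_dir` is
#' set, the model, range, chosen parameters and per-specimen fractions are
#' persisted as plain-text artifacts stamped with the seeds and config
#' fingerprint.
#'
#' @param cfg A [run_config()].
#' @param diagnosis Diagnosis blast population: [event_matrix()] or FCS/CSV
#'   path.
#' @param donors List of healthy-donor specimens (same forms).
#' @param followups Named list of follow-up specimens (same forms).
#' @return A `pipeline_result`: list with `model` (`patient_model`),
#'   `params`, `range`, `results` (named list of `mrd_result`), `fractions`
#'   (named numeric, percent), `config_hash`.
#' @export
run_full_pipeline <- function(cfg, diagnosis, donors, followups) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_flowmrd("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  diagnosis <- stage("read diagnosis", load_events(diagnosis, "diagnosis"))
  donors <- stage("read donors", lapply(donors, load_events, what = "donor"))
  followups <- stage("read follow-ups", lapply(followups, load_events, what = "follow-up"))
  if (is.null(names(followups)) || any(!nzchar(names(followups))))
    names(followups) <- vapply(followups, function(f) f$specimen_id, character(1))

  channels <- cfg$channels %||% diagnosis$channels$short_name
  ts <- stage("build_training_set",
              build_training_set(diagnosis, donors, channels))
  sub <- stage("stratified_sample",
               stratified_sample(ts, cfg$n_sample, cfg$sample_seed))
  range <- stage("fit_scaling", fit_scaling(sub, cfg$lo, cfg$hi))
  scaled <- sub
  scaled$features <- stage("apply_scaling", apply_scaling(sub$features, range))
  gcfg <- cfg$grid
  gcfg$seed <- cfg$cv_seed
  params <- stage("grid_search", grid_search(scaled, gcfg))
  model <- stage("train_model", train_model(scaled, params, range, channels))
  results <- lapply(names(followups), function(nm)
    stage(paste0("predict_mrd[", nm, "]"), predict_mrd(model, followups[[nm]])))
  names(results) <- names(followups)
  fractions <- vapply(results, `[[`, numeric(1), "leukemic_fraction")

  out <- structure(list(model = model, params = params, range = range,
                        results = results, fractions = fractions,
                        config_hash = config_hash(cfg)),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_patient_model(model, file.path(cfg$out_dir, "patient.model"))
    write_scaling_range(range, file.path(cfg$out_dir, "train.range"))
    hdr <- sprintf("# flowMRD run config=%s sample_seed=%d cv_seed=%d C=%g gamma=%g cv_accuracy=%.4f",
                   out$config_hash, cfg$sample_seed, cfg$cv_seed,
                   params$C, params$gamma, params$cv_accuracy)
    fr_path <- file.path(cfg$out_dir, "mrd_fractions.csv")
    writeLines(c(hdr, "specimen,leukemic_fraction_percent,n_events",
                 sprintf("%s,%.6f,%d", names(results), fractions,
                         vapply(results, `[[`, integer(1), "n_events"))),
               fr_path)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (config %s): C = %g, gamma = %g, CV accuracy = %.2f%%\n",
              x$config_hash, x$params$C, x$params$gamma, x$params$cv_accuracy))
  for (nm in names(x$fractions))
    cat(sprintf("  %s: MRD = %.4f%%\n", nm, x$fractions[nm]))
  invisible(x)
}

#' Build a complete synthetic patient case
#'
#' Study-condition defaults: a diagnosis blast export of `5e4` events, 15
#' healthy-donor marrow files of `1e4` events each (together a > 2 x 10^5
#' event training pool), and follow-up specimens of `1e5` events with the
#' blast population spiked at the requested fractions.
#'
#' @param seed Master seed; donor and follow-up seeds are derived from it.
#' @param followup_fractions Spike fractions (proportions, not percent) for
#'   the follow-up specimens.
#' @param n_blasts,n_donor_events,n_followup Event counts per file.
#' @param n_donors Number of healthy-donor files.
#' @param separation Blast-population separation multiplier (see
#'   [aml_blast_population()]).
#' @return List with `diagnosis` ([event_matrix()] of blasts), `donors`
#'   (list of [event_matrix()]), `followups` (named list of
#'   `labeled_specimen`), `truth` (named numeric realised fractions, in
#'   percent).
#' @export
make_synthetic_patient <- function(seed = 1L,
                                   followup_fractions = c(0.0005, 0.001, 0.01, 0.05, 0.25),
                                   n_blasts = 5e4, n_donor_events = 1e4,
                                   n_followup = 1e5, n_donors = 15L,
                                   separation = 1) {
  blast_pop <- aml_blast_population(separation = separation)
  blast_pop$fraction <- 1
  diag_spec <- synthetic_spec(list(blast_pop), n_events = n_blasts,
                              seed = derive_seed(seed, 1L))
  diagnosis <- simulate_specimen(diag_spec, "diagnosis_P1")$events

  donors <- lapply(seq_len(n_donors), function(i) {
    sp <- normal_marrow_spec(n_events = n_donor_events, seed = derive_seed(seed, 1L + i))
    simulate_specimen(sp, sprintf("donor%02d", i))$events
  })

  followups <- list()
  truth <- numeric(0)
  for (k in seq_along(followup_fractions)) {
    bg <- normal_marrow_spec(n_events = n_followup,
                             seed = derive_seed(seed, 100L + k))
    nm <- sprintf("followup%02d", k)
    fu <- spike_mrd(bg, blast_pop, followup_fractions[k], n_events = n_followup,
                    seed = derive_seed(seed, 200L + k), specimen_id = nm)
    followups[[nm]] <- fu
    truth[nm] <- 100 * fu$spiked_fraction
  }
  list(diagnosis = diagnosis, donors = donors, followups = followups, truth = truth)
}

#' Generate an FCS fixture set on disk
#'
#' Writes a full synthetic patient case — 1 diagnosis blast file, healthy
#' donor files and spiked follow-ups — as FCS 3.0 files with
#' `event_index,label` truth-label sidecar CSVs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param spec_file Optional YAML file overriding the defaults; recognised
#'   keys: `n_blasts`, `n_donor_events`, `n_followup`, `n_donors`,
#'   `followup_fractions`, `separation`.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, spec_file = NULL) {
  args <- list(seed = seed, followup_fractions = c(0.001, 0.01, 0.25))
  if (!is.null(spec_file)) {
    cfg <- yaml::read_yaml(spec_file)
    for (k in intersect(names(cfg), c("n_blasts", "n_donor_events", "n_followup",
                                      "n_donors", "followup_fractions", "separation")))
      args[[k]] <- unlist(cfg[[k]])
  }
  case <- do.call(make_synthetic_patient, args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(ev, name) {
    p <- file.path(out_dir, paste0(name, ".fcs"))
    write_fcs(ev, p, datatype = "D")
    paths <<- c(paths, p)
  }
  wr(case$diagnosis, "diagnosis_P1")
  for (d in case$donors) wr(d, d$specimen_id)
  for (nm in names(case$followups)) {
    fu <- case$followups[[nm]]
    wr(fu$events, nm)
    lp <- file.path(out_dir, paste0(nm, ".labels.csv"))
    write_truth_labels(fu, lp)
    paths <- c(paths, lp)
  }
  invisible(paths)
}
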
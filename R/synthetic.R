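#' Default synthetic acquisition panel
#'
#' The four-colour LAIP panel plus scatter, in acquisition order:
#' FSC, SSC, CD7 (FITC), CD117 (PE), HLA-DR (APC), CD45 (PE-Cy7).
#' @export
default_panel <- function() c("FSC", "SSC", "CD7", "CD117", "HLA-DR", "CD45")

#' Describe one event population
#'
#' A population is a multivariate Gaussian in intensity space: a per-channel
#' centre and spread, an optional channel-correlation matrix, and the
#' fraction of the specimen it contributes.
#'
#' @param name Population label (the leukemic population's name carries the
#'   ground-truth label downstream).
#' @param fraction Fraction of specimen events in `[0, 1]`.
#' @param location Named or ordered per-channel centre (arbitrary intensity
#'   units).
#' @param spread Per-channel standard deviation (same units, `>= 0`);
#'   recycled if scalar.
#' @param correlation Optional symmetric positive-definite correlation
#'   matrix across channels (identity if omitted).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, fraction, location, spread, correlation = NULL) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop_flowmrd("population '%s': fraction must be in [0,1]", name)
  spread <- rep_len(as.numeric(spread), length(location))
  if (any(spread < 0))
    stop_flowmrd("population '%s': spreads must be >= 0", name)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isSymmetric(correlation) ||
        inherits(try(chol(correlation), silent = TRUE), "try-error"))
      stop_flowmrd("population '%s': correlation must be symmetric positive definite",
                   name)
  }
  structure(list(name = as.character(name), fraction = fraction,
                 location = as.numeric(location), spread = spread,
                 correlation = correlation),
            class = "population_spec")
}

#' Describe a synthetic specimen
#'
#' @param populations List of [population_spec()]; fractions must sum to 1
#'   (within 1e-9).
#' @param n_events Number of events (`>= 1`); defaults to `1e5`, the minimum
#'   acquisition size the pipeline assumes for clinical files.
#' @param seed RNG seed; the same spec and seed always reproduce the same
#'   specimen.
#' @param channels Ordered channel names; defaults to [default_panel()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(populations, n_events = 1e5, seed = 1L,
                           channels = default_panel()) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (length(populations) < 1L) stop_flowmrd("need at least one population")
  if (anyDuplicated(channels)) stop_flowmrd("channel names must be unique")
  if (n_events < 1) stop_flowmrd("n_events must be >= 1")
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop_flowmrd("population fractions sum to %.12f, not 1", sum(fr))
  for (p in populations)
    if (length(p$location) != length(channels))
      stop_flowmrd("population '%s' has %d channel locations for %d channels",
                   p$name, length(p$location), length(channels))
  structure(list(populations = populations, n_events = as.integer(n_events),
                 seed = as.integer(seed), channels = as.character(channels)),
            class = "synthetic_spec")
}

draw_population <- function(pop, n, channels) {
  p <- length(channels)
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  if (!is.null(pop$correlation)) z <- z %*% chol(pop$correlation)
  x <- sweep(sweep(z, 2L, pop$spread, `*`), 2L, pop$location, `+`)
  pmax(x, 0)  # detectors report non-negative intensities
}

#' Simulate a labeled specimen
#'
#' Per-population event counts are the exact largest-remainder apportionment
#' of `n_events` by the population fractions, so ground-truth fractions are
#' deterministic; only event coordinates are stochastic (seeded). Negative
#' Gaussian draws are truncated at zero.
#'
#' @param spec A [synthetic_spec()].
#' @param specimen_id Label for the resulting [event_matrix()].
#' @return A `labeled_specimen`: list with `events` ([event_matrix()]),
#'   `truth_labels` (per-event population name) and `spiked_fraction`
#'   (realised fraction of events whose population name starts with
#'   `"blast"` or `"leukemi"`).
#' @export
simulate_specimen <- function(spec, specimen_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  fr <- vapply(spec$populations, `[[`, numeric(1), "fraction")
  counts <- largest_remainder(spec$n_events, fr)
  mats <- vector("list", length(counts))
  with_seed(spec$seed, {
    for (i in seq_along(spec$populations)) {
      if (counts[i] > 0L)
        mats[[i]] <- draw_population(spec$populations[[i]], counts[i], spec$channels)
    }
  })
  keep <- counts > 0L
  values <- do.call(rbind, mats[keep])
  if (is.null(values))
    values <- matrix(numeric(0), ncol = length(spec$channels))
  labels <- rep(vapply(spec$populations, `[[`, character(1), "name")[keep],
                counts[keep])
  ev <- event_matrix(values, spec$channels, specimen_id)
  structure(list(events = ev, truth_labels = labels,
                 spiked_fraction = mean(is_leukemic_label(labels))),
            class = "labeled_specimen")
}

is_leukemic_label <- function(labels) {
  grepl("^(blast|leukemi)", labels, ignore.case = TRUE)
}

#' @export
print.labeled_specimen <- function(x, ...) {
  cat(sprintf("labeled_specimen: %d events, spiked fraction %.6f\n",
              nrow(x$events$values), x$spiked_fraction))
  print(table(x$truth_labels))
  invisible(x)
}

#' Spike a leukemic population into a normal background
#'
#' Emulates a follow-up MRD specimen: exactly `round(fraction * n_events)`
#' events come from the blast population, and the normal populations are
#' rescaled by largest-remainder apportionment to fill the remainder.
#' `spiked_fraction` of the result records the realised (post-rounding)
#' fraction.
#'
#' @param normal A [synthetic_spec()] describing the normal background.
#' @param blast A [population_spec()] for the leukemic population.
#' @param fraction Target leukemic fraction in `[0, 1]`.
#' @param n_events Specimen size; defaults to the normal spec's.
#' @param seed RNG seed.
#' @param specimen_id Specimen label.
#' @return A `labeled_specimen`; see [simulate_specimen()].
#' @export
spike_mrd <- function(normal, blast, fraction, n_events = normal$n_events,
                      seed = normal$seed, specimen_id = "followup") {
  stopifnot(inherits(normal, "synthetic_spec"), inherits(blast, "population_spec"))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop_flowmrd("spike fraction %.4g outside [0,1]", fraction)
  n_events <- as.integer(n_events)
  n_leuk <- as.integer(round(fraction * n_events))
  n_norm <- n_events - n_leuk
  norm_fr <- vapply(normal$populations, `[[`, numeric(1), "fraction")
  counts <- if (n_norm > 0L) largest_remainder(n_norm, norm_fr)
            else integer(length(norm_fr))
  pops <- c(normal$populations, list(blast))
  all_counts <- c(counts, n_leuk)
  # Reuse the deterministic-count machinery with explicit counts.
  keep <- all_counts > 0L
  mats <- vector("list", length(pops))
  with_seed(seed, {
    for (i in seq_along(pops)) {
      if (all_counts[i] > 0L)
        mats[[i]] <- draw_population(pops[[i]], all_counts[i], normal$channels)
    }
  })
  values <- do.call(rbind, mats[keep])
  if (is.null(values))
    values <- matrix(numeric(0), ncol = length(normal$channels))
  labels <- rep(vapply(pops, `[[`, character(1), "name")[keep], all_counts[keep])
  ev <- event_matrix(values, normal$channels, specimen_id)
  structure(list(events = ev, truth_labels = labels,
                 spiked_fraction = n_leuk / n_events),
            class = "labeled_specimen")
}

#' Write the truth-label sidecar for a labeled specimen
#'
#' @param specimen A `labeled_specimen`.
#' @param path Output CSV path (`event_index,label`).
#' @return `path`, invisibly.
#' @export
write_truth_labels <- function(specimen, path) {
  utils::write.csv(data.frame(event_index = seq_along(specimen$truth_labels),
                              label = specimen$truth_labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a specimen spec from a YAML config
#'
#' The config mirrors [synthetic_spec()]: top-level `n_events`, `seed`,
#' `channels`, and a `populations` list with `name`, `fraction`, `location`,
#' `spread` and optional `correlation` entries.
#'
#' @param path YAML file.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- lapply(cfg$populations, function(p) {
    population_spec(p$name, p$fraction, unlist(p$location), unlist(p$spread),
                    if (!is.null(p$correlation))
                      matrix(unlist(p$correlation),
                             nrow = length(p$location), byrow = TRUE))
  })
  synthetic_spec(pops,
                 n_events = if (is.null(cfg$n_events)) 1e5 else cfg$n_events,
                 seed = if (is.null(cfg$seed)) 1L else cfg$seed,
                 channels = if (is.null(cfg$channels)) default_panel()
                            else unlist(cfg$channels))
}

# ---- Reference populations -------------------------------------------------

#' Reference normal bone-marrow background
#'
#' Three compact populations with typical scatter/marker geometry:
#' lymphocytes (CD45 bright, low SSC, CD7+ T cells included), granulocytes
#' (high SSC, CD45 mid) and monocytes (HLA-DR+). Intensities are arbitrary
#' linear units on a 0-1023-like scale.
#'
#' @param n_events Specimen size.
#' @param seed RNG seed.
#' @return A [synthetic_spec()].
#' @export
normal_marrow_spec <- function(n_events = 1e5, seed = 1L) {
  lymph <- population_spec("lymphocytes", 0.60,
                           location = c(350, 150, 250, 20, 60, 800),
                           spread = c(30, 20, 25, 10, 20, 40))
  gran <- population_spec("granulocytes", 0.30,
                          location = c(600, 700, 30, 25, 40, 400),
                          spread = c(50, 60, 15, 12, 15, 40))
  mono <- population_spec("monocytes", 0.10,
                          location = c(550, 350, 40, 30, 500, 650),
                          spread = c(40, 35, 15, 12, 40, 40))
  synthetic_spec(list(lymph, gran, mono), n_events = n_events, seed = seed)
}

#' Reference leukemic blast population
#'
#' A CD7+/CD117+ co-expressing blast cluster with dim CD45 — the
#' leukemia-associated immunophenotype the panel targets. At
#' `separation = 1` the CD117 centre sits more than 6 pooled standard
#' deviations from every normal population; smaller values shrink the
#' marker-space distance towards the normal centroid (scatter unchanged).
#'
#' @param fraction Fraction used when the population joins a
#'   [synthetic_spec()] directly (ignored by [spike_mrd()]).
#' @param separation Multiplier on the marker-space offset from the normal
#'   centroid, in `(0, 1]`.
#' @return A [population_spec()] named `"blasts"`.
#' @export
aml_blast_population <- function(fraction = 1, separation = 1) {
  base <- c(450, 220, 70, 40, 120, 500)    # normal-marrow-like anchor
  full <- c(450, 220, 600, 550, 420, 250)  # fully separated LAIP position
  loc <- base + separation * (full - base)
  population_spec("blasts", fraction, location = loc,
                  spread = c(35, 25, 30, 30, 35, 30))
}
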
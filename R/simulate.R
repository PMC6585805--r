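#' Configuration for the synthetic kinetic-data generator
#'
#' Defaults emulate the study conditions of a two-substrate tyrosine-kinase
#' array run: 144 peptides (one internal positive control), three technical
#' replicates, readings on a regular grid spanning the 640-1840 s analysis
#' windows, an active-peptide structure matching the published overlap
#' (55 shared, 8 unique to condition A, 4 unique to condition B), a class mix
#' close to the published early/mid/late proportions, and a modest
#' multiplicative activity advantage of condition A over B for shared
#' actives. Inactive peptides are flat background plus noise.
#'
#' @param n_peptides total peptides including the internal control.
#' @param n_replicates technical replicates per peptide.
#' @param time_grid reading times in seconds; must cover the kinetic windows
#'   (640-1840 s) with at least one reading per 400 s window.
#' @param n_active_shared,n_active_a_only,n_active_b_only active-peptide
#'   counts by condition membership.
#' @param class_mix probabilities over early/mid/late for active peptides.
#' @param effect_ratio multiplicative amplitude factor of condition A over B
#'   for shared actives (> 0; >= 1 means A is the more active substrate).
#' @param noise_sd additive Gaussian noise SD, AU.
#' @param background_level flat baseline fluorescence, AU.
#' @param amplitude_range log-uniform amplitude range for active peptides,
#'   AU; graded amplitudes give the spread of Vmax that the rank-background
#'   trend fit assumes.
#' @param conditions two condition labels, A first.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of settings, class `kinome_sim_config`.
#' @export
sim_config <- function(n_peptides = 144, n_replicates = 3,
                       time_grid = seq(0, 1900, by = 100),
                       n_active_shared = 55, n_active_a_only = 8,
                       n_active_b_only = 4,
                       class_mix = c(early = 0.68, mid = 0.25, late = 0.07),
                       effect_ratio = 1.25, noise_sd = 5,
                       background_level = 20,
                       amplitude_range = c(50, 200),
                       conditions = c("ECM", "Ti"), seed = NULL) {
  cfg <- list(n_peptides = as.integer(n_peptides),
              n_replicates = as.integer(n_replicates),
              time_grid = as.numeric(time_grid),
              n_active_shared = as.integer(n_active_shared),
              n_active_a_only = as.integer(n_active_a_only),
              n_active_b_only = as.integer(n_active_b_only),
              class_mix = class_mix, effect_ratio = effect_ratio,
              noise_sd = noise_sd, background_level = background_level,
              amplitude_range = as.numeric(amplitude_range),
              conditions = as.character(conditions), seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "kinome_sim_config")
}

validate_sim_config <- function(cfg) {
  n_active <- cfg$n_active_shared + cfg$n_active_a_only + cfg$n_active_b_only
  if (cfg$n_peptides < 2L) kk_validation_error("n_peptides must be >= 2")
  if (cfg$n_replicates < 1L) kk_validation_error("n_replicates must be >= 1")
  if (any(c(cfg$n_active_shared, cfg$n_active_a_only, cfg$n_active_b_only) < 0L)) {
    kk_validation_error("active-peptide counts must be non-negative")
  }
  if (n_active > cfg$n_peptides - 1L) {
    kk_validation_error("active peptides exceed the number of analyte peptides")
  }
  if (length(cfg$class_mix) != 3L ||
      !setequal(names(cfg$class_mix), kinetic_class_levels) ||
      any(cfg$class_mix < 0) || abs(sum(cfg$class_mix) - 1) > 1e-8) {
    kk_validation_error("class_mix must be named early/mid/late probabilities summing to 1")
  }
  if (!is.numeric(cfg$effect_ratio) || cfg$effect_ratio <= 0) {
    kk_validation_error("effect_ratio must be > 0")
  }
  if (cfg$noise_sd < 0) kk_validation_error("noise_sd must be >= 0")
  grid <- cfg$time_grid
  if (is.unsorted(grid, strictly = TRUE) || any(grid < 0)) {
    kk_validation_error("time_grid must be strictly increasing and >= 0")
  }
  if (min(grid) > 640 || max(grid) < 1840) {
    kk_validation_error("time_grid must cover the 640-1840 s analysis range")
  }
  for (w in list(c(640, 1040), c(1040, 1440), c(1440, 1840))) {
    if (!any(grid >= w[1] & grid <= w[2])) {
      kk_validation_error("every 400 s kinetic window needs at least one reading")
    }
  }
  if (length(cfg$amplitude_range) != 2L || any(cfg$amplitude_range <= 0) ||
      cfg$amplitude_range[1] > cfg$amplitude_range[2]) {
    kk_validation_error("amplitude_range must be two positive increasing values")
  }
  if (length(cfg$conditions) != 2L || anyDuplicated(cfg$conditions)) {
    kk_validation_error("conditions must be two distinct labels")
  }
  invisible(cfg)
}

#' Noiseless kinetic curve templates
#'
#' The three kinetic shapes seen on tyrosine-kinase arrays, all flat at
#' `background_level` before the 640 s reaction start:
#' \describe{
#'   \item{early}{saturating exponential
#'     `A * (1 - exp(-k * (t - 640)))` with `k = log(10)/800`, i.e. 90% of
#'     the plateau is reached by 1440 s — classical kinetics whose initial
#'     slope approximates Vmax.}
#'   \item{mid}{logistic `A / (1 + exp(-(t - 1240)/tau))`: a lag phase, then
#'     the steepest rise at the centre of the mid window (Maxwell-Boltzmann
#'     -like activation).}
#'   \item{late}{the same logistic centred at 1640 s, so the steepest rise
#'     falls in the late window.}
#'   \item{background}{flat at `background_level`.}
#' }
#'
#' @param kinetic_class one of `"early"`, `"mid"`, `"late"`, `"background"`.
#' @param amplitude plateau amplitude A, AU (> 0).
#' @param times reading times, seconds.
#' @param background_level additive flat baseline, AU.
#' @param tau logistic time constant, seconds; the logistic slope at its
#'   centre is `A/(4*tau)`.
#' @return noiseless intensities at `times`.
#' @export
curve_model <- function(kinetic_class, amplitude, times, background_level = 0,
                        tau = 100) {
  if (kinetic_class != "background" && (!is.numeric(amplitude) || amplitude <= 0)) {
    kk_validation_error("amplitude must be > 0")
  }
  g <- switch(kinetic_class,
    early = amplitude * (1 - exp(-(log(10) / 800) * pmax(0, times - 640))),
    mid = amplitude / (1 + exp(-(times - 1240) / tau)),
    late = amplitude / (1 + exp(-(times - 1640) / tau)),
    background = numeric(length(times)),
    kk_validation_error(sprintf("unknown kinetic class '%s'", kinetic_class)))
  ifelse(times < 640, background_level, background_level + g)
}

#' Simulate a two-condition kinetic dataset with known ground truth
#'
#' Each peptide gets an activity status per condition and, if active, a
#' kinetic class and a log-uniform amplitude; shared actives have their
#' amplitude multiplied by `effect_ratio` in condition A. Every replicate
#' curve is the noiseless [curve_model()] template plus i.i.d. Gaussian
#' noise. The internal positive control (`ART_003_...`) is active in both
#' conditions with a fixed high amplitude and early kinetics. Identical
#' seeds produce identical datasets.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [as_kinetic_dataset()] long table),
#'   `truth` (per-peptide `active_in_a`, `active_in_b`, `true_class`, and
#'   the amplitudes used) and `annotation` (a matching peptide annotation
#'   table assigning each simulated analyte its own synthetic gene symbol).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n_analyte <- config$n_peptides - 1L
  control_id <- "ART_003_EAIYAAPFAKKKXC"
  analyte_ids <- sprintf("PEP_%03d", seq_len(n_analyte))
  n_act <- config$n_active_shared + config$n_active_a_only + config$n_active_b_only
  picked <- if (n_act > 0) sample(analyte_ids, n_act) else character()
  shared <- picked[seq_len(config$n_active_shared)]
  a_only <- picked[config$n_active_shared + seq_len(config$n_active_a_only)]
  b_only <- picked[config$n_active_shared + config$n_active_a_only +
                     seq_len(config$n_active_b_only)]
  cls <- if (n_act > 0) {
    sample(kinetic_class_levels, n_act, replace = TRUE,
           prob = config$class_mix[kinetic_class_levels])
  } else character()
  amp <- exp(stats::runif(n_act, log(config$amplitude_range[1]),
                          log(config$amplitude_range[2])))
  names(cls) <- names(amp) <- picked

  peptides <- kk_sort(c(analyte_ids, control_id))
  truth <- data.frame(peptide_id = peptides,
                      active_in_a = peptides %in% c(shared, a_only, control_id),
                      active_in_b = peptides %in% c(shared, b_only, control_id),
                      true_class = "background",
                      amplitude_a = 0, amplitude_b = 0,
                      stringsAsFactors = FALSE)
  idx <- match(picked, truth$peptide_id)
  truth$true_class[idx] <- cls
  truth$amplitude_b[idx] <- ifelse(picked %in% b_only | picked %in% shared, amp, 0)
  truth$amplitude_a[idx] <- ifelse(picked %in% a_only, amp,
                                   ifelse(picked %in% shared,
                                          amp * config$effect_ratio, 0))
  ctrl <- match(control_id, truth$peptide_id)
  truth$true_class[ctrl] <- "early"
  truth$amplitude_a[ctrl] <- truth$amplitude_b[ctrl] <- 300
  attr(truth, "conditions") <- config$conditions

  grid <- config$time_grid
  nt <- length(grid)
  R <- config$n_replicates
  blocks <- vector("list", 2L * length(peptides))
  bi <- 0L
  for (ci in 1:2) {
    amp_col <- if (ci == 1L) truth$amplitude_a else truth$amplitude_b
    for (pi in seq_along(peptides)) {
      a <- amp_col[pi]
      base <- curve_model(if (a > 0) truth$true_class[pi] else "background",
                          if (a > 0) a else 1, grid, config$background_level)
      bi <- bi + 1L
      blocks[[bi]] <- rep(base, R)
    }
  }
  intensity <- unlist(blocks, use.names = FALSE) +
    stats::rnorm(2L * length(peptides) * R * nt, sd = config$noise_sd)
  dataset <- data.frame(
    condition = rep(config$conditions, each = length(peptides) * R * nt),
    peptide_id = rep(rep(peptides, each = R * nt), times = 2L),
    replicate = rep(rep(seq_len(R), each = nt), times = 2L * length(peptides)),
    time_s = rep(grid, times = 2L * length(peptides) * R),
    intensity = intensity,
    stringsAsFactors = FALSE)
  ord <- kk_order(dataset$condition, dataset$peptide_id, dataset$replicate,
                  dataset$time_s)
  dataset <- dataset[ord, , drop = FALSE]
  rownames(dataset) <- NULL
  annotation <- data.frame(
    peptide_id = peptides, protein_label = peptides,
    gene_id = ifelse(peptides == control_id, NA_character_,
                     sub("^PEP", "GENE", peptides)),
    site_start = NA_integer_, site_end = NA_integer_,
    is_artificial_control = FALSE,
    is_internal_positive_control = peptides == control_id,
    stringsAsFactors = FALSE)
  list(dataset = as_kinetic_dataset(dataset, validate = FALSE),
       truth = truth, annotation = annotation)
}
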
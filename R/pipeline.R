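#' Pipeline configuration
#'
#' Exactly one of `input` (a kinetic CSV/TSV on disk) or `sim` (a
#' [sim_config()] describing a synthetic run) must be given.
#'
#' @param input path to a kinetic intensity table, or `NULL`.
#' @param sim a [sim_config()], or `NULL`.
#' @param out_dir output directory (created if absent).
#' @param windows a [kinetic_windows()].
#' @param n_background,sd_multiplier calling-rule settings.
#' @param pairing pairing policy for the AUC comparison.
#' @param gene_sets path to a GMT file, or `NULL` to skip enrichment.
#' @param annotations path to a peptide annotation TSV; packaged synthetic
#'   fixture when `NULL`.
#' @param background_size enrichment universe size N.
#' @param seed integer seed applied to the whole run.
#' @return validated settings list, class `kinome_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, out_dir = "kinomekin-run",
                            windows = kinetic_windows(), n_background = 60,
                            sd_multiplier = 1.95,
                            pairing = c("intersection", "union", "all"),
                            gene_sets = NULL, annotations = NULL,
                            background_size = 20000, seed = NULL) {
  pairing <- match.arg(pairing)
  if (is.null(input) == is.null(sim)) {
    kk_validation_error("exactly one of 'input' and 'sim' must be given")
  }
  if (!is.null(input) && !file.exists(input)) {
    kk_validation_error(sprintf("input file does not exist: %s", input))
  }
  if (!is.null(gene_sets) && !file.exists(gene_sets)) {
    kk_validation_error(sprintf("gene-set file does not exist: %s", gene_sets))
  }
  if (!is.null(annotations) && !file.exists(annotations)) {
    kk_validation_error(sprintf("annotation file does not exist: %s", annotations))
  }
  if (!is.null(sim)) validate_sim_config(sim)
  structure(list(input = input, sim = sim, out_dir = out_dir,
                 windows = windows, n_background = n_background,
                 sd_multiplier = sd_multiplier, pairing = pairing,
                 gene_sets = gene_sets, annotations = annotations,
                 background_size = background_size, seed = seed),
            class = "kinome_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; `sim` may be a
#' mapping of [sim_config()] fields.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) kk_io_error(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    y$sim$class_mix <- unlist(y$sim$class_mix) %||% NULL
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$windows)) y$windows <- do.call(kinetic_windows, y$windows)
  do.call(pipeline_config, y)
}

#' Run the full kinome-profiling pipeline
#'
#' simulate/read -> Vmax estimation -> Markov calling -> two-condition AUC
#' comparison -> (optional) gene-set enrichment, with every artefact written
#' under `config$out_dir` and a reproducibility manifest recording the seed,
#' settings, package/R versions and md5 checksums of all outputs. Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (written to stderr).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "kinome_pipeline_config")) {
    kk_validation_error("config must come from pipeline_config()")
  }
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  if (!is.null(config$sim)) {
    sim <- config$sim
    if (is.null(sim$seed) && !is.null(config$seed)) sim$seed <- config$seed
    say("stage simulate: %d peptides x %d replicates", sim$n_peptides,
        sim$n_replicates)
    simd <- simulate_dataset(sim)
    data <- simd$dataset
    data_path <- file.path(config$out_dir, "data.csv")
    write_kinetics_table(data, data_path)
    truth_path <- file.path(config$out_dir, "truth.tsv")
    utils::write.table(simd$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, data_path, truth_path)
  } else {
    say("stage read: %s", config$input)
    data <- read_kinetics_table(config$input)
  }

  say("stage fit: Vmax estimation and Markov calling")
  fit <- kinome_profile(data, windows = config$windows,
                        n_background = config$n_background,
                        sd_multiplier = config$sd_multiplier)
  calls_path <- file.path(config$out_dir, "calls.tsv")
  write_calls_table(fit$calls, calls_path)
  outputs <- c(outputs, calls_path)

  conds <- kk_sort(unique(fit$calls$condition))
  cmp <- NULL
  if (length(conds) >= 2L) {
    say("stage compare: %s vs %s", conds[1], conds[2])
    cmp <- compare_conditions(fit, conds[1], conds[2], pairing = config$pairing)
    cmp_path <- file.path(config$out_dir, "comparison.json")
    cmp_json <- list(condition_a = cmp$condition_a, condition_b = cmp$condition_b,
                     pairing = cmp$pairing, n_pairs = length(cmp$peptides),
                     mean_auc_a = cmp$mean_auc_a, mean_auc_b = cmp$mean_auc_b,
                     sd_auc_a = cmp$sd_auc_a, sd_auc_b = cmp$sd_auc_b,
                     wilcoxon_statistic = cmp$wilcoxon_statistic,
                     p_value = cmp$p_value,
                     venn = cmp$venn[c("n_both", "n_a_only", "n_b_only")],
                     class_counts = as.data.frame(as.table(cmp$class_counts)))
    jsonlite::write_json(cmp_json, cmp_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, cmp_path)
  }

  if (!is.null(config$gene_sets)) {
    say("stage enrich: %s", config$gene_sets)
    sets <- read_gene_sets(config$gene_sets)
    ann <- if (!is.null(config$sim) && is.null(config$annotations)) {
      simd$annotation
    } else {
      read_peptide_annotations(config$annotations)
    }
    hit_lists <- lapply(conds, function(cc) {
      cl <- fit$calls[fit$calls$condition == cc, ]
      map_peptides_to_genes(cl$peptide_id[cl$markov_positive], ann)
    })
    names(hit_lists) <- conds
    enr <- enrichment_table(hit_lists, sets,
                            background_size = config$background_size)
    enr_path <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(enr$results, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, enr_path)
    if (!is.null(enr$membership)) {
      mem_path <- file.path(config$out_dir, "membership.tsv")
      utils::write.table(cbind(gene = rownames(enr$membership),
                               as.data.frame(enr$membership)),
                         mem_path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, mem_path)
    }
  }

  manifest <- list(
    seed = config$seed,
    pairing = config$pairing,
    n_background = config$n_background,
    sd_multiplier = config$sd_multiplier,
    simulated = !is.null(config$sim),
    package_version = as.character(utils::packageVersion("kinomekin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    checksums = as.list(tools::md5sum(outputs)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(manifest)
}

#' Check the packaged published call table against its printed summaries
#'
#' Recomputes the eleven published summary counts from a call-table
#' transcription — total calls per substrate (63 ECM, 59 titanium), the
#' overlap partition (55 shared, 8 ECM-only, 4 titanium-only) and the
#' per-class call counts (ECM 43/16/4, titanium 37/10/12) — and reports
#' pass/fail per count.
#'
#' @param published call-table transcription; the packaged fixture by
#'   default.
#' @return data frame with columns `check`, `expected`, `observed`, `pass`;
#'   attribute `all_pass`.
#' @export
reproduce_published_counts <- function(published = load_published_calls()) {
  if (!is.data.frame(published) || nrow(published) == 0L) {
    kk_integrity_error("published call table is empty")
  }
  calls <- published_as_calls(published)
  ecm <- calls[calls$condition == "ECM", ]
  ti <- calls[calls$condition == "Ti", ]
  venn <- venn_overlap(ecm$peptide_id, ti$peptide_id)
  cc <- class_counts(calls)
  observed <- c(ecm_total = nrow(ecm), ti_total = nrow(ti),
                venn_both = venn$n_both, venn_ecm_only = venn$n_a_only,
                venn_ti_only = venn$n_b_only,
                ecm_early = cc["ECM", "early"], ecm_mid = cc["ECM", "mid"],
                ecm_late = cc["ECM", "late"],
                ti_early = cc["Ti", "early"], ti_mid = cc["Ti", "mid"],
                ti_late = cc["Ti", "late"])
  expected <- c(ecm_total = 63, ti_total = 59, venn_both = 55,
                venn_ecm_only = 8, venn_ti_only = 4, ecm_early = 43,
                ecm_mid = 16, ecm_late = 4, ti_early = 37, ti_mid = 10,
                ti_late = 12)
  report <- data.frame(check = names(expected), expected = unname(expected),
                       observed = unname(observed[names(expected)]),
                       stringsAsFactors = FALSE)
  report$pass <- report$expected == report$observed
  attr(report, "all_pass") <- all(report$pass)
  report
}
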
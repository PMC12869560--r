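# Pipeline orchestration: staged runs driven by one structured config
# file, with reproducibility manifests per stage.

#' Validate a pipeline configuration file
#'
#' Structural checks before any stage runs: known stage sections, split
#' fractions summing to 1, strictly increasing band edges, resolvable
#' constraint-rule fields, positive sizes and seeds present.
#'
#' @param config_path Path to a YAML (or JSON) config file.
#' @return `"ok"` if clean, otherwise a character vector of violations.
#' @export
validate_config <- function(config_path) {
  cfg <- read_config(config_path)
  v <- character(0)
  if (is.null(cfg$seed)) v <- c(v, "top-level 'seed' is required")
  known <- c("seed", "output", "simulate", "prepare", "train", "generate",
             "postprocess", "evaluate")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    v <- c(v, paste0("unknown config sections: ",
                     paste(extra, collapse = ", ")))
  fr <- cfg$prepare$fractions
  if (!is.null(fr)) {
    fr <- unlist(fr)
    if (abs(sum(fr) - 1) > 1e-8)
      v <- c(v, "prepare.fractions must sum to 1")
    if (any(fr <= 0)) v <- c(v, "prepare.fractions must be positive")
  }
  for (b in names(cfg$prepare$bands %||% list())) {
    e <- unlist(cfg$prepare$bands[[b]])
    if (any(diff(e) <= 0))
      v <- c(v, paste0("band edges for '", b,
                       "' must be strictly increasing"))
  }
  for (r in cfg$generate$rules %||% list()) {
    if (is.null(r$kind) ||
        !r$kind %in% c("forbid-token", "forbid-co-occurrence", "require-if"))
      v <- c(v, paste0("rule with unknown kind: ",
                       r$kind %||% "(missing)"))
    if (is.null(r$consequent) || length(r$consequent) == 0)
      v <- c(v, "rule with empty consequent")
  }
  n <- cfg$simulate$n_patients
  if (!is.null(n) && n < 1) v <- c(v, "simulate.n_patients must be >= 1")
  if (length(v) == 0) "ok" else v
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

write_manifest <- function(stage_dir, cfg, stage, seed, inputs, t0) {
  files <- list.files(stage_dir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  digests <- tryCatch(tools::md5sum(files), error = function(e) NULL)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("synthehr")),
    seed = seed,
    config = cfg,
    inputs = inputs,
    output_digests = as.list(digests),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 2),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the '", produced_by,
         "' stage first")
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (ground-truth cohort), `prepare` (aggregate codes,
#' fit bands, discretise, split, fit the reconstructor), `train` (engine
#' training), `generate` (sampling, optionally constrained/conditional),
#' `postprocess` (reconstruction to the three-table layout) and
#' `evaluate` (realism report against the held-out real test split).
#' Every stage writes its artifacts plus a `manifest.json` (config
#' snapshot, seed, file digests, timing) into `output_dir/<stage>/`.
#'
#' @param stage One of the six stage names.
#' @param config_path Path to the structured config file (see
#'   [validate_config()]).
#' @param output_dir Run directory shared by all stages.
#' @return Invisibly, a list with `status` (0 on success) and the
#'   manifest.
#' @export
run_stage <- function(stage = c("simulate", "prepare", "train", "generate",
                                "postprocess", "evaluate"),
                      config_path, output_dir) {
  stage <- match.arg(stage)
  cfg <- read_config(config_path)
  ok <- validate_config(config_path)
  if (!identical(ok, "ok"))
    stop("invalid config: ", paste(ok, collapse = "; "))
  seed <- as.integer(cfg$seed)
  sdir <- file.path(output_dir, stage)
  if (!dir.exists(sdir)) dir.create(sdir, recursive = TRUE)
  t0 <- Sys.time()
  message("[synthehr] stage '", stage, "' -> ", sdir)
  inputs <- character(0)

  if (stage == "simulate") {
    sc <- do.call(sim_config, c(cfg$simulate %||% list(),
                                list(seed = seed)))
    sim <- simulate_cohort(sc)
    write_cohort(sim$cohort, file.path(sdir, "cohort"))
    saveRDS(sim$schema, file.path(sdir, "schema.rds"))
    saveRDS(sim$truth, file.path(sdir, "truth.rds"))
    jsonlite::write_json(truth_check(sim$cohort, sim$truth),
                         file.path(sdir, "truth_check.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (stage == "prepare") {
    schema <- readRDS(need_artifact(
      file.path(output_dir, "simulate", "schema.rds"), "simulate"))
    inputs <- file.path(output_dir, "simulate", "cohort")
    cohort <- read_cohort(need_artifact(inputs, "simulate"), schema)
    pc <- cfg$prepare %||% list()
    agg <- aggregate_codes(cohort,
                           min_count = pc$min_count %||% 50L,
                           prefix_lengths = unlist(pc$prefix_lengths %||%
                                                     c(3L, 2L)))
    cohort <- agg$cohort
    parts <- split_cohort(cohort, unlist(pc$fractions %||%
                                           c(train = 0.8, validation = 0.1,
                                             test = 0.1)), seed = seed)
    schema_fit <- fit_bands(cohort$schema, parts$train,
                            n_bands = pc$n_bands %||% 20L)
    for (nm in names(parts)) parts[[nm]]$schema <- schema_fit
    toks <- lapply(parts, discretize, schema = schema_fit)
    recon <- fit_reconstructor(parts$train, schema_fit,
                               aggregation_map = agg$map)
    saveRDS(schema_fit, file.path(sdir, "schema_fitted.rds"))
    saveRDS(toks, file.path(sdir, "tokenized.rds"))
    saveRDS(parts, file.path(sdir, "splits.rds"))
    write_reconstructor(recon, file.path(sdir, "reconstructor.rds"))
  } else if (stage == "train") {
    toks <- readRDS(need_artifact(
      file.path(output_dir, "prepare", "tokenized.rds"), "prepare"))
    inputs <- file.path(output_dir, "prepare", "tokenized.rds")
    ec <- do.call(engine_config, c(cfg$train %||% list(),
                                   list(seed = seed)))
    model <- train_engine(toks$train, toks$validation, ec)
    saveRDS(model, file.path(sdir, "model.rds"))
    utils::write.csv(model$history, file.path(sdir, "history.csv"),
                     row.names = FALSE)
  } else if (stage == "generate") {
    model <- readRDS(need_artifact(
      file.path(output_dir, "train", "model.rds"), "train"))
    inputs <- file.path(output_dir, "train", "model.rds")
    gc_ <- cfg$generate %||% list()
    rules <- if (!is.null(gc_$rules))
      do.call(constraint_rules, gc_$rules) else NULL
    synth <- sample_patients(model,
                             n = gc_$n %||% length(model$vocab),
                             rng_seed = seed,
                             rules = rules,
                             condition_labels = gc_$condition_labels)
    saveRDS(synth, file.path(sdir, "synthetic_tokens.rds"))
  } else if (stage == "postprocess") {
    synth <- readRDS(need_artifact(
      file.path(output_dir, "generate", "synthetic_tokens.rds"), "generate"))
    recon <- read_reconstructor(need_artifact(
      file.path(output_dir, "prepare", "reconstructor.rds"), "prepare"))
    inputs <- file.path(output_dir, c("generate/synthetic_tokens.rds",
                                      "prepare/reconstructor.rds"))
    syn_cohort <- reconstruct_cohort(synth, recon, rng_seed = seed)
    write_cohort(syn_cohort, file.path(sdir, "cohort"))
  } else if (stage == "evaluate") {
    splits <- readRDS(need_artifact(
      file.path(output_dir, "prepare", "splits.rds"), "prepare"))
    syn_dir <- need_artifact(
      file.path(output_dir, "postprocess", "cohort"), "postprocess")
    inputs <- syn_dir
    schema <- readRDS(file.path(output_dir, "prepare", "schema_fitted.rds"))
    syn_cohort <- read_cohort(syn_dir, schema)
    ev <- cfg$evaluate %||% list()
    rep <- comparison_report(splits$test, syn_cohort,
                             max_lag = ev$max_lag %||% 30)
    jsonlite::write_json(tidy(rep), file.path(sdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(rep$summary_table, file.path(sdir, "summary_table.csv"),
                     row.names = FALSE)
  }
  manifest <- write_manifest(sdir, cfg, stage, seed, inputs, t0)
  invisible(list(status = 0L, manifest = manifest))
}
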
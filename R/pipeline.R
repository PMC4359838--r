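# End-to-end workflow: read -> screen -> learn structure -> information
# curves -> per-factor joint clustering -> reports. All outputs are
# deterministic functions of (input, config, master seed): no timestamps or
# machine entropy enter any file.

#' Pipeline configuration
#'
#' @param input Path to a symptom CSV, or a [symptom_matrix()].
#' @param out_dir Output directory (created if needed).
#' @param min_count Frequency-screen cutoff (required; see
#'   [screen_by_frequency()]).
#' @param factor_map Path to a factor-map JSON or a [syndrome_factor_map()].
#' @param threshold Information-coverage threshold in percent (default 95).
#' @param search A [search_config()]; its seed is overridden by `seed`.
#' @param scope Curve scope mode: `"model"` or `"children"`.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param mc_samples Monte-Carlo sample size for large-scope curves.
#' @param plots Also write PNG curve plots.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, min_count, factor_map,
                            threshold = 95, search = search_config(),
                            scope = c("model", "children"), seed = 1L,
                            mc_samples = 20000L, plots = FALSE) {
  scope <- match.arg(scope)
  if (threshold <= 0 || threshold > 100)
    stop_lantree("threshold must be in (0, 100]", "lantree_config_error")
  structure(list(input = input, out_dir = out_dir,
                 min_count = as.integer(min_count), factor_map = factor_map,
                 threshold = threshold, search = search, scope = scope,
                 seed = as.integer(seed), mc_samples = as.integer(mc_samples),
                 plots = isTRUE(plots)),
            class = "pipeline_config")
}

config_digest <- function(cfg) {
  s <- cfg
  s$input <- if (is.character(s$input)) basename(s$input) else "in-memory"
  s$factor_map <- if (is.character(s$factor_map)) basename(s$factor_map) else "in-memory"
  s$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full latent-structure analysis pipeline
#'
#' Stages: (1) read and validate the binary symptom matrix; (2) frequency
#' screen; (3) BIC-guided latent tree structure search
#' ([search_structure()]); (4) information curve and significant-manifest
#' list per latent variable; (5) per-factor joint clustering
#' ([build_jcm()]), with sub-syndrome splits ([subdivide()]) whenever the
#' factor's class variable has more than two states. Emits the learned model
#' (JSON + DOT), the search trace, per-latent curve TSVs, per-factor JCM
#' reports and a run manifest into `out_dir`; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `ltm_pipeline`: list with `data`, `model`,
#'   `bic`, `trace`, `curves`, `significant`, `jcms`, `out_dir`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }

  data <- stage("read", {
    if (inherits(cfg$input, "symptom_matrix")) cfg$input
    else read_symptom_matrix(cfg$input)
  })
  map <- stage("factor-map", {
    if (inherits(cfg$factor_map, "syndrome_factor_map")) cfg$factor_map
    else read_factor_map(cfg$factor_map)
  })

  screened <- stage("screen", screen_by_frequency(data, cfg$min_count))
  utils::write.table(prevalence_table(screened),
                     file.path(cfg$out_dir, "prevalence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  scfg <- cfg$search
  scfg$seed <- derive_seed(cfg$seed, "search")
  sr <- stage("structure-search", search_structure(screened, scfg))
  model <- sr$model
  write_model_json(model, file.path(cfg$out_dir, "model.json"))
  export_dot(model, file.path(cfg$out_dir, "model.dot"))
  utils::write.table(sr$trace, file.path(cfg$out_dir, "search_trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  curve_dir <- file.path(cfg$out_dir, "curves")
  dir.create(curve_dir, showWarnings = FALSE)
  lats <- latent_vars(model)
  curves <- list()
  signif <- list()
  for (y in lats) {
    curves[[y]] <- stage(paste0("curve-", y), information_curve(
      model, y, scope = if (cfg$scope == "children") "children" else NULL,
      mc_samples = cfg$mc_samples, seed = derive_seed(cfg$seed, paste0("curve-", y))))
    write_curve_tsv(curves[[y]], file.path(curve_dir, paste0(y, ".tsv")))
    if (cfg$plots) {
      grDevices::png(file.path(curve_dir, paste0(y, ".png")),
                     width = 900, height = 600)
      plot(curves[[y]], threshold = cfg$threshold)
      grDevices::dev.off()
    }
    signif[[y]] <- select_significant(curves[[y]], cfg$threshold)
  }
  sig_df <- do.call(rbind, lapply(names(signif), function(y)
    data.frame(latent = y, rank = seq_along(signif[[y]]),
               manifest = signif[[y]])))
  utils::write.table(sig_df, file.path(cfg$out_dir, "significant.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  jcm_dir <- file.path(cfg$out_dir, "jcm")
  dir.create(jcm_dir, showWarnings = FALSE)
  jcfg <- cfg$search
  jcfg$seed <- derive_seed(cfg$seed, "jcm")
  jcms <- list()
  fac_names <- names(map$factors)
  for (i in seq_along(fac_names)) {
    fac <- fac_names[[i]]
    j <- stage(paste0("jcm-", fac), build_jcm(
      model, screened, fac, map, cfg = jcfg, threshold = cfg$threshold,
      scope = cfg$scope, z_name = paste0("Z", i),
      mc_samples = cfg$mc_samples))
    if (j$cardinality > 2L)
      j <- stage(paste0("subdivide-", fac),
                 subdivide(j, screened, cfg = jcfg, threshold = cfg$threshold,
                           mc_samples = cfg$mc_samples))
    write_curve_tsv(j$curve, file.path(jcm_dir, paste0(fac, "_curve.tsv")))
    utils::write.table(
      data.frame(factor = fac, rank = seq_along(j$selected),
                 manifest = j$selected),
      file.path(jcm_dir, paste0(fac, "_selected.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    for (s in j$subsyndromes %||% list()) {
      if (!is.null(s$curve))
        write_curve_tsv(s$curve, file.path(jcm_dir, paste0(fac, "_", s$name, "_curve.tsv")))
      utils::write.table(
        data.frame(subsyndrome = s$name, rank = seq_along(s$selected),
                   manifest = s$selected),
        file.path(jcm_dir, paste0(fac, "_", s$name, "_selected.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jcms[[fac]] <- j
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lantree")),
    seed = cfg$seed,
    config_md5 = config_digest(cfg),
    n_records = nrow(data$values),
    n_symptoms_input = ncol(data$values),
    n_symptoms_screened = ncol(screened$values),
    n_latent = length(lats),
    bic = sr$bic,
    factors = lapply(jcms, function(j) list(
      z = j$z_name, cardinality = j$cardinality, members = j$members,
      selected = j$selected,
      subsyndromes = lapply(j$subsyndromes %||% list(), function(s)
        list(name = s$name, selected = s$selected)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(data = screened, model = model, bic = sr$bic,
                 trace = sr$trace, curves = curves, significant = signif,
                 jcms = jcms, out_dir = cfg$out_dir, manifest = manifest),
            class = "ltm_pipeline")
}

#' @export
print.ltm_pipeline <- function(x, ...) {
  cat(sprintf("Pipeline run: %d records, %d symptoms, %d latent variables, BIC %.2f\n",
              nrow(x$data$values), ncol(x$data$values),
              length(latent_vars(x$model)), x$bic))
  for (f in names(x$jcms)) {
    j <- x$jcms[[f]]
    cat(sprintf("  %s (%s, %d states): %s\n", f, j$z_name, j$cardinality,
                paste(j$selected, collapse = ", ")))
    for (s in j$subsyndromes %||% list())
      cat(sprintf("    %s: %s\n", s$name, paste(s$selected, collapse = ", ")))
  }
  invisible(x)
}
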
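# End-to-end pipeline orchestration: simulate -> signature -> enrichment ->
# phenotype, with a YAML-serialisable config and a machine-readable run
# manifest (config hash, seeds, versions, per-output checksums) from which
# a run is fully reproducible.

#' Default pipeline configuration
#'
#' Nested list with one section per stage; every randomised stage derives an
#' explicit seed from the top-level `seed`. The list serialises losslessly
#' to YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param out_dir run output directory.
#' @param seed master integer seed.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(out_dir, seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    seed = seed,
    stages = list(simulate = TRUE, signature = TRUE, enrich = TRUE,
                  fucci = TRUE, morph = TRUE),
    simulate = list(seed = seed, n_genes = 17004L,
                    planted_log2fc = 2, within_treatment_cv = 0.2,
                    n_replicates_per_condition = 1L,
                    gene_sets = list(n_sets = 50L, enrichment_factor = 5,
                                     size_range = c(100L, 2000L),
                                     seed = seed + 1L)),
    signature = list(min_abs_log2fc = 0.5, pseudocount = 0.5,
                     rpkm_threshold = "kmeans"),
    enrich = list(alternative = "two.sided"),
    fucci = list(n_cells = 200L, plateau = 0.9,
                 schedule = c("ENZA", "ENZA", "ENZA", "ENZA", "VEH"),
                 dormancy_level = 0.5, min_drop = 0.2, seed = seed + 2L),
    morph = list(n_cysts = 6L, n_spheroids = 6L, pixel_size_um = 1,
                 min_size_um = 50, seed = seed + 3L)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a `pipeline_config` list.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  if (is.null(config$out_dir) || !nzchar(config$out_dir))
    stop("config validation: out_dir is required")
  if (is.null(config$seed)) stop("config validation: seed is required")
  need <- c("stages", "simulate", "signature", "enrich", "fucci", "morph")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L)
    stop("config validation: missing section(s): ",
         paste(miss, collapse = ", "))
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, signature, enrich, fucci,
#' morph), writes every stage output as TSV/GMT/PNG under `config$out_dir`,
#' and finishes with `manifest.json` recording the config (and its MD5
#' hash), seeds, package and R versions, and an MD5 checksum for every
#' output file. Identical config and seed reproduce identical checksums. A
#' stage failure aborts the run with the failing stage named; outputs of
#' completed stages are retained.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage_env <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  run_stage("simulate", function() {
    sc <- config$simulate
    cfg <- sim_config(n_genes = sc$n_genes,
                      planted_log2fc = sc$planted_log2fc,
                      within_treatment_cv = sc$within_treatment_cv,
                      n_replicates_per_condition = sc$n_replicates_per_condition,
                      seed = sc$seed)
    sim <- simulate_expression(cfg)
    stage_env$sim <- sim
    outputs <<- c(outputs,
                  write_expression_tsv(sim$expr, file.path(out, "expression.tsv")),
                  write_truth_tsv(sim$truth, file.path(out, "truth.tsv")))
    gs <- sc$gene_sets
    sets <- simulate_gene_sets(sim$truth, n_sets = gs$n_sets,
                               enrichment_factor = gs$enrichment_factor,
                               size_range = unlist(gs$size_range),
                               seed = gs$seed)
    stage_env$sets <- sets
    outputs <<- c(outputs, write_gmt(sets, file.path(out, "gene_sets.gmt")))
  })

  run_stage("signature", function() {
    if (is.null(stage_env$sim))
      stage_env$sim <- list(expr = read_expression_tsv(
        file.path(out, "expression.tsv")))
    sg <- config$signature
    fit <- apdt_signature(stage_env$sim$expr,
                          min_abs_log2fc = sg$min_abs_log2fc,
                          pseudocount = sg$pseudocount,
                          rpkm_threshold = sg$rpkm_threshold)
    stage_env$fit <- fit
    outputs <<- c(outputs,
                  write_signature_tsv(fit, file.path(out, "signature.tsv")))
    pm <- percent_max_transform(
      stage_env$sim$expr$rpkm[fit$table$gene_id, , drop = FALSE])
    pm_df <- data.frame(gene_id = rownames(pm), pm, check.names = FALSE)
    f <- file.path(out, "percent_max.tsv")
    utils::write.table(pm_df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, f)
  })

  run_stage("enrich", function() {
    if (is.null(stage_env$sets))
      stage_env$sets <- read_gmt(file.path(out, "gene_sets.gmt"))
    universe <- rownames(stage_env$sim$expr$rpkm)
    res <- enrich_all(stage_env$sets, stage_env$fit, universe,
                      alternative = config$enrich$alternative)
    outputs <<- c(outputs,
                  write_enrichment_tsv(res, file.path(out, "enrichment.tsv")))
  })

  run_stage("fucci", function() {
    fc <- config$fucci
    traces <- simulate_fucci(n_cells = fc$n_cells,
                             schedule = unlist(fc$schedule),
                             plateau = fc$plateau, seed = fc$seed)
    traces <- classify_traces(traces)
    frac <- dormancy_fraction(traces)
    rev <- reversibility_test(frac, unlist(fc$schedule),
                              dormancy_level = fc$dormancy_level,
                              min_drop = fc$min_drop)
    outputs <<- c(outputs,
                  write_fucci_tsv(traces, file.path(out, "fucci_traces.tsv")))
    f <- file.path(out, "dormancy.tsv")
    utils::write.table(frac, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, f)
    jsonlite::write_json(rev, file.path(out, "reversibility.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, file.path(out, "reversibility.json"))
  })

  run_stage("morph", function() {
    mc <- config$morph
    masks <- simulate_masks(n_cysts = mc$n_cysts,
                            n_spheroids = mc$n_spheroids,
                            pixel_size_um = mc$pixel_size_um,
                            seed = mc$seed)
    rec <- measure_objects(masks$mask, mc$pixel_size_um)
    filt <- size_filter_and_count(rec, min_size_um = mc$min_size_um)
    outputs <<- c(outputs, write_mask_png(masks$mask,
                                          file.path(out, "mask.png")))
    for (nm in c("morphometry", "morphometry_counts")) {
      obj <- if (nm == "morphometry") rec else filt$counts
      f <- file.path(out, paste0(nm, ".tsv"))
      utils::write.table(obj, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <<- c(outputs, f)
    }
  })

  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("apdtsig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
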
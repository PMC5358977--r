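#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis with explicit
#' seeds, so a run is fully described by its configuration. The
#' configuration is serialized verbatim into the run manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param contours input contours: a `usv_collection` or a path to a
#'   contour CSV/JSON file. Ignored when `generate` is given.
#' @param generate optional [repertoire_config()]; when set, the input
#'   collection is generated rather than read.
#' @param hop optional common hop (seconds) to resample contours to before
#'   analysis.
#' @param jump_threshold step-detection threshold, kHz.
#' @param transition_entropy,convergence_tol,tsne_seed t-SNE stage
#'   parameters (see [embed_repertoire()]).
#' @param sigma density kernel width, map units.
#' @param grid_n grid cells per axis.
#' @param n_boot bootstrap replicates per group.
#' @param alpha nominal familywise level.
#' @param boot_seed seed of the bootstrap stage.
#' @param run_significance,run_steps,run_stats stage toggles.
#' @return an object of class `usv_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, contours = NULL, generate = NULL,
                            hop = NULL, jump_threshold = 10,
                            transition_entropy = 5, convergence_tol = 1e-4,
                            tsne_seed = 0L, sigma = 4, grid_n = 100L,
                            n_boot = 1000L, alpha = 0.05, boot_seed = 0L,
                            run_significance = TRUE, run_steps = TRUE,
                            run_stats = TRUE) {
  if (is.null(contours) && is.null(generate))
    stop("supply input 'contours' or a 'generate' config")
  structure(list(out_dir = out_dir, contours = contours, generate = generate,
                 hop = hop, jump_threshold = jump_threshold,
                 transition_entropy = transition_entropy,
                 convergence_tol = convergence_tol,
                 tsne_seed = as.integer(tsne_seed), sigma = sigma,
                 grid_n = as.integer(grid_n), n_boot = as.integer(n_boot),
                 alpha = alpha, boot_seed = as.integer(boot_seed),
                 run_significance = run_significance, run_steps = run_steps,
                 run_stats = run_stats),
            class = "usv_pipeline_config")
}

# config echo for the manifest, with non-serializable inputs summarized
.config_manifest <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$contours, "usv_collection"))
    cfg$contours <- sprintf("<in-memory collection of %d contours>",
                            length(cfg$contours))
  if (inherits(cfg$generate, "repertoire_config"))
    cfg$generate <- unclass(cfg$generate)
  cfg
}

#' Run the full repertoire analysis pipeline
#'
#' Executes the stages in dependency order — input (generate or read),
#' acoustic statistics, all-pairs DTW distances, t-SNE embedding, density
#' and bootstrap significance maps, and the map-based step analysis — and
#' writes each stage's output plus a run manifest (`manifest.json`)
#' recording the configuration and an MD5 hash of every output file.
#' Identical configurations (including seeds) produce identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest; on disk: `contours.csv`, `measures.csv`, `anova.json`,
#'   `dist.bin` (+ `.json` sidecar), `map.csv`, `significance.json`,
#'   `p_ht.csv`, `steps.json`, `manifest.json` under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "usv_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  outputs <- character()
  stage <- "input"
  res <- list()
  tryCatch({
    coll <- if (!is.null(config$generate)) generate_repertoire(config$generate)
            else if (inherits(config$contours, "usv_collection")) config$contours
            else read_contours(config$contours)
    if (!is.null(config$hop)) coll <- resample_collection(coll, config$hop)
    write_contours(coll, path("contours.csv"))
    outputs <- c(outputs, "contours.csv")
    res$collection <- coll
    analysis <- drop_clipped(coll)

    if (config$run_stats) {
      stage <- "stats"
      m <- measure_collection(analysis, config$jump_threshold)
      write.csv(m, path("measures.csv"), row.names = FALSE)
      outputs <- c(outputs, "measures.csv")
      anova_rep <- lapply(c(duration = "duration", bandwidth = "bandwidth",
                            mean_frequency = "mean_frequency"),
                          function(v) tryCatch(anova_by_measure(analysis, v),
                                               error = function(e)
                                                 list(error = conditionMessage(e))))
      jsonlite::write_json(anova_rep, path("anova.json"), auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, "anova.json")
      res$measures <- m; res$anova <- anova_rep
    }

    stage <- "distances"
    d <- all_pairs(analysis)
    write_distances(d, path("dist.bin"))
    outputs <- c(outputs, "dist.bin", "dist.bin.json")
    res$distances <- d

    stage <- "embed"
    map <- embed_repertoire(d, transition_entropy = config$transition_entropy,
                            convergence_tol = config$convergence_tol,
                            seed = config$tsne_seed)
    write_map(map, path("map.csv"))
    outputs <- c(outputs, "map.csv")
    res$map <- map
    grid <- grid_spec(map, n_x = config$grid_n, n_y = config$grid_n,
                      margin = 3 * config$sigma)

    if (config$run_significance) {
      stage <- "significance"
      ds <- density_significance(map, groups(analysis), grid = grid,
                                 sigma = config$sigma,
                                 n_boot = config$n_boot,
                                 alpha = config$alpha,
                                 seed = config$boot_seed)
      sig <- ds$signif
      jsonlite::write_json(
        list(H = ds$H, m = sig$m, alpha = sig$alpha,
             alpha_corrected = sig$alpha_corrected,
             n_cells = sig$grid$n_x * sig$grid$n_y,
             n_cells_ht_greater = sum(sig$mask_ht_greater),
             n_cells_wt_greater = sum(sig$mask_wt_greater)),
        path("significance.json"), auto_unbox = TRUE, digits = NA)
      write.csv(as.data.frame(sig$p_ht), path("p_ht.csv"), row.names = FALSE)
      outputs <- c(outputs, "significance.json", "p_ht.csv")
      res$density_significance <- ds
    }

    if (config$run_steps) {
      stage <- "steps"
      st <- step_analysis(map, analysis, grid = grid, sigma = config$sigma,
                          jump_threshold = config$jump_threshold)
      jsonlite::write_json(
        list(table = st$table, proportions = as.list(st$proportions),
             chi_square = st$chi_square, continuity_correction = TRUE,
             jump_threshold = config$jump_threshold),
        path("steps.json"), auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "steps.json")
      res$steps <- st
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "manifest"
  hashes <- as.list(tools::md5sum(file.path(config$out_dir, outputs)))
  names(hashes) <- outputs
  manifest <- list(config = .config_manifest(config), outputs = hashes)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
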
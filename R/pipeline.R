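#' Run the full modelling workflow end to end
#'
#' Orchestrates the stages: synthesise observations with a known ground
#' truth, fit the 3- and 4-state models by rejection sampling, compare them
#' by AIC, summarise cell-state compositions, and (optionally) run the
#' eFAST sensitivity analysis. Any stage can be skipped. Every source of
#' randomness derives from the single `seed`, and a manifest (config echo,
#' stage seeds, package version, timings, artifact inventory) is returned
#' and — when `out_dir` is given — written alongside CSV/JSON artifacts.
#'
#' @param design An [experiment_design()] (default RAW-like, TNF only).
#' @param spec_truth [model_spec()] used to generate the data (default
#'   3-state).
#' @param n_samples Prior draws per fit.
#' @param top_k Retained sets per fit.
#' @param prior A [prior_spec()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "fit3", "fit4", "compare", "compose", "efast")`.
#' @param efast_reps Stochastic replicates per eFAST set (default 5 here;
#'   raise to 30 for production-scale noise averaging).
#' @param efast_samples Samples per eFAST curve (default 65).
#' @param seed Global seed.
#' @param out_dir Optional output directory for artifacts + manifest.
#' @return A list of class `norm_pipeline` with `manifest` and the stage
#'   results (`observations`, `fit3`, `fit4`, `comparison`, `composition`,
#'   `sensitivity`).
#' @examples
#' \donttest{
#' res <- run_norm_pipeline(n_samples = 2000, stages = c("synth", "fit3"),
#'                          seed = 7)
#' res$manifest$stages
#' }
#' @export
run_norm_pipeline <- function(design = experiment_design("raw_like", proteins = "TNF"),
                              spec_truth = model_spec(3),
                              n_samples = 1e4, top_k = 50,
                              prior = prior_spec(),
                              stages = c("synth", "fit3", "fit4", "compare",
                                         "compose"),
                              efast_reps = 5, efast_samples = 65,
                              seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, c("synth", "fit3", "fit4", "compare",
                                "compose", "efast"), several.ok = TRUE)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "normacs",
    version = as.character(utils::packageVersion("normacs")),
    seed = seed,
    config = list(cell_type = design$cell_type, proteins = design$proteins,
                  conditions = design$conditions, times_h = design$times_h,
                  cells_per_sample = design$cells_per_sample,
                  n_samples = n_samples, top_k = top_k,
                  prior = unclass(prior), truth_states = spec_truth$n_states,
                  stages = stages),
    stages = list(), outputs = character(0))
  res <- list()
  stamp <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr()
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3),
                                     seed = seed)
    value
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(path)
      manifest$outputs <<- c(manifest$outputs, path)
    }
  }

  if ("synth" %in% stages) {
    res$observations <- stamp("synth", function()
      generate_observations(design, spec_truth, seed = seed))
    emit("observations.csv", function(p) write_observations(res$observations, p))
    emit("ground_truth.json", function(p)
      jsonlite::write_json(ground_truth(res$observations), p, digits = NA))
  }
  obs <- res$observations
  if (is.null(obs) && any(c("fit3", "fit4") %in% stages)) {
    stop("fit stages need the synth stage (or supply observations)", call. = FALSE)
  }
  if ("fit3" %in% stages) {
    res$fit3 <- stamp("fit3", function()
      rejection_fit(obs, model_spec(3), prior, n_samples, top_k, seed = seed + 1))
    emit("fit3.json", function(p)
      jsonlite::write_json(list(glance = glance(res$fit3), samples = tidy(res$fit3)),
                           p, digits = NA))
  }
  if ("fit4" %in% stages) {
    res$fit4 <- stamp("fit4", function()
      rejection_fit(obs, model_spec(4), prior, n_samples, top_k, seed = seed + 2))
    emit("fit4.json", function(p)
      jsonlite::write_json(list(glance = glance(res$fit4), samples = tidy(res$fit4)),
                           p, digits = NA))
  }
  if ("compare" %in% stages) {
    if (is.null(res$fit3) || is.null(res$fit4)) {
      stop("the compare stage needs both fit3 and fit4", call. = FALSE)
    }
    res$comparison <- stamp("compare", function() compare_models(res$fit3, res$fit4))
    emit("comparison.csv", function(p) readr::write_csv(res$comparison, p))
  }
  if ("compose" %in% stages) {
    readout <- if (design$cell_type == "raw_like") 16 else 12
    res$composition <- stamp("compose", function() {
      purrr::map_dfr(design$proteins, function(prot) {
        purrr::map_dfr(c("1000", "1000/1000"), function(cond) {
          rep_t <- readout + condition_clock_offset(cond)
          cc <- state_composition_report(design$truth[[prot]],
                                         condition_protocol(cond), rep_t,
                                         spec_truth)
          cc$protein <- prot; cc$condition <- cond
          cc
        })
      })
    })
    emit("composition.csv", function(p) readr::write_csv(res$composition, p))
  }
  if ("efast" %in% stages) {
    res$sensitivity <- stamp("efast", function() {
      d <- efast_design(n_samples = efast_samples, seed = seed + 3)
      y <- efast_run(d, condition_protocol("1000"),
                     readout_time_h = if (design$cell_type == "raw_like") 16 else 12,
                     n_replicates = efast_reps, base_seed = seed + 4)
      efast_analyze(d, y)
    })
    emit("efast.csv", function(p) readr::write_csv(tidy(res$sensitivity), p))
  }

  res$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest$outputs <- c(manifest$outputs, file.path(out_dir, "manifest.json"))
  }
  class(res) <- "norm_pipeline"
  res
}

#' @export
print.norm_pipeline <- function(x, ...) {
  cat("<norm_pipeline> stages:",
      paste(names(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$comparison)) {
    cat(sprintf("  preferred model: %d-state (mean AIC %.3g vs %.3g)\n",
                x$comparison$preferred, x$comparison$mean_aic_3,
                x$comparison$mean_aic_4))
  }
  invisible(x)
}
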
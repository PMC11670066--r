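#' Run the full Allee-effect analysis pipeline
#'
#' Reads the three input tables, computes neighbourhood metrics for every
#' sampled colony, fits and compares the candidate fertilization models,
#' analyses spawning synchrony and intensity, builds the cubic
#' approximation from the best nearest-neighbour model and evaluates the
#' site's fertilization potential (by both the cubic and the direct model
#' route). All stage outputs are written as CSV under `out_dir` and
#' returned as a bundle; given the same inputs and config the outputs are
#' identical run to run.
#'
#' @param config A [run_config()].
#' @param colony_path,events_path,samples_path Input CSV paths.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param quiet Suppress stage messages?
#' @return List of class `allee_report`: `metrics`, `comparison`,
#'   `best_fit`, `synchrony`, `intensity`, `curve`, `potential`,
#'   `potential_direct`.
#' @export
run_pipeline <- function(config, colony_path, events_path, samples_path,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$models))
    stop("configuration error: empty candidate-model list", call. = FALSE)
  say <- function(...) if (!quiet) message("[", ..., "]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  set.seed(config$seed)

  say("read: ", colony_path, ", ", events_path, ", ", samples_path)
  colonies <- stage("read", read_colony_table(colony_path))
  events <- stage("read", read_spawn_events(events_path))
  samples <- stage("read", read_fert_samples(samples_path))

  say("metrics: radii ", paste(config$radii, collapse = "/"),
      " m, lambda ", config$lambda, " m")
  metrics <- stage("metrics",
                   compute_all_metrics(unique(samples$colony_id), colonies,
                                       config))

  say("compare: ", length(config$models), " candidate models")
  comparison <- stage("compare",
                      compare_models(config$models, samples, metrics,
                                     events = events, colonies = colonies))
  best_fit <- attr(comparison, "fits")[[1]]

  say("synchrony: ", config$n_perm, " permutations, seed ", config$seed)
  dists <- pairwise_distances(colonies)
  pairs <- stage("synchrony", build_pairs(events, dists))
  synchrony <- stage("synchrony",
                     fit_synchrony_model(pairs, n_perm = config$n_perm,
                                         seed = config$seed))
  intensity <- stage("synchrony", compare_spawning_intensity(events))

  say("allee: cubic over [", config$grid[1], ", ", config$grid[2],
      "] m, step ", config$grid[3])
  if (!"nn" %in% names(best_fit$coefficients)) {
    nn_fit <- Filter(function(f) "nn" %in% names(f$coefficients),
                     attr(comparison, "fits"))
    if (!length(nn_fit))
      stop("stage 'allee': no candidate model carries the nn term",
           call. = FALSE)
    curve_fit <- nn_fit[[1]]
  } else curve_fit <- best_fit
  curve <- stage("allee", fit_cubic(curve_fit, grid = config$grid))
  nn_vals <- stats::setNames(metrics$nn_m, metrics$colony_id)
  potential <- stage("allee", fertilization_potential(curve, nn_vals))
  potential_direct <- stage("allee",
                            fertilization_potential(curve_fit, nn_vals))

  report <- structure(list(metrics = metrics, comparison = comparison,
                           best_fit = best_fit, synchrony = synchrony,
                           intensity = intensity, curve = curve,
                           potential = potential,
                           potential_direct = potential_direct),
                      class = "allee_report")
  if (!is.null(out_dir)) write_report(report, out_dir, config)
  report
}

write_report <- function(report, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  num <- function(x, digits = 10) formatC(x, digits = digits, format = "g")
  m <- as.data.frame(report$metrics)
  m[-1] <- lapply(m[-1], num)
  write_csv(m, file.path(out_dir, "neighborhood_metrics.csv"))
  writeLines(paste0("lambda_m,", config$lambda, "\nradii_m,",
                    paste(config$radii, collapse = ";")),
             file.path(out_dir, "metrics_meta.csv"))
  cmp <- as.data.frame(report$comparison)
  cmp$aic <- num(cmp$aic)
  cmp$intercept <- num(cmp$intercept)
  write_csv(cmp, file.path(out_dir, "model_comparison.csv"))
  writeLines(format_model_comparison(report$comparison),
             file.path(out_dir, "model_comparison.txt"))
  sy <- report$synchrony
  write_csv(data.frame(slope_min_per_m = num(sy$slope), se = num(sy$se),
                       naive_p = num(sy$naive_p), perm_p = num(sy$perm_p),
                       n_pairs = sy$n_pairs),
            file.path(out_dir, "synchrony.csv"))
  cv <- report$curve
  write_csv(data.frame(c3 = num(cv$c3), c2 = num(cv$c2), c1 = num(cv$c1),
                       c0 = num(cv$c0), F0 = num(cv$F0)),
            file.path(out_dir, "allee_curve.csv"))
  write_csv(data.frame(
    method = c("cubic", "direct"),
    fertilization_potential_pct =
      num(c(report$potential$fertilization_potential,
            report$potential_direct$fertilization_potential))),
    file.path(out_dir, "fertilization_potential.csv"))
  invisible(out_dir)
}

#' @export
print.allee_report <- function(x, ...) {
  cat("Allee-effect analysis report\n")
  cat("  best model:", x$comparison$model[1],
      sprintf("(AIC %.1f)\n", x$comparison$aic[1]))
  cat(sprintf("  synchrony slope: %.3f min/m (perm p %.3g)\n",
              x$synchrony$slope, x$synchrony$perm_p))
  cat(sprintf("  F0: %.1f%%; fertilization potential: %.1f%% (cubic), %.1f%% (direct)\n",
              x$curve$F0, x$potential$fertilization_potential,
              x$potential_direct$fertilization_potential))
  invisible(x)
}
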
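#' End-to-end BQQ analysis of a dataset
#'
#' Reads (or accepts) a long-format dataset, fits the benefit model,
#' EB-predicts individual benefits, and writes the full set of artifacts:
#' a fit summary (JSON), the benefit sample (CSV), the BQQ point set (CSV),
#' the BQQ plot (SVG or PNG) and the CVM discrepancies (JSON).
#'
#' @param data a [pm_data] object or a path to a long-format CSV.
#' @param y therapeutic target.
#' @param t benefit evaluation time, or `"max"` for the dataset maximum.
#' @param spec a [relm_spec].
#' @param out_dir output directory (created if needed).
#' @param plot_format `"svg"` or `"png"`.
#' @param drop_singletons passed to [eb_benefits()].
#' @return (invisibly) list with `fit`, `sample`, `points`, `cvm`, `paths`.
#' @export
run_fit_bqq <- function(data, y, t = "max", spec = relm_spec(),
                        out_dir = ".", plot_format = "svg",
                        drop_singletons = FALSE) {
  if (is.character(data)) data <- read_pm_data(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- fit_relm(data, spec)
  if (!fit$converged) stop("model fit did not converge")
  eb <- predict_random_effects(fit, data)
  tt <- if (identical(t, "max")) fit$max_time else as.numeric(t)
  sample <- eb_benefits(fit, eb, y = y, t = tt, drop_singletons = drop_singletons)
  points <- build_bqq(sample, fit)
  cvm <- cvm_sample(sample, fit)
  message("estimation: ", spec$method, "; t = ", tt,
          "; group sizes: ", paste(attr(sample, "group_sizes"), collapse = ", "))

  paths <- list(
    fit = file.path(out_dir, "fit_summary.json"),
    benefits = file.path(out_dir, "benefits.csv"),
    points = file.path(out_dir, "bqq_points.csv"),
    plot = file.path(out_dir, paste0("bqq_plot.", plot_format)),
    cvm = file.path(out_dir, "cvm.json"))
  write_json_file(list(
    method = spec$method, psi = as.list(fit$psi),
    Sigma = unname(apply(fit$Sigma, 1, as.list)),
    sigma2_eps = fit$sigma2_eps, loglik = fit$loglik,
    converged = fit$converged, singular = fit$singular,
    n_patients = fit$n_patients, t = tt, y = y), paths$fit)
  write_benefits(sample, paths$benefits)
  utils::write.csv(as.data.frame(points), paths$points,
                   row.names = FALSE, quote = FALSE)
  render_bqq(points, paths$plot)
  write_json_file(list(omega = as.list(cvm$omega), n_g = as.list(cvm$n_g),
                       omega_bar = cvm$omega_bar), paths$cvm)
  invisible(list(fit = fit, sample = sample, points = points, cvm = cvm,
                 paths = paths))
}

write_json_file <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required for JSON output")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run one simulation cell and write its artifacts
#'
#' Runs [run_scenario()] and writes the per-replicate discrepancy table, a
#' one-row summary (mean discrepancies per arm, ratio `R`, representative
#' replicate ids) and the representative replicate's BQQ plot for each arm.
#'
#' @param cfg a [scenario_config].
#' @param out_dir output directory.
#' @param plot_format `"svg"` or `"png"`.
#' @param method estimation method.
#' @return (invisibly) the `scenario_result`, with `paths` attached.
#' @export
run_simulation_cell <- function(cfg, out_dir = ".", plot_format = "svg",
                                method = "REML") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_scenario(cfg, method = method)
  tab <- cbind(scenario = cfg$scenario, param = cfg$param,
               N = cfg$N, n = cfg$n, res$table)
  paths <- list(table = file.path(out_dir, "replicates.csv"),
                summary = file.path(out_dir, "summary.csv"))
  utils::write.csv(tab, paths$table, row.names = FALSE, quote = FALSE)
  summary <- data.frame(scenario = cfg$scenario, param = cfg$param,
                        N = cfg$N, n = cfg$n, replicates = cfg$replicates,
                        omegabarbar_nonnormal = res$omega_barbar["nonnormal"],
                        omegabarbar_normal = res$omega_barbar["normal"],
                        R = res$R,
                        rep_nonnormal = res$representative["nonnormal"],
                        rep_normal = res$representative["normal"],
                        resimulations = res$resimulations)
  utils::write.csv(summary, paths$summary, row.names = FALSE, quote = FALSE)
  for (arm in c("nonnormal", "normal")) {
    det <- replicate_details(res, res$representative[[arm]], arm, method)
    p <- file.path(out_dir, paste0("bqq_representative_", arm, ".", plot_format))
    render_bqq(det$points, p)
    paths[[paste0("plot_", arm)]] <- p
  }
  attr(res, "paths") <- paths
  invisible(res)
}
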
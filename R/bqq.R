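#' Benefit quantile-quantile (BQQ) point set
#'
#' Within each covariate group `g` the EB-predicted benefits are sorted and
#' the `i`-th order statistic is paired with the plug-in theoretical quantile
#' `B((i - 0.5)/N_g; x_g, t)` derived from random-effect normality.  Points
#' scattered symmetrically about the `y = x` line support the normality
#' assumption; asymmetric deviations flag a misfit of the benefit model.
#' Ties among benefits are kept in stable patient-id order.
#'
#' @param sample a `benefit_sample` from [eb_benefits()].
#' @param fit the [relm_fit] the sample came from.
#' @return object of class `bqq_points`: data frame `theoretical`,
#'   `empirical`, `group`, `label`, `patient_id` with attributes `t`, `y`,
#'   `group_sizes`.
#' @export
build_bqq <- function(sample, fit) {
  stopifnot(inherits(sample, "benefit_sample"), inherits(fit, "relm_fit"))
  t <- attr(sample, "t"); y <- attr(sample, "y")
  if (any(table(sample$group) < 2))
    stop("BQQ plotting needs N_g >= 2 in every covariate group")
  pieces <- lapply(sort(unique(sample$group)), function(g) {
    sel <- sample$group == g
    x <- as.numeric(as.data.frame(sample)[which(sel)[1], fit$covariates])
    law <- benefit_law(fit, x, t, y)
    ord <- order(sample$benefit[sel], sample$patient_id[sel])
    n_g <- sum(sel)
    data.frame(theoretical = benefit_quantile((seq_len(n_g) - 0.5) / n_g, law),
               empirical = sample$benefit[sel][ord],
               group = g, label = sample$label[sel][1],
               patient_id = sample$patient_id[sel][ord],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, t = t, y = y,
            group_sizes = as.integer(table(out$group)),
            class = c("bqq_points", "data.frame"))
}

#' Plot a BQQ point set
#'
#' Square unit axes, the `y = x` reference line, and one marker shape per
#' covariate group (circles for the first group, triangles for the second).
#'
#' @param points a [build_bqq()] result.
#' @return a ggplot object.
#' @export
plot_bqq <- function(points) {
  stopifnot(inherits(points, "bqq_points"))
  df <- as.data.frame(points)
  df$label <- factor(df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical, y = .data$empirical,
                                   shape = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_shape_manual(values = rep(c(16, 17, 15, 3), length.out =
                                               nlevels(df$label))) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "theoretical quantile", y = "EB quantile",
                  shape = "group") +
    ggplot2::theme_bw()
}

#' Render a BQQ plot (or any ggplot) to SVG or PNG
#'
#' The format follows the file extension (`.svg` or `.png`).
#'
#' @param points a [build_bqq()] result or a ggplot object.
#' @param path output path ending in `.svg` or `.png`.
#' @param width,height device size in inches.
#' @export
render_bqq <- function(points, path, width = 5, height = 5) {
  p <- if (inherits(points, "bqq_points")) plot_bqq(points) else points
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else stop("unsupported plot format: ", ext)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Simulate a null dataset from a fitted model
#'
#' Draws responses at the observed design (same visit times, phases and
#' covariate patterns, hence the same group sizes) with normal random effects
#' `N(0, Sigma_hat)` and errors `N(0, sigma2_eps_hat)` — the null model under
#' which the BQQ plot should hug the diagonal.
#'
#' @param fit a [relm_fit].
#' @param data the [pm_data] supplying the design.
#' @return a [pm_data] with simulated responses.
#' @export
simulate_null_dataset <- function(fit, data) {
  stopifnot(inherits(fit, "relm_fit"), inherits(data, "pm_data"))
  spec <- fit$spec
  patients <- attr(data, "patients")
  X <- fixed_design(data, spec)
  Z <- random_design(data$time, spec)
  tau <- MASS::mvrnorm(length(patients), rep(0, ncol(fit$Sigma)), fit$Sigma)
  tau <- matrix(tau, nrow = length(patients))
  rows_tau <- tau[match(data$patient_id, patients), , drop = FALSE]
  y <- drop(X %*% fit$psi) + rowSums(Z * rows_tau) +
    stats::rnorm(nrow(data), 0, sqrt(fit$sigma2_eps))
  out <- as.data.frame(data)
  out$response <- y
  pm_data(out, covariates = attr(data, "covariates"))
}

#' Lineup of null-simulated BQQ plots around the observed one
#'
#' Simulates `K` datasets from the fitted null model (normal random effects),
#' refits the model to each, recomputes EB benefits and BQQ points, and
#' arranges the `K` null panels plus the observed-data panel in a grid with
#' the observed panel at a chosen (or random) position.  If the observed
#' panel can be singled out, the normality assumption is suspect.
#'
#' @param fit a converged [relm_fit].
#' @param data the observed [pm_data].
#' @param y therapeutic target.
#' @param t benefit evaluation time (default: maximum observed time).
#' @param K number of null panels (the display grid has `K + 1`).
#' @param seed integer seed driving all simulation randomness.
#' @param position position of the observed panel in the grid (default:
#'   centre slot, e.g. 5 of 9 when `K = 8`).
#' @param max_retries resimulation attempts per panel when a null fit fails.
#' @return object of class `bqq_lineup`: list with `panels` (list of
#'   `bqq_points`, observed panel included at `position`), `position`,
#'   `omega_bars` (per panel), `retries`, and `plot` (a faceted ggplot).
#' @export
bqq_lineup <- function(fit, data, y, t = fit$max_time, K = 8, seed = 1,
                       position = NULL, max_retries = 25) {
  stopifnot(K >= 1)
  if (!fit$converged) stop("lineup requires a converged fit")
  if (is.null(position)) position <- ceiling((K + 1) / 2)
  stopifnot(position >= 1, position <= K + 1)
  set.seed(seed)
  retries <- 0L
  nulls <- vector("list", K)
  null_omega <- numeric(K)
  for (k in seq_len(K)) {
    for (attempt in seq_len(max_retries)) {
      res <- tryCatch({
        sim <- simulate_null_dataset(fit, data)
        f2 <- fit_relm(sim, fit$spec)
        if (!f2$converged) stop("null fit did not converge")
        eb2 <- predict_random_effects(f2, sim)
        s2 <- eb_benefits(f2, eb2, y = y, t = t, warn_threshold = 0)
        list(points = build_bqq(s2, f2), omega_bar = cvm_sample(s2, f2)$omega_bar)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      retries <- retries + 1L
    }
    if (inherits(res, "error"))
      stop("null replicate ", k, " failed after ", max_retries,
           " attempts: ", conditionMessage(res))
    nulls[[k]] <- res$points
    null_omega[k] <- res$omega_bar
  }
  eb <- predict_random_effects(fit, data)
  obs_sample <- eb_benefits(fit, eb, y = y, t = t, warn_threshold = 0)
  obs <- build_bqq(obs_sample, fit)
  obs_omega <- cvm_sample(obs_sample, fit)$omega_bar
  panels <- append(nulls, list(obs), after = position - 1)
  omega_bars <- append(null_omega, obs_omega, after = position - 1)
  df <- do.call(rbind, lapply(seq_along(panels), function(i)
    cbind(as.data.frame(panels[[i]]), panel = i)))
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theoretical,
                                          y = .data$empirical,
                                          shape = factor(.data$label))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_shape_manual(values = c(16, 17, 15, 3)[
      seq_along(unique(df$label))]) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "theoretical quantile", y = "EB quantile",
                  shape = "group") +
    ggplot2::theme_bw()
  structure(list(panels = panels, position = position,
                 omega_bars = omega_bars, retries = retries, plot = plt),
            class = "bqq_lineup")
}
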
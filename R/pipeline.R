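#' Empirical SAR distribution under the pose law
#'
#' Draws M poses from the input distribution, evaluates the surrogate, and
#' summarizes the resulting SAR sample: percentile table (linear
#' interpolation between order statistics, i.e. [stats::quantile()] type 7)
#' and histogram counts for plotting.
#'
#' @param surrogate a [fit_lar()] surrogate.
#' @param dist pose [input_distribution()]; defaults to the surrogate's.
#' @param m number of draws (default 1e5).
#' @param seed RNG seed.
#' @param percentiles percent levels reported (50 and 95 always included).
#' @param bins histogram bin count.
#' @return object of class `sar_distribution`: `metric`, `samples`,
#'   `percentiles` (named vector), `histogram` (data frame of bin mids and
#'   counts), `m`, `seed`.
#' @export
sar_distribution <- function(surrogate, dist = surrogate$dist, m = 1e5, seed,
                             percentiles = c(5, 25, 50, 75, 95), bins = 50) {
  percentiles <- sort(unique(c(percentiles, 50, 95)))
  poses <- sample_pose_distribution(m, dist, seed)
  s <- predict(surrogate, poses)
  q <- stats::quantile(s, percentiles / 100, type = 7, names = FALSE)
  h <- graphics::hist(s, breaks = bins, plot = FALSE)
  structure(list(metric = surrogate$metric, samples = s,
                 percentiles = stats::setNames(q, paste0("p", percentiles)),
                 percent_levels = percentiles,
                 histogram = data.frame(mid = h$mids, count = h$counts),
                 m = m, seed = seed),
            class = "sar_distribution")
}

#' Percentile-level deviation between two SAR distributions
#'
#' (individual - reference) / reference x 100 at percentile q, with
#' percentiles taken by linear interpolation of order statistics from the
#' stored samples. The reference distribution is always the denominator.
#'
#' @param dist_ref,dist_ind [sar_distribution()]s of the same metric.
#' @param q percentile level(s) in (0, 100).
#' @return deviation(s) in percent.
#' @export
percentile_deviation <- function(dist_ref, dist_ind, q) {
  if (!is.null(dist_ref$metric) && !is.null(dist_ind$metric) &&
      !identical(dist_ref$metric, dist_ind$metric))
    stop("distributions describe different metrics")
  if (any(q <= 0 | q >= 100)) stop("q must lie in (0, 100)")
  vr <- stats::quantile(dist_ref$samples, q / 100, type = 7, names = FALSE)
  vi <- stats::quantile(dist_ind$samples, q / 100, type = 7, names = FALSE)
  if (any(vr == 0)) stop("reference percentile is zero; deviation undefined")
  (vi - vr) / vr * 100
}

# one deterministic forward evaluation of both study metrics for each pose
# row; observations are cached by design size so several surrogate fits can
# share a design without re-running the solver
make_forward_runner <- function(phantom, props, coil, table_offset = 0.05,
                                tilt_axis = "long", normalization = "raw_B1") {
  cache <- psar10g_cache(phantom, props)
  memo <- new.env(parent = emptyenv())
  run <- function(x) {
    x <- matrix(x, ncol = 2L)
    key <- paste0(nrow(x), ":", signif(sum(x), 12))
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- matrix(NA_real_, nrow(x), 2L,
                  dimnames = list(NULL, c("wbSAR", "pSAR10g")))
    for (i in seq_len(nrow(x))) {
      sar <- sar_field(phantom, props, coil, pose(x[i, 1], x[i, 2]),
                       table_offset, tilt_axis)
      sar <- normalize_sar(sar, phantom, props, normalization)
      out[i, 1] <- wb_sar(sar, phantom, props)
      out[i, 2] <- psar10g(sar, phantom, props, cache = cache)$value
    }
    memo[[key]] <- out
    out
  }
  list(both = run,
       wbSAR = function(x) run(x)[, "wbSAR"],
       pSAR10g = function(x) run(x)[, "pSAR10g"])
}

#' Default study configuration
#'
#' The full configuration of [run_study()] with every tunable at its
#' default; individual entries can be overridden via `...` (coil,
#' distribution, surrogate, seeds are themselves lists).
#'
#' @param ... named overrides merged over the defaults.
#' @return a config list.
#' @export
study_config <- function(...) {
  cfg <- list(
    coil = list(frequency = 64e6, b1 = 1e-6, length = 0.02, taper = 0.10,
                centre = 0),
    table_offset = 0.05,
    tilt_axis = "long",
    normalization = "raw_B1",
    distribution = list(mean = c(0, 0), sd = c(0.10 / 3, 5 / 3),
                        lower = c(-0.10, -5), upper = c(0.10, 5)),
    surrogate = list(p_range = 1:5, n_schedule = c(25, 50, 100),
                     threshold = 0.01, m = 1e5),
    seeds = list(phantom = 20190325, design = 1, distribution = 2),
    metrics = c("wbSAR", "pSAR10g"),
    percentiles = c(5, 25, 50, 75, 95),
    output_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read a study configuration from a YAML file
#'
#' Fields absent from the file keep their [study_config()] defaults.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(study_config, yaml::read_yaml(path))
}

config_distribution <- function(cfg) {
  d <- cfg$distribution
  input_distribution(d$mean, d$sd, d$lower, d$upper,
                     names = c("z_shift_m", "tilt_deg"))
}

config_coil <- function(cfg) do.call(coil_field, cfg$coil)

#' Run the full stochastic dosimetry study
#'
#' For a reference/individual phantom pair: (1) deterministic SAR metrics at
#' the standard position with reference-denominator deviations; (2) a shared
#' Latin-hypercube design in pose space evaluated through the forward model
#' for each phantom; (3) adaptive sparse polynomial-chaos fits per metric per
#' phantom; (4) SAR distributions from surrogate draws under the pose law;
#' (5) a percentile-level deviation table. All randomness flows from the
#' seeds in the config.
#'
#' @param pair a list with elements `reference` and `individual`, each a list
#'   `phantom` + `props` (as returned by [make_fixture_pair()]); if `NULL`
#'   the synthetic pair is generated from `cfg$seeds$phantom`.
#' @param cfg configuration from [study_config()] or [read_study_config()].
#' @return object of class `study_report`.
#' @export
run_study <- function(pair = NULL, cfg = study_config()) {
  if (is.null(pair))
    pair <- make_fixture_pair(seed = cfg$seeds$phantom)
  coil <- config_coil(cfg)
  dist <- config_distribution(cfg)
  models <- c("reference", "individual")

  standard <- lapply(models, function(m)
    sar_metrics(pair[[m]]$phantom, pair[[m]]$props, coil, pose(0, 0),
                cfg$table_offset, cfg$tilt_axis, cfg$normalization))
  names(standard) <- models
  std_dev <- vapply(c("wbSAR", "hdSAR", "pSAR10g"), function(k)
    weight_deviation(standard$reference[[k]], standard$individual[[k]]),
    numeric(1))

  runners <- lapply(models, function(m)
    make_forward_runner(pair[[m]]$phantom, pair[[m]]$props, coil,
                        cfg$table_offset, cfg$tilt_axis, cfg$normalization))
  names(runners) <- models
  sampler <- function(n) lhs_design(n, dist, seed = cfg$seeds$design + n)

  surrogates <- list()
  dists <- list()
  for (m in models) {
    surrogates[[m]] <- list()
    dists[[m]] <- list()
    for (met in cfg$metrics) {
      fit <- adaptive_fit(sampler, runners[[m]][[met]],
                          p_range = cfg$surrogate$p_range,
                          n_schedule = cfg$surrogate$n_schedule,
                          threshold = cfg$surrogate$threshold, metric = met)
      surrogates[[m]][[met]] <- fit
      dists[[m]][[met]] <- sar_distribution(
        fit, dist, m = cfg$surrogate$m, seed = cfg$seeds$distribution,
        percentiles = cfg$percentiles)
    }
  }

  qlev <- sort(unique(c(cfg$percentiles, 50, 95)))
  dev_tab <- do.call(rbind, lapply(cfg$metrics, function(met)
    data.frame(metric = met, percentile = qlev,
               reference = stats::quantile(dists$reference[[met]]$samples,
                                           qlev / 100, type = 7, names = FALSE),
               individual = stats::quantile(dists$individual[[met]]$samples,
                                            qlev / 100, type = 7, names = FALSE),
               deviation_pct = percentile_deviation(dists$reference[[met]],
                                                    dists$individual[[met]], qlev),
               stringsAsFactors = FALSE)))

  report <- structure(list(standard_position = standard,
                           standard_deviation_pct = std_dev,
                           surrogates = surrogates,
                           distributions = dists,
                           percentile_deviation = dev_tab,
                           config = cfg),
                      class = "study_report")
  if (!is.null(cfg$output_dir)) write_study_report(report, cfg$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n  standard position (reference vs individual):\n")
  for (k in names(x$standard_deviation_pct))
    cat(sprintf("    %-8s %.4g vs %.4g W/kg (deviation %+.2f%%)\n", k,
                x$standard_position$reference[[k]],
                x$standard_position$individual[[k]],
                x$standard_deviation_pct[[k]]))
  cat("  surrogate diagnostics (1 - Q2, %):\n")
  for (m in names(x$surrogates))
    for (met in names(x$surrogates[[m]]))
      cat(sprintf("    %-10s %-8s %.3g%% (N = %d, p = %d)%s\n", m, met,
                  100 * x$surrogates[[m]][[met]]$diagnostics$rel_err,
                  x$surrogates[[m]][[met]]$diagnostics$n,
                  x$surrogates[[m]][[met]]$diagnostics$p,
                  if (isTRUE(x$surrogates[[m]][[met]]$converged)) ""
                  else " [not converged]"))
  cat("  percentile deviations:\n")
  print(x$percentile_deviation, row.names = FALSE)
  invisible(x)
}

#' Write a study report's artifacts
#'
#' Report JSON (deterministic given the config seeds; no timestamps),
#' percentile/deviation and histogram CSVs, and serialized surrogates.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if missing).
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$percentile_deviation,
                   file.path(dir, "percentile_deviation.csv"), row.names = FALSE)
  for (m in names(report$distributions))
    for (met in names(report$distributions[[m]])) {
      d <- report$distributions[[m]][[met]]
      utils::write.csv(d$histogram,
                       file.path(dir, sprintf("hist_%s_%s.csv", m, met)),
                       row.names = FALSE)
      write_surrogate(report$surrogates[[m]][[met]],
                      file.path(dir, sprintf("surrogate_%s_%s.json", m, met)))
    }
  obj <- list(
    standard_position = lapply(report$standard_position, function(s)
      list(wbSAR = s$wbSAR, hdSAR = s$hdSAR, pSAR10g = s$pSAR10g,
           psar10g_location = as.integer(s$psar10g_location),
           normalization = s$normalization, pose = s$pose)),
    standard_deviation_pct = as.list(report$standard_deviation_pct),
    diagnostics = lapply(report$surrogates, function(g)
      lapply(g, function(s) c(s$diagnostics, converged = isTRUE(s$converged)))),
    percentiles = lapply(report$distributions, function(g)
      lapply(g, function(d) as.list(d$percentiles))),
    percentile_deviation = report$percentile_deviation,
    seeds = report$config$seeds)
  jsonlite::write_json(obj, file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Validate a surrogate against direct Monte-Carlo forward runs
#'
#' Pushes the same pose sample through the surrogate and through the
#' deterministic forward model and compares the resulting percentiles;
#' intended for small phantoms where direct evaluation is cheap.
#'
#' @param surrogate a [fit_lar()] surrogate.
#' @param model_runner function(x) mapping poses to the surrogate's metric.
#' @param n_mc number of Monte-Carlo poses (default 200).
#' @param seed RNG seed.
#' @param percentiles percent levels compared (default 50 and 95).
#' @return list: `percentiles` data frame (level, surrogate, direct,
#'   rel_gap), `max_rel_gap`.
#' @export
surrogate_vs_montecarlo <- function(surrogate, model_runner, n_mc = 200, seed,
                                    percentiles = c(50, 95)) {
  poses <- sample_pose_distribution(n_mc, surrogate$dist, seed)
  direct <- model_runner(poses)
  approx <- predict(surrogate, poses)
  qd <- stats::quantile(direct, percentiles / 100, type = 7, names = FALSE)
  qa <- stats::quantile(approx, percentiles / 100, type = 7, names = FALSE)
  gap <- abs(qa - qd) / abs(qd)
  list(percentiles = data.frame(level = percentiles, surrogate = qa,
                                direct = qd, rel_gap = gap),
       max_rel_gap = max(gap))
}
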
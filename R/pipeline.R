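# End-to-end orchestration: simulate/load -> label -> test -> compare,
# with validated configuration, structured logging of exclusions, and
# reproducible seeds.

#' Validated configuration of a dose-response mapping run
#'
#' @param cohort A `drm_cohort` (from [generate_cohort()] or
#'   [read_cohort_bundle()]), a [cohort_spec()] to generate from, or a
#'   bundle directory path.
#' @param endpoints Endpoints to analyse; default: all endpoints present
#'   in the cohort's toxicity table.
#' @param methods Subset of `c("uncorrected", "baseline_corrected")`.
#' @param statistic `"welch"` or `"mannwhitney"`.
#' @param alpha_beta Alpha/beta (Gy) used when generating from a spec.
#' @param cutpoint Dichotomization grade cutpoint (default 1).
#' @param n_iterations Permutations per endpoint-method (default 1000).
#' @param percentile Tmax percentile for the threshold (default 95).
#' @param tails `"both"`, `"upper"` or `"lower"`.
#' @param seed Master seed for the permutation streams.
#' @param output_dir Optional directory; when set, the summary JSON,
#'   per-analysis CSV artifacts and a config echo are written there.
#' @param run_shapiro Also run the per-voxel normality screen per group
#'   (slower; default FALSE).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort, endpoints = NULL,
                       methods = c("uncorrected", "baseline_corrected"),
                       statistic = c("welch", "mannwhitney"),
                       alpha_beta = 1, cutpoint = 1L,
                       n_iterations = 1000L, percentile = 95,
                       tails = c("both", "upper", "lower"),
                       seed = 1L, output_dir = NULL, run_shapiro = FALSE) {
  statistic <- match.arg(statistic); tails <- match.arg(tails)
  methods <- match.arg(methods, c("uncorrected", "baseline_corrected"),
                       several.ok = TRUE)
  if (n_iterations < 100L) stop("`n_iterations` must be at least 100")
  if (percentile <= 0 || percentile >= 100)
    stop("`percentile` must be in (0, 100)")
  structure(list(cohort = cohort, endpoints = endpoints, methods = methods,
                 statistic = statistic, alpha_beta = alpha_beta,
                 cutpoint = as.integer(cutpoint),
                 n_iterations = as.integer(n_iterations),
                 percentile = percentile, tails = tails,
                 seed = as.integer(seed), output_dir = output_dir,
                 run_shapiro = isTRUE(run_shapiro)),
            class = "run_config")
}

resolve_cohort <- function(cfg) {
  ch <- cfg$cohort
  if (inherits(ch, "drm_cohort")) return(ch)
  if (inherits(ch, "cohort_spec")) return(generate_cohort(ch, cfg$alpha_beta))
  if (is.character(ch) && length(ch) == 1L && dir.exists(ch))
    return(read_cohort_bundle(ch))
  stop("`cohort` must be a drm_cohort, a cohort_spec, or a bundle directory")
}

#' Run the full dose-response mapping analysis
#'
#' For every endpoint and labelling method: dichotomizes grades, splits
#' the map stack, computes the voxel-wise statistic map, permutation Tmax
#' thresholds and significance masks, and counts significant voxels. For
#' endpoints analysed under both methods, the Dice overlap of the two
#' significance masks is reported. Each endpoint-method analysis draws
#' its permutation seed deterministically from the master seed, so
#' repeated runs with an identical configuration are numerically
#' identical.
#'
#' @param cfg A [run_config()].
#' @return Object of class `drm_result`: `summary` (one row per
#'   endpoint-method: events, non-events, exclusions, thresholds,
#'   significant-voxel counts), `comparison` (per-endpoint method
#'   comparison incl. DSC), `analyses` (named list of
#'   [permutation_tmax()] results), `shapiro` (optional screens),
#'   `config` echo.
#' @export
run_drm_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- resolve_cohort(cfg)
  endpoints <- cfg$endpoints
  if (is.null(endpoints)) endpoints <- unique(cohort$grades$endpoint)
  missing_ep <- setdiff(endpoints, unique(cohort$grades$endpoint))
  if (length(missing_ep))
    stop("endpoints absent from the toxicity table: ",
         paste(missing_ep, collapse = ", "))
  stack <- cohort$stack
  analyses <- list(); shapiro <- list()
  rows <- list()
  for (ep in endpoints) {
    g <- cohort$grades[cohort$grades$endpoint == ep, , drop = FALSE]
    g <- g[order(g$patient_id), , drop = FALSE]
    if (nrow(g) != nrow(stack$X))
      stop(sprintf("endpoint %s: %d grade rows for %d patients", ep,
                   nrow(g), nrow(stack$X)))
    for (m in cfg$methods) {
      key <- paste(ep, m, sep = ".")
      lab <- dichotomize(g, method = m, cutpoint = cfg$cutpoint)
      n_ev <- sum(lab$event == 1, na.rm = TRUE)
      n_ne <- sum(lab$event == 0, na.rm = TRUE)
      n_ex <- sum(lab$excluded)
      if (n_ev < 2L || n_ne < 2L) {
        rows[[key]] <- data.frame(endpoint = ep, method = m, n_event = n_ev,
                                  n_nonevent = n_ne, n_excluded = n_ex,
                                  threshold_upper = NA_real_,
                                  threshold_lower = NA_real_,
                                  n_sig = NA_integer_,
                                  n_sig_high = NA_integer_,
                                  n_sig_low = NA_integer_,
                                  refused = TRUE, stringsAsFactors = FALSE)
        next
      }
      pseed <- patient_seed(cfg$seed, match(ep, endpoints),
                            match(m, cfg$methods))
      pr <- permutation_tmax(stack, lab, statistic = cfg$statistic,
                             n_iterations = cfg$n_iterations,
                             percentile = cfg$percentile, tails = cfg$tails,
                             seed = pseed)
      analyses[[key]] <- pr
      if (cfg$run_shapiro) {
        sp <- split_cohort(stack, lab)
        shapiro[[key]] <- list(event = shapiro_screen(sp$event),
                               nonevent = shapiro_screen(sp$nonevent))
      }
      rows[[key]] <- data.frame(endpoint = ep, method = m, n_event = n_ev,
                                n_nonevent = n_ne, n_excluded = n_ex,
                                threshold_upper = pr$threshold_upper,
                                threshold_lower = pr$threshold_lower,
                                n_sig = count_significant(pr$sig_mask),
                                n_sig_high = count_significant(pr$sig_mask_high),
                                n_sig_low = count_significant(pr$sig_mask_low),
                                refused = FALSE, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  res <- structure(list(summary = summary,
                        comparison = NULL, analyses = analyses,
                        shapiro = if (length(shapiro)) shapiro else NULL,
                        config = cfg, organ = stack$organ,
                        n_valid_voxels = sum(stack$valid)),
                   class = "drm_result")
  if (all(c("uncorrected", "baseline_corrected") %in% cfg$methods))
    res$comparison <- compare_methods(res)
  if (!is.null(cfg$output_dir)) write_drm_result(res, cfg$output_dir)
  res
}

#' @export
print.drm_result <- function(x, ...) {
  cat(sprintf("<drm_result> %s, %d analyses, %d valid voxels\n",
              x$organ, nrow(x$summary), x$n_valid_voxels))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("method comparison:\n")
    print(x$comparison, row.names = FALSE)
  }
  invisible(x)
}

#' Compare labelling methods endpoint by endpoint
#'
#' Builds the without/with baseline-correction comparison table: event
#' counts, significant-voxel counts and the Dice overlap of the two
#' significance masks, one row per endpoint analysed under both methods.
#'
#' @param result A `drm_result` from [run_drm_analysis()], or a list of
#'   two such results (`uncorrected` first) computed on the same cohort.
#' @return Data frame: endpoint, events and voxel counts per method, DSC.
#' @export
compare_methods <- function(result) {
  if (inherits(result, "drm_result")) {
    s <- result$summary; analyses <- result$analyses
  } else if (is.list(result) && length(result) == 2L &&
             all(vapply(result, inherits, logical(1), "drm_result"))) {
    a <- result[[1]]; b <- result[[2]]
    if (!identical(a$organ, b$organ) ||
        !identical(a$n_valid_voxels, b$n_valid_voxels))
      stop("results come from different cohorts")
    s <- rbind(a$summary, b$summary)
    analyses <- c(a$analyses, b$analyses)
  } else stop("`result` must be a drm_result or a list of two")
  eps <- intersect(s$endpoint[s$method == "uncorrected"],
                   s$endpoint[s$method == "baseline_corrected"])
  out <- lapply(eps, function(ep) {
    ru <- s[s$endpoint == ep & s$method == "uncorrected", ][1, ]
    rc <- s[s$endpoint == ep & s$method == "baseline_corrected", ][1, ]
    ku <- paste(ep, "uncorrected", sep = ".")
    kc <- paste(ep, "baseline_corrected", sep = ".")
    d <- if (!is.null(analyses[[ku]]) && !is.null(analyses[[kc]])) {
      dsc(analyses[[ku]]$sig_mask, analyses[[kc]]$sig_mask)$dsc
    } else NA_real_
    data.frame(endpoint = ep,
               events_uncorrected = ru$n_event,
               events_corrected = rc$n_event,
               voxels_uncorrected = ru$n_sig, voxels_corrected = rc$n_sig,
               dsc = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

write_drm_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$comparison))
    utils::write.csv(res$comparison, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  cfg <- res$config
  cfg$cohort <- if (is.character(cfg$cohort)) cfg$cohort else
    class(cfg$cohort)[1]
  class(cfg) <- NULL
  js <- list(config = cfg, organ = res$organ,
             n_valid_voxels = res$n_valid_voxels,
             summary = res$summary, comparison = res$comparison)
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (key in names(res$analyses)) {
    pr <- res$analyses[[key]]
    utils::write.csv(pr$observed$t, file.path(dir, paste0(key, "_tmap.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(tmax = pr$tmax_samples,
                                tmin = pr$tmin_samples),
                     file.path(dir, paste0(key, "_tmax_samples.csv")),
                     row.names = FALSE)
    utils::write.csv(pr$sig_mask * 1L,
                     file.path(dir, paste0(key, "_sigmask.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
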
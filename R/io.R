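#' Read and validate a breath-by-breath CSV
#'
#' Expected schema (comma separated, header, UTF-8): `breath_index`,
#' `t_start_s`, `f_i_n2o`, `f_et_n2o` and optionally `f_a_n2o`; gas
#' fractions as decimals. Validation failures name the offending rows.
#'
#' @param path CSV file path.
#' @return `data.frame` of class `"breath_series"`.
#' @export
read_breath_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("breath_index", "t_start_s", "f_i_n2o", "f_et_n2o")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fcols <- intersect(c("f_i_n2o", "f_et_n2o", "f_a_n2o"), names(d))
  for (cc in c(need, fcols)) {
    if (!is.numeric(d[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))
      stop(sprintf("non-numeric values in `%s` (row %s)", cc,
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  for (cc in fcols) {
    bad <- which(d[[cc]] < 0 | d[[cc]] > 1 | !is.finite(d[[cc]]))
    if (length(bad))
      stop(sprintf("`%s` outside [0, 1] at row %s", cc,
                   paste(head(bad, 5), collapse = ", ")))
  }
  if (is.unsorted(d$t_start_s, strictly = TRUE)) {
    bad <- which(diff(d$t_start_s) <= 0)[1] + 1L
    stop("`t_start_s` not strictly increasing at row ", bad)
  }
  structure(d, class = c("breath_series", "data.frame"))
}

#' @rdname read_breath_csv
#' @param breaths Breath series to write.
#' @export
write_breath_csv <- function(breaths, path) {
  write.csv(as.data.frame(breaths), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write thermodilution triplet CSVs
#'
#' Schema: `subject_id`, `time_s`, `q1`, `q2`, `q3`, `q_t_lmin`,
#' `accepted` (flows in L/min).
#'
#' @param path CSV file path.
#' @return `data.frame` of triplet measurements.
#' @export
read_thermo_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_s", "q_t_lmin", "accepted")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d$accepted <- as.logical(d$accepted)
  d
}

#' @rdname read_thermo_csv
#' @param thermo Triplet table to write.
#' @export
write_thermo_csv <- function(thermo, path) {
  write.csv(thermo, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Values that parse as numbers become numeric, `true`/`false`
#' become logical, comma-separated numbers become vectors.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

#' Estimate, align and pair a whole virtual study
#'
#' Runs the rolling estimator on every subject's breath series, determines
#' the per-subject reporting delay against the accepted thermodilution
#' series by regression, and pairs the delay-corrected series.
#'
#' @param study An `"ist_virtual_study"` from [run_virtual_study()].
#' @param window,stride,bounds Passed to [rolling_estimates()].
#' @param lag Fixed delay correction (s); when `NULL` (default) it is
#'   estimated per subject with [estimate_delay()].
#' @param tolerance Pairing tolerance (s), see [pair_measurements()].
#' @return List with `pairs` (all subjects pooled), `estimates` and
#'   `delays` (per subject).
#' @export
analyse_virtual_study <- function(study, window = 180, stride = 30,
                                  bounds = list(q_eff = c(0.5, 25),
                                                elv = c(0.2, 5)),
                                  lag = NULL, tolerance = 15) {
  stopifnot(inherits(study, "ist_virtual_study"))
  estimates <- list(); delays <- numeric(); pairs <- list()
  for (s in study$subjects) {
    est <- rolling_estimates(s$breaths, s$vent, study$cfg$wave,
                             window = window, stride = stride,
                             bounds = bounds)
    th <- s$thermo[s$thermo$accepted, , drop = FALSE]
    lg <- if (is.null(lag))
      as.numeric(estimate_delay(est, data.frame(time_s = th$time_s,
                                                value = th$q_t_lmin)))
    else lag
    pr <- pair_measurements(th, est, lag = lg, tolerance = tolerance)
    estimates[[as.character(s$id)]] <- est
    delays[as.character(s$id)] <- lg
    pairs[[as.character(s$id)]] <- pr
  }
  list(pairs = do.call(rbind, pairs), estimates = estimates,
       delays = delays)
}

#' Full agreement and trending report for paired measurements
#'
#' Computes everything the validation of a cardiac output monitor reports:
#' the repeatability coefficient of the reference, the interchangeability
#' rate, repeated-measures Bland-Altman of absolute values and of changes
#' from baseline, and the trending suite on consecutive paired changes
#' (four-quadrant concordance with regression, half-circle polar analysis
#' on the absolute and percent scales, and TIM class fractions).
#'
#' @param pairs `data.frame` with `subject_id`, `time_s`, `q_t_lmin`,
#'   `q_ist_lmin`.
#' @param triplets Thermodilution triplet table for
#'   [repeatability_coefficient()]; alternatively give `r_qt` directly.
#' @param r_qt Repeatability coefficient; overrides `triplets`.
#' @param exclusion_pct Trending exclusion zone (% of mean reference
#'   cardiac output), default 15.
#' @param baseline_until End of the baseline window (s), for the
#'   delta-from-baseline Bland-Altman and percent scaling.
#' @param tim_boundary Passed to [tim_classify()].
#' @return List with `agreement` (fields `bias`, `loa_low`, `loa_high`,
#'   `bias_ci`, `interchangeability_rate`, `repeatability_coefficient`,
#'   `n_pairs`, plus `delta_*` analogues from the baseline-referenced
#'   analysis) and `trend` (fields `concordance_4q`, `slope`, `intercept`,
#'   `r`, `angular_bias`, `radial_loa`, `polar_concordance`,
#'   `angular_bias_pct`, `polar_concordance_pct`, `tim_fractions`,
#'   `exclusion_threshold`, `n_included`).
#' @export
compare_methods <- function(pairs, triplets = NULL, r_qt = NULL,
                            exclusion_pct = 15, baseline_until = NULL,
                            tim_boundary = "printed") {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 4)
  if (is.null(r_qt)) {
    if (is.null(triplets)) stop("give either `triplets` or `r_qt`")
    r_qt <- repeatability_coefficient(triplets)
  }
  mean_q <- mean(pairs$q_t_lmin)
  inter <- interchangeability(pairs, r_qt)
  ba_abs <- bland_altman(pairs, mode = "absolute")
  ba_del <- bland_altman(pairs, mode = "delta", baseline_until = baseline_until)
  agreement <- list(bias = ba_abs$bias, loa_low = ba_abs$loa_low,
                    loa_high = ba_abs$loa_high, bias_ci = ba_abs$bias_ci,
                    interchangeability_rate = inter$rate,
                    repeatability_coefficient = r_qt,
                    n_pairs = nrow(pairs),
                    delta_bias = ba_del$bias, delta_loa_low = ba_del$loa_low,
                    delta_loa_high = ba_del$loa_high,
                    delta_bias_ci = ba_del$bias_ci)
  dl <- delta_pairs(pairs, reference = "previous", scale = "absolute",
                    baseline_until = baseline_until)
  fq <- four_quadrant(dl, mean_q, exclusion_pct)
  pa <- polar_analysis(dl, mean_q, exclusion_pct)
  dlp <- delta_pairs(pairs, reference = "previous", scale = "percent",
                     baseline_until = baseline_until)
  pap <- polar_analysis(dlp, 100 * 1, exclusion_pct)  # percent scale: radius in % of baseline
  tim <- tim_classify(pairs, r_qt, boundary = tim_boundary)
  trend <- list(concordance_4q = fq$concordance, slope = fq$slope,
                intercept = fq$intercept, r = fq$r,
                angular_bias = pa$angular_bias, radial_loa = pa$radial_loa,
                polar_concordance = pa$polar_concordance,
                angular_bias_pct = pap$angular_bias,
                polar_concordance_pct = pap$polar_concordance,
                tim_fractions = tim$fractions,
                exclusion_threshold = fq$exclusion_threshold,
                n_included = fq$n_included)
  list(agreement = agreement, trend = trend)
}

#' Run the complete virtual-study pipeline
#'
#' Chains [run_virtual_study()], [analyse_virtual_study()] and
#' [compare_methods()]; optionally writes all artifacts (per-subject
#' `breaths_*.csv`, `thermo_*.csv`, `truth_*.csv`, pooled `pairs.csv`, the
#' report JSON and a manifest recording seed and parameters) into
#' `outdir`. Rerunning with the same configuration reproduces every file.
#'
#' @param cfg A [scenario_config()].
#' @param outdir Output directory; created if missing. `NULL` (default)
#'   writes nothing.
#' @param ... Passed to [analyse_virtual_study()].
#' @return List with `report` (`agreement` + `trend`), `pairs`, `delays`,
#'   `study`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(scenario_config(n_subjects = 2, seed = 3))
#' res$report$trend$concordance_4q
#' }
run_pipeline <- function(cfg, outdir = NULL, ...) {
  stopifnot(inherits(cfg, "scenario_config"))
  study <- run_virtual_study(cfg)
  ana <- analyse_virtual_study(study, ...)
  thermo_all <- do.call(rbind, lapply(study$subjects, `[[`, "thermo"))
  report <- compare_methods(ana$pairs, triplets = thermo_all,
                            baseline_until = cfg$baseline_duration)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in study$subjects) {
      write_breath_csv(s$breaths,
                       file.path(outdir, sprintf("breaths_%02d.csv", s$id)))
      write_thermo_csv(s$thermo,
                       file.path(outdir, sprintf("thermo_%02d.csv", s$id)))
      write.csv(s$truth, file.path(outdir, sprintf("truth_%02d.csv", s$id)),
                row.names = FALSE, quote = FALSE)
    }
    write.csv(ana$pairs, file.path(outdir, "pairs.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(package = "istco",
                     version = as.character(utils::packageVersion("istco")),
                     seed = cfg$seed,
                     config = cfg[setdiff(names(cfg), "wave")],
                     wave = unclass(cfg$wave),
                     delays_s = as.list(ana$delays))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, pairs = ana$pairs, delays = ana$delays,
       study = study)
}
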
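#' Repeatability coefficient of the reference method
#'
#' Pooled within-triplet coefficient of variation of the accepted
#' thermodilution triplicates, scaled by the least-significant-change
#' factor: `CV = sqrt(mean((sd/mean)^2))` over triplets and
#' `R_QT = 1.96 * sqrt(2) * CV`. R_QT is the smallest fractional change in
#' the reference that is distinguishable from its own measurement noise.
#'
#' @param triplets `data.frame` with columns `q1`, `q2`, `q3` (L/min) and
#'   optionally `accepted` (only accepted rows are used), e.g. from
#'   [run_virtual_study()]; or a numeric matrix with one triplet per row.
#' @return R_QT as a dimensionless fraction.
#' @export
#' @examples
#' repeatability_coefficient(data.frame(q1 = 4.8, q2 = 5.0, q3 = 5.2))
repeatability_coefficient <- function(triplets) {
  if (is.matrix(triplets)) triplets <- as.data.frame(triplets) |>
      setNames(c("q1", "q2", "q3"))
  stopifnot(all(c("q1", "q2", "q3") %in% names(triplets)))
  if ("accepted" %in% names(triplets))
    triplets <- triplets[as.logical(triplets$accepted), , drop = FALSE]
  if (nrow(triplets) < 1L) stop("no accepted triplets")
  m <- as.matrix(triplets[, c("q1", "q2", "q3")])
  mu <- rowMeans(m)
  if (any(mu <= 0)) stop("triplet means must be positive")
  cv2 <- apply(m, 1, sd)^2 / mu^2
  1.96 * sqrt(2) * sqrt(mean(cv2))
}

#' Interchangeability of paired absolute measurements
#'
#' A pair is interchangeable when the two methods differ by less than the
#' maximal acceptable difference
#' `((q_t + q_ist)/2) * sqrt(R_QT^2 + R_QT^2)`, i.e. the disagreement is
#' within what two reference measurements could show by repeatability
#' alone.
#'
#' @param pairs `data.frame` with `q_t_lmin` and `q_ist_lmin`.
#' @param r_qt Repeatability coefficient (fraction, >= 0), from
#'   [repeatability_coefficient()].
#' @return List with per-pair logical `interchangeable`, the per-pair
#'   `threshold` (L/min), and `rate` (%).
#' @export
interchangeability <- function(pairs, r_qt) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0, r_qt >= 0)
  thr <- ((pairs$q_t_lmin + pairs$q_ist_lmin) / 2) * r_qt * sqrt(2)
  ok <- abs(pairs$q_t_lmin - pairs$q_ist_lmin) < thr
  list(interchangeable = ok, threshold = thr, rate = 100 * mean(ok))
}

#' Bland-Altman agreement adjusted for repeated measurements
#'
#' Differences `d = q_ist - q_t` are decomposed by subject: the limits of
#' agreement use `sd_adj^2 = between-subject variance of the subject-mean
#' differences + mean within-subject variance`, so that multiple
#' measurements per animal do not fake precision. The bias confidence
#' interval is computed from the subject-level mean differences
#' (t distribution, `n_subjects - 1` df). In `mode = "delta"` each
#' subject's values are first re-expressed as changes from that subject's
#' baseline mean (pairs with `time_s <= baseline_until`, or the first pair
#' when no baseline window is given), which removes between-subject offset
#' before the comparison.
#'
#' @param pairs `data.frame` with `subject_id`, `q_t_lmin`, `q_ist_lmin`
#'   (and `time_s` for `mode = "delta"`).
#' @param mode `"absolute"` or `"delta"` (changes from subject baseline).
#' @param baseline_until End of the baseline window (s), used only by
#'   `mode = "delta"`.
#' @return List with `bias`, `loa_low`, `loa_high`, `bias_ci` (length-2),
#'   `sd_adj`, `n_pairs`, `n_subjects`.
#' @export
bland_altman <- function(pairs, mode = c("absolute", "delta"),
                         baseline_until = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pairs),
            all(c("subject_id", "q_t_lmin", "q_ist_lmin") %in% names(pairs)))
  if (mode == "delta") {
    pairs <- do.call(rbind, lapply(split(pairs, pairs$subject_id), function(p) {
      p <- p[order(p$time_s), ]
      base <- if (!is.null(baseline_until)) which(p$time_s <= baseline_until) else 1L
      if (length(base) == 0L) base <- 1L
      p$q_t_lmin <- p$q_t_lmin - mean(p$q_t_lmin[base])
      p$q_ist_lmin <- p$q_ist_lmin - mean(p$q_ist_lmin[base])
      p
    }))
  }
  d <- pairs$q_ist_lmin - pairs$q_t_lmin
  by_subj <- split(d, pairs$subject_id)
  n_s <- length(by_subj)
  if (n_s < 2L) stop("repeated-measures adjustment needs >= 2 subjects")
  subj_means <- vapply(by_subj, mean, numeric(1))
  singletons <- vapply(by_subj, length, integer(1)) < 2L
  if (any(singletons))
    message(sprintf(
      "%d subject(s) with a single pair contribute only to the between-subject component",
      sum(singletons)))
  within <- vapply(by_subj[!singletons], var, numeric(1))
  sd_adj <- sqrt(var(subj_means) +
                   if (length(within)) mean(within) else 0)
  bias <- mean(d)
  se_bias <- sd(subj_means) / sqrt(n_s)
  ci <- bias + c(-1, 1) * qt(0.975, df = n_s - 1) * se_bias
  list(bias = bias, loa_low = bias - 1.96 * sd_adj,
       loa_high = bias + 1.96 * sd_adj, bias_ci = ci, sd_adj = sd_adj,
       n_pairs = length(d), n_subjects = n_s)
}

#' Paired changes between successive (or baseline-referenced) measurements
#'
#' Computes the per-subject changes in both methods between consecutive
#' paired measurements (`reference = "previous"`, the usual input to
#' trending analysis) or against the subject's baseline
#' (`reference = "baseline"`). The polar radius
#' `r = (dq_t + dq_ist)/2` is attached. On the percent scale, changes are
#' expressed relative to the subject's baseline mean.
#'
#' @param pairs `data.frame` with `subject_id`, `time_s`, `q_t_lmin`,
#'   `q_ist_lmin`.
#' @param reference `"previous"` or `"baseline"`.
#' @param scale `"absolute"` (L/min) or `"percent"`.
#' @param baseline_until End of the baseline window (s); defaults to the
#'   first pair per subject.
#' @return `data.frame` with `subject_id`, `time_s`, `dq_t`, `dq_ist`,
#'   `radius`.
#' @export
delta_pairs <- function(pairs, reference = c("previous", "baseline"),
                        scale = c("absolute", "percent"),
                        baseline_until = NULL) {
  reference <- match.arg(reference)
  scale <- match.arg(scale)
  stopifnot(all(c("subject_id", "time_s", "q_t_lmin", "q_ist_lmin") %in%
                  names(pairs)))
  out <- lapply(split(pairs, pairs$subject_id), function(p) {
    p <- p[order(p$time_s), ]
    if (nrow(p) < 2L) return(NULL)
    base_idx <- if (!is.null(baseline_until)) which(p$time_s <= baseline_until) else 1L
    if (length(base_idx) == 0L) base_idx <- 1L
    bt <- mean(p$q_t_lmin[base_idx]); bi <- mean(p$q_ist_lmin[base_idx])
    if (reference == "previous") {
      dt <- diff(p$q_t_lmin); di <- diff(p$q_ist_lmin); tt <- p$time_s[-1]
    } else {
      dt <- p$q_t_lmin - bt; di <- p$q_ist_lmin - bi; tt <- p$time_s
    }
    if (scale == "percent") { dt <- 100 * dt / bt; di <- 100 * di / bi }
    data.frame(subject_id = p$subject_id[1], time_s = tt,
               dq_t = dt, dq_ist = di, radius = (dt + di) / 2)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

# Shared exclusion rule: a change is kept when the magnitude of its polar
# radius reaches the exclusion threshold. One rule for both the
# four-quadrant and the polar analysis.
apply_exclusion <- function(deltas, mean_q, exclusion_pct) {
  stopifnot(mean_q > 0, exclusion_pct >= 0)
  thr <- exclusion_pct / 100 * mean_q
  deltas$included <- abs(deltas$radius) >= thr
  attr(deltas, "exclusion_threshold") <- thr
  deltas
}

#' Four-quadrant trending analysis
#'
#' Concordance is the percentage of included paired changes sharing the
#' same direction; changes with a small mean magnitude (polar radius below
#' `exclusion_pct`% of the mean cardiac output) are excluded as likely
#' noise. An OLS regression of `dq_ist` on `dq_t` and the Pearson
#' correlation over the included pairs are reported.
#'
#' @param deltas `data.frame` from [delta_pairs()].
#' @param mean_q Mean cardiac output (L/min) defining the exclusion zone.
#' @param exclusion_pct Exclusion zone as a percentage of `mean_q`,
#'   default 15.
#' @return List with `concordance` (%), `slope`, `intercept`, `r`,
#'   `n_included`, `exclusion_threshold` (L/min); `empty = TRUE` when no
#'   pair survives exclusion.
#' @export
four_quadrant <- function(deltas, mean_q, exclusion_pct = 15) {
  d <- apply_exclusion(deltas, mean_q, exclusion_pct)
  inc <- d[d$included, , drop = FALSE]
  thr <- attr(d, "exclusion_threshold")
  if (nrow(inc) == 0L)
    return(list(empty = TRUE, concordance = NA_real_, slope = NA_real_,
                intercept = NA_real_, r = NA_real_, n_included = 0L,
                exclusion_threshold = thr))
  conc <- 100 * mean(sign(inc$dq_t) == sign(inc$dq_ist))
  reg <- linear_regression(inc$dq_t, inc$dq_ist)
  list(empty = FALSE, concordance = conc, slope = reg$slope,
       intercept = reg$intercept, r = reg$r, n_included = nrow(inc),
       exclusion_threshold = thr)
}

# Half-circle polar angle (degrees) of one paired change. Points with a
# negative mean change are reflected through the origin so that every
# angle lands in (-90, 90] around the 45-degree line of identity.
polar_angle <- function(dq_t, dq_ist, radius) {
  neg <- radius < 0
  dq_t <- ifelse(neg, -dq_t, dq_t)
  dq_ist <- ifelse(neg, -dq_ist, dq_ist)
  atan2(dq_ist, dq_t) * 180 / pi - 45
}

#' Half-circle polar plot trending analysis
#'
#' Each paired change becomes a point with radius `(dq_t + dq_ist)/2` and
#' angle `atan2(dq_ist, dq_t) - 45` degrees, so perfect agreement sits on
#' the polar axis (0 degrees). Net-negative changes are reflected through
#' the origin onto the half circle. After the same radius exclusion as the
#' four-quadrant analysis, the angular bias (mean angle), radial limits of
#' agreement (bias +/- 1.96 SD of angles) and polar concordance
#' (% of points within the `concordance_band`) are reported.
#'
#' @inheritParams four_quadrant
#' @param concordance_band Half-width (degrees) of the good-trending band,
#'   default 30.
#' @return List with `angular_bias` (deg), `radial_loa` (length-2, deg),
#'   `polar_concordance` (%), `n_included`, `exclusion_threshold`,
#'   `angles` (deg, included points).
#' @export
polar_analysis <- function(deltas, mean_q, exclusion_pct = 15,
                           concordance_band = 30) {
  d <- apply_exclusion(deltas, mean_q, exclusion_pct)
  inc <- d[d$included, , drop = FALSE]
  thr <- attr(d, "exclusion_threshold")
  if (nrow(inc) == 0L)
    return(list(empty = TRUE, angular_bias = NA_real_,
                radial_loa = c(NA_real_, NA_real_),
                polar_concordance = NA_real_, n_included = 0L,
                exclusion_threshold = thr, angles = numeric(0)))
  th <- polar_angle(inc$dq_t, inc$dq_ist, inc$radius)
  bias <- mean(th)
  spread <- if (nrow(inc) > 1L) 1.96 * sd(th) else 0
  list(empty = FALSE, angular_bias = bias,
       radial_loa = bias + c(-1, 1) * spread,
       polar_concordance = 100 * mean(abs(th) <= concordance_band),
       n_included = nrow(inc), exclusion_threshold = thr, angles = th)
}

#' Trend interchangeability method (TIM)
#'
#' Classifies every consecutive change in the reference method. A change
#' is *interpretable* when the repeatability confidence intervals
#' `q * (1 -+ R_QT)` of the two reference values do not overlap (otherwise
#' the reference itself cannot resolve the change). Each interpretable
#' change is then classed by where the second pair `(q_t2, q_ist2)` falls
#' relative to two boundary lines anchored at the first pair (X on the
#' reference axis, Y on the test-method axis):
#' `X = Y(1 + R_QT) + (1 + R_QT)(q_t1 - q_ist1)` and
#' `X = Y(1 - R_QT) + (1 + R_QT)(q_t1 - q_ist1)`.
#' Between the lines: *interchangeable*. Outside, but with the point's own
#' precision interval `q_t2 * (1 -+ R_QT)` reaching a boundary:
#' *uncertain*. Otherwise *non-interchangeable*.
#'
#' The second boundary's intercept factor is implemented as printed in the
#' method description (an asymmetric `(1 + R_QT)`); `boundary =
#' "symmetric"` switches it to `(1 - R_QT)` in case the asymmetry is a
#' typesetting artefact.
#'
#' @param pairs `data.frame` with `subject_id`, `time_s`, `q_t_lmin`,
#'   `q_ist_lmin`, time-ordered within subject.
#' @param r_qt Repeatability coefficient, in (0, 1).
#' @param boundary `"printed"` (default) or `"symmetric"`.
#' @return List with per-change `classes` (factor: uninterpretable /
#'   interchangeable / uncertain / non-interchangeable) and `fractions`
#'   (named percentages over all consecutive changes, summing to 100).
#' @export
tim_classify <- function(pairs, r_qt, boundary = c("printed", "symmetric")) {
  boundary <- match.arg(boundary)
  stopifnot(r_qt > 0, r_qt < 1,
            all(c("subject_id", "time_s", "q_t_lmin", "q_ist_lmin") %in%
                  names(pairs)))
  if (any(pairs$q_t_lmin <= 0 | pairs$q_ist_lmin <= 0))
    stop("flows must be positive")
  f2 <- if (boundary == "printed") 1 + r_qt else 1 - r_qt
  classes <- unlist(lapply(split(pairs, pairs$subject_id), function(p) {
    p <- p[order(p$time_s), ]
    if (nrow(p) < 2L) return(character(0))
    vapply(seq_len(nrow(p) - 1L), function(i) {
      qt1 <- p$q_t_lmin[i];  qi1 <- p$q_ist_lmin[i]
      qt2 <- p$q_t_lmin[i + 1]; qi2 <- p$q_ist_lmin[i + 1]
      ci1 <- qt1 * c(1 - r_qt, 1 + r_qt)
      ci2 <- qt2 * c(1 - r_qt, 1 + r_qt)
      if (ci1[1] <= ci2[2] && ci2[1] <= ci1[2]) return("uninterpretable")
      x_hi <- qi2 * (1 + r_qt) + (1 + r_qt) * (qt1 - qi1)
      x_lo <- qi2 * (1 - r_qt) + f2 * (qt1 - qi1)
      b <- range(x_lo, x_hi)
      if (qt2 >= b[1] && qt2 <= b[2]) return("interchangeable")
      if (ci2[1] <= b[2] && b[1] <= ci2[2]) return("uncertain")
      "non-interchangeable"
    }, character(1))
  }), use.names = FALSE)
  lev <- c("uninterpretable", "interchangeable", "uncertain",
           "non-interchangeable")
  cl <- factor(classes, levels = lev)
  fr <- if (length(cl)) 100 * table(cl) / length(cl) else table(cl) * NA_real_
  list(classes = cl, fractions = setNames(as.numeric(fr), lev),
       n_changes = length(cl))
}

#' Ordinary least-squares line and Pearson correlation
#'
#' Thin wrapper over [stats::lm()] and [stats::cor()] used by the trending
#' analyses and the delay regression.
#'
#' @param x,y Numeric vectors of equal length (>= 3, `var(x) > 0`).
#' @return List with `slope`, `intercept`, `r`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (var(x) == 0) stop("degenerate x: zero variance")
  co <- coef(lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]), r = cor(x, y))
}
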
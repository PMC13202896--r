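#' Harrell's concordance index
#'
#' Over all comparable pairs (the patient with the shorter observed time had
#' an event; pairs tied on time are comparable only when exactly one is an
#' event, the event member counting as the earlier failure), a pair is
#' concordant when the earlier failure has the higher risk; risk ties score
#' 0.5. The confidence interval is a seeded patient-level percentile
#' bootstrap.
#'
#' @param risks Numeric risk scores.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param n_boot Bootstrap replicates for the CI (0 disables the CI).
#' @param conf_level Confidence level.
#' @param seed Bootstrap seed.
#' @return List with `c`, `ci` (or `NULL`), `n_pairs`.
#' @examples
#' rec <- survival_record(c(1, 2, 3), c(1, 1, 1))
#' harrell_cindex(c(3, 1, 2), rec, n_boot = 0)$c  # 2/3
#' @export
harrell_cindex <- function(risks, records, n_boot = 1000L,
                           conf_level = 0.95, seed = 1L) {
  te <- as_time_event(records)
  cstat <- function(r, time, event) {
    n <- length(r)
    Td <- outer(time, time, "<")
    Te <- outer(time, time, "==")
    Ev <- matrix(event == 1, n, n)          # row i: i is an event
    cmp <- (Td & Ev) | (Te & Ev & t(!Ev))   # i fails first
    diag(cmp) <- FALSE
    if (!any(cmp)) return(c(NA_real_, 0))
    Rgt <- outer(r, r, ">")
    Req <- outer(r, r, "==")
    conc <- sum(Rgt[cmp]) + 0.5 * sum(Req[cmp])
    c(conc / sum(cmp), sum(cmp))
  }
  base <- cstat(risks, te$time, te$event)
  if (is.na(base[1])) stop_moesurv("no comparable pairs")
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(risks)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cstat(risks[idx], te$time[idx], te$event[idx])[1]
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    a <- (1 - conf_level) / 2
    ci <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  }
  list(c = base[1], ci = ci, n_pairs = base[2])
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps \code{survival::survfit}; censored patients leave the risk set
#' just after their observed time.
#'
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @return Object of class `km_fit`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time).
#' @export
km_estimate <- function(records) {
  te <- as_time_event(records)
  fit <- survival::survfit(survival::Surv(te$time, te$event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("km_fit", "data.frame"))
}

#' @rdname km_estimate
#' @param fit A `km_fit`.
#' @param t Evaluation time(s).
#' @param left_limit Return `S(t-)` (the value just before `t`) instead of
#'   the right-continuous `S(t)`.
#' @export
km_surv_at <- function(fit, t, left_limit = FALSE) {
  vapply(t, function(tt) {
    keep <- if (left_limit) fit$time < tt else fit$time <= tt
    if (!any(keep)) 1 else fit$surv[max(which(keep))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Wraps \code{survival::survdiff} (standard observed-vs-expected
#' hypergeometric sums, chi-square on 1 degree of freedom).
#'
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(records, group) {
  te <- as_time_event(records)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop_moesurv("log-rank test needs exactly 2 groups")
  if (sum(te$event) < 1L) stop_moesurv("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(te$time, te$event) ~ g)
  list(statistic = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards regression
#'
#' Breslow-tie Cox regression via \code{survival::coxph}. `mode = "uni"`
#' fits each covariate alone; `mode = "multi"` fits them jointly.
#'
#' @param data Data frame of covariates.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param covariates Character vector of column names (default: all columns).
#' @param mode `"uni"` or `"multi"`.
#' @return Object of class `cox_fit`: list with `table` (term, beta, hr,
#'   ci lower/upper, wald p), `mode`, `fit` (the multi-mode `coxph` object,
#'   or the list of single fits), `baseline` (Breslow cumulative baseline
#'   hazard of the multi fit).
#' @export
cox_regression <- function(data, records, covariates = NULL,
                           mode = c("multi", "uni")) {
  mode <- match.arg(mode)
  te <- as_time_event(records)
  covariates <- covariates %||% colnames(data)
  const <- vapply(covariates, function(v) length(unique(data[[v]])) < 2L,
                  logical(1))
  if (any(const))
    stop_moesurv("constant covariate(s): %s",
                 paste(covariates[const], collapse = ", "))
  df <- data.frame(.time = te$time, .event = te$event,
                   data[covariates], check.names = FALSE)
  one_fit <- function(vars) {
    fm <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", vars), collapse = " + ")))
    fit <- survival::coxph(fm, data = df, ties = "breslow")
    if (!is.null(fit$info) && any(!is.finite(coef(fit))))
      stop_moesurv("Cox fit failed to converge")
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               beta = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               lower = s$conf.int[, "lower .95"],
               upper = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }
  if (mode == "uni") {
    tabs <- lapply(covariates, one_fit)
    tab <- do.call(rbind, tabs)
    fit_obj <- NULL
    baseline <- NULL
  } else {
    fm <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", covariates), collapse = " + ")))
    fit_obj <- survival::coxph(fm, data = df, ties = "breslow")
    if (any(!is.finite(stats::coef(fit_obj))))
      stop_moesurv("Cox fit failed to converge (possible separation)")
    s <- summary(fit_obj)
    tab <- data.frame(term = rownames(s$coefficients),
                      beta = s$coefficients[, "coef"],
                      hr = s$coefficients[, "exp(coef)"],
                      lower = s$conf.int[, "lower .95"],
                      upper = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      row.names = NULL)
    bh <- survival::basehaz(fit_obj, centered = FALSE)
    baseline <- data.frame(time = bh$time, cumhaz = bh$hazard)
  }
  structure(list(table = tab, mode = mode, fit = fit_obj,
                 covariates = covariates, data_ranges =
                   lapply(data[covariates], range), baseline = baseline),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit %s-variate>\n", x$mode))
  print(x$table, digits = 3)
  invisible(x)
}

#' Breslow baseline cumulative hazard from risk scores
#'
#' `H0(t) = sum_{event times s <= t} d_s / sum_{j in R(s)} exp(r_j)`; the
#' survival probability of a patient with risk `r` is
#' `S(t | r) = exp(-H0(t) exp(r))`. This converts the fusion network's
#' linear risk scores into absolute survival probabilities for calibration,
#' decision-curve analysis and nomograms.
#'
#' @param risks Training-set risk scores.
#' @param records Matching `survival_record`.
#' @return Object of class `breslow_baseline`: data frame `time`, `cumhaz`.
#' @export
breslow_baseline <- function(risks, records) {
  te <- as_time_event(records)
  er <- exp(risks - mean(risks))
  # centering only stabilizes the exponentials; survival_probability centers
  # the risks identically, so the product H0(t) exp(r) is unchanged
  ut <- sort(unique(te$time[te$event == 1]))
  cumhaz <- numeric(length(ut))
  acc <- 0
  for (k in seq_along(ut)) {
    s <- ut[k]
    d <- sum(te$time == s & te$event == 1)
    denom <- sum(er[te$time >= s])
    acc <- acc + d / denom
    cumhaz[k] <- acc
  }
  structure(list(time = ut, cumhaz = cumhaz, risk_center = mean(risks)),
            class = "breslow_baseline")
}

#' @rdname breslow_baseline
#' @param baseline A `breslow_baseline`.
#' @param new_risks Risk scores to convert.
#' @param t Horizon.
#' @return `survival_probability` returns `S(t | r)` for each risk.
#' @export
survival_probability <- function(baseline, new_risks, t) {
  h0 <- if (!any(baseline$time <= t)) 0
  else baseline$cumhaz[max(which(baseline$time <= t))]
  exp(-h0 * exp(new_risks - baseline$risk_center))
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' Cases are patients with an observed event by the horizon `t`; controls
#' are patients still event-free beyond `t`. Each case is weighted by
#' `1 / G(T_i-)` and each control by `1 / G(t)`, where `G` is the
#' Kaplan-Meier estimator of the censoring distribution, which removes the
#' bias from right censoring. With no censoring the weights are all 1 and
#' the measure reduces exactly to the binary AUC of event-by-t status.
#'
#' @param risks Numeric risk scores.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param horizon Evaluation time `t`.
#' @return AUC(t) in `[0, 1]`.
#' @export
td_roc <- function(risks, records, horizon) {
  te <- as_time_event(records)
  case <- te$time <= horizon & te$event == 1
  ctrl <- te$time > horizon
  if (!any(case)) stop_moesurv("no events by the horizon: AUC(t) undefined")
  if (!any(ctrl)) stop_moesurv("no survivors beyond the horizon: AUC(t) undefined")
  cens_fit <- km_estimate(list(time = te$time, event = 1 - te$event))
  w_case <- 1 / pmax(km_surv_at(cens_fit, te$time[case], left_limit = TRUE), 1e-10)
  w_ctrl <- rep(1 / pmax(km_surv_at(cens_fit, horizon), 1e-10), sum(ctrl))
  rc <- risks[case]; rk <- risks[ctrl]
  gt <- outer(rc, rk, ">")
  eq <- outer(rc, rk, "==")
  W <- w_case %o% w_ctrl
  sum(W * (gt + 0.5 * eq)) / sum(W)
}

#' Optimal ROC cutoff by the Youden index
#'
#' Scans the midpoints of adjacent sorted unique scores (a case is called
#' positive when its score exceeds the threshold) and returns the threshold
#' maximizing `J = sensitivity + specificity - 1`; ties are broken toward
#' the higher threshold (higher specificity).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
roc_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L)
    stop_moesurv("both classes must be present")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop_moesurv("scores are constant")
  thr <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stats_at <- vapply(thr, function(th) {
    pos <- scores > th
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  j <- stats_at[1, ]
  best <- max(which(j == max(j)))   # highest threshold among ties
  list(threshold = thr[best], j = j[best],
       sensitivity = stats_at[2, best], specificity = stats_at[3, best])
}

#' Calibration curve at a horizon
#'
#' Bins patients by predicted survival probability (tertiles by default);
#' within each bin the observed survival is the Kaplan-Meier estimate at the
#' horizon. Empty bins are merged with their lower neighbour (a message is
#' emitted).
#'
#' @param pred_surv Predicted survival probabilities at `horizon` in `[0, 1]`.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param horizon Evaluation time.
#' @param bins Number of bins.
#' @return Data frame with `bin`, `n`, `pred_mean`, `obs_surv`.
#' @export
calibration_curve <- function(pred_surv, records, horizon, bins = 3L) {
  if (any(pred_surv < 0 | pred_surv > 1))
    stop_moesurv("predicted probabilities must lie in [0, 1]")
  te <- as_time_event(records)
  qs <- stats::quantile(pred_surv, probs = seq(0, 1, length.out = bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  if (length(qs) - 1 < bins)
    message("calibration: merged empty/duplicate bins (",
            length(qs) - 1, " used)")
  grp <- cut(pred_surv, qs, labels = FALSE)
  out <- lapply(sort(unique(grp)), function(b) {
    sel <- grp == b
    km <- km_estimate(list(time = te$time[sel], event = te$event[sel]))
    data.frame(bin = b, n = sum(sel), pred_mean = mean(pred_surv[sel]),
               obs_surv = km_surv_at(km, horizon))
  })
  do.call(rbind, out)
}

#' Decision-curve analysis (net benefit)
#'
#' Event status at the horizon is taken from the observed data: patients
#' with an event by `t` are cases, patients followed beyond `t` are
#' controls, and patients censored before `t` are excluded (their count is
#' returned as an attribute). Net benefit at threshold probability `pt` is
#' `TP/n - FP/n * pt / (1 - pt)`; treat-all and treat-none references are
#' included.
#'
#' @param pred_event_prob Predicted event probability by the horizon.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @param horizon Evaluation time.
#' @param thresholds Threshold probabilities in (0, 1).
#' @return Data frame with `threshold`, `nb_model`, `nb_all`, `nb_none`;
#'   attribute `n_excluded` counts censored-before-horizon patients.
#' @export
decision_curve <- function(pred_event_prob, records, horizon,
                           thresholds = seq(0.05, 0.6, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_moesurv("thresholds must lie in (0, 1)")
  te <- as_time_event(records)
  keep <- !(te$time <= horizon & te$event == 0)
  excl <- sum(!keep)
  p <- pred_event_prob[keep]
  status <- as.integer(te$time[keep] <= horizon & te$event[keep] == 1)
  n <- length(p)
  prev <- mean(status)
  out <- t(vapply(thresholds, function(pt) {
    pos <- p > pt
    tp <- sum(pos & status == 1) / n
    fp <- sum(pos & status == 0) / n
    odds <- pt / (1 - pt)
    c(nb_model = tp - fp * odds,
      nb_all = prev - (1 - prev) * odds,
      nb_none = 0)
  }, numeric(3)))
  res <- data.frame(threshold = thresholds, out)
  attr(res, "n_excluded") <- excl
  res
}

#' Nomogram point mapping for a multivariate Cox model
#'
#' The covariate with the largest absolute linear-predictor range
#' (`|beta| * range`) spans 0-100 points; every other covariate is scaled
#' proportionally. Total points map back to the linear predictor and, via
#' the Breslow baseline, to survival probabilities at requested horizons.
#' Zero-range covariates are excluded with a message. The mapping is
#' invariant to rescaling all coefficients jointly with the point scale.
#'
#' @param fit A multivariate `cox_fit` from [cox_regression()].
#' @param horizons Optional horizons for survival-probability anchors.
#' @return Object of class `nomogram_map`: list with `points_per_unit`
#'   (data frame: term, beta, min, max, points_at_min/max), `scale`
#'   (points per unit of linear predictor), `offset`
#'   (`lp = total_points / scale + offset`), and `lp_to_surv(lp, t)` inputs
#'   (`baseline`).
#' @export
nomogram_points <- function(fit, horizons = NULL) {
  if (!inherits(fit, "cox_fit") || fit$mode != "multi")
    stop_moesurv("nomogram_points needs a multivariate cox_fit")
  tab <- fit$table
  rng <- fit$data_ranges[tab$term]
  span <- vapply(seq_len(nrow(tab)), function(j)
    abs(tab$beta[j]) * diff(rng[[j]]), numeric(1))
  drop_terms <- span == 0
  if (any(drop_terms)) {
    message("nomogram: excluded zero-range covariate(s): ",
            paste(tab$term[drop_terms], collapse = ", "))
    tab <- tab[!drop_terms, , drop = FALSE]
    rng <- rng[!drop_terms]
    span <- span[!drop_terms]
  }
  if (!nrow(tab)) stop_moesurv("no usable covariates for the nomogram")
  scale <- 100 / max(span)                   # points per unit of beta * x
  offset <- sum(vapply(seq_len(nrow(tab)), function(j)
    min(tab$beta[j] * rng[[j]]), numeric(1)))
  pts <- data.frame(term = tab$term, beta = tab$beta,
                    min = vapply(rng, min, numeric(1)),
                    max = vapply(rng, max, numeric(1)),
                    points_range = span * scale)
  structure(list(points = pts, scale = scale, offset = offset,
                 baseline = fit$baseline, horizons = horizons),
            class = "nomogram_map")
}

#' @rdname nomogram_points
#' @param map A `nomogram_map`.
#' @param newdata Data frame with the model covariates.
#' @return `nomogram_total_points` returns per-patient total points;
#'   `nomogram_lp` converts totals back to the linear predictor.
#' @export
nomogram_total_points <- function(map, newdata) {
  pts <- map$points
  rowSums(vapply(seq_len(nrow(pts)), function(j) {
    contr <- pts$beta[j] * newdata[[pts$term[j]]]
    (contr - min(pts$beta[j] * c(pts$min[j], pts$max[j]))) * map$scale
  }, numeric(nrow(newdata))))
}

#' @rdname nomogram_points
#' @param total_points Total point values.
#' @export
nomogram_lp <- function(map, total_points) {
  total_points / map$scale + map$offset
}

#' Stratify a cohort at a risk cutoff and compare survival
#'
#' @param risks Numeric risk scores.
#' @param cutoff Risk cutoff (high risk = `risk > cutoff`); must split the
#'   cohort into two non-empty groups.
#' @param records A `survival_record` or list/data frame with `time`, `event`.
#' @return List with `group` (factor), `km` (per-group `km_fit`s), and
#'   `logrank`.
#' @export
stratify_by_cutoff <- function(risks, cutoff, records) {
  te <- as_time_event(records)
  high <- risks > cutoff
  if (!any(high) || all(high))
    stop_moesurv("cutoff produces an empty risk group")
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  km <- lapply(split(seq_along(risks), grp), function(idx)
    km_estimate(list(time = te$time[idx], event = te$event[idx])))
  lr <- logrank_test(te, grp)
  list(group = grp, km = km, logrank = lr,
       sizes = table(grp))
}
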
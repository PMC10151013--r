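# Conditional pain-probability curves and per-call-period probability
# timelines built from a fitted model or directly supplied logistic
# coefficients.

#' Construct a conditional pain-probability curve
#'
#' A logistic mapping from a per-length impedance metric to the probability
#' of active knee pain: P(pain) = logistic(beta0 + beta1 x metric). Can be
#' built from directly supplied coefficients (e.g. a published model) or from
#' an OA-subset model fit via [curve_from_fit()].
#'
#' @param beta0 intercept (log-odds)
#' @param beta1 slope (log-odds per ohm/m)
#' @param metric which metric the curve is in: `"plr128"` or `"plx40"`
#' @param valid_range optional (min, max) ohm/m observed in the fitting data;
#'   evaluation outside it warns
#' @return a `probability_curve`
#' @export
probability_curve <- function(beta0, beta1, metric = c("plr128", "plx40"),
                              valid_range = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = beta0, beta1 = beta1, metric = metric,
                 valid_range = valid_range),
            class = "probability_curve")
}

#' Build a probability curve from a fitted OA-subset model
#'
#' Uses the intercept and the metric main effect of a model-3 style fit.
#'
#' @param fit a `kneebis_glmm` with coefficients named `(Intercept)` and `plz`
#' @param metric metric label for the curve
#' @param valid_range optional operating range
#' @return a [probability_curve()]
#' @export
curve_from_fit <- function(fit, metric = c("plr128", "plx40"),
                           valid_range = NULL) {
  stopifnot(inherits(fit, "kneebis_glmm"))
  co <- fit$coefficients
  if (!all(c("(Intercept)", "plz") %in% names(co)))
    stop("fit must contain `(Intercept)` and `plz` terms", call. = FALSE)
  probability_curve(co[["(Intercept)"]], co[["plz"]], metric,
                    valid_range = valid_range)
}

#' Evaluate a probability curve
#'
#' @param curve a [probability_curve()]
#' @param value metric value(s) in ohm/m
#' @return probability in (0, 1); values outside the curve's `valid_range`
#'   trigger a warning, not an error
#' @export
#' @examples
#' cv <- probability_curve(-4.850, 0.007, "plr128")
#' probability(cv, 500.8) # ~0.207
probability <- function(curve, value) {
  stopifnot(inherits(curve, "probability_curve"), all(is.finite(value)))
  if (!is.null(curve$valid_range) &&
      any(value < curve$valid_range[1] | value > curve$valid_range[2]))
    warning("metric value outside the curve's fitted operating range")
  stats::plogis(curve$beta0 + curve$beta1 * value)
}

#' Per-call-period probability timeline for one participant
#'
#' One entry per kept call period, ordered by (day, call): the period's mean
#' metric value and its pain probability under the curve.
#'
#' @param curve a [probability_curve()]
#' @param reduced reduced-metrics table (see [reduce_study()])
#' @param participant_id participant to extract
#' @param configuration electrode configuration (default `"trans"`)
#' @return data.frame `participant_id, day, call, value, probability`,
#'   class `probability_timeline`
#' @export
timeline <- function(curve, reduced, participant_id, configuration = "trans") {
  col <- if (curve$metric == "plr128") "plr128_mean" else "plx40_mean"
  d <- reduced[reduced$participant_id == participant_id &
                 reduced$config == configuration & !is.na(reduced[[col]]), ,
               drop = FALSE]
  if (nrow(d) == 0L) {
    warning("no kept call periods for participant ", participant_id)
    out <- data.frame(participant_id = character(), day = integer(),
                      call = integer(), value = numeric(),
                      probability = numeric())
    class(out) <- c("probability_timeline", class(out))
    return(out)
  }
  d <- d[order(d$day, d$call), , drop = FALSE]
  out <- data.frame(participant_id = d$participant_id, day = d$day,
                    call = d$call, value = d[[col]],
                    probability = round(probability(curve, d[[col]]), 3))
  rownames(out) <- NULL
  class(out) <- c("probability_timeline", class(out))
  out
}

#' Group-by-pain metric means
#'
#' Arithmetic means of a metric over kept call periods grouped by
#' (group, pain outcome). Cells with no periods are reported as missing
#' rather than erroring (a control group without pain reports is expected).
#'
#' @param reduced reduced-metrics table
#' @param metric `"plr128"` or `"plx40"`
#' @param configuration electrode configuration
#' @param subset `"all"` or `"OA_only"`
#' @return data.frame `group, pain, mean, n` including missing cells (n = 0,
#'   mean NA)
#' @export
group_contrast <- function(reduced, metric = c("plr128", "plx40"),
                           configuration = "trans",
                           subset = c("all", "OA_only")) {
  metric <- match.arg(metric)
  subset <- match.arg(subset)
  col <- paste0(metric, "_mean")
  d <- reduced[reduced$config == configuration & !is.na(reduced[[col]]) &
                 !is.na(reduced$pain), , drop = FALSE]
  if (subset == "OA_only") d <- d[d$group == 1, , drop = FALSE]
  cells <- expand.grid(group = sort(unique(d$group)), pain = c(0L, 1L))
  cells$mean <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    v <- d[[col]][d$group == cells$group[i] & d$pain == cells$pain[i]]
    cells$n[i] <- length(v)
    if (length(v)) cells$mean[i] <- mean(v)
  }
  cells
}
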
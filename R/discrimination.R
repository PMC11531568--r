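#' Measured donor-acceptor distance set with censoring
#'
#' Holds the experimentally determined distance (with uncertainty) for each
#' labelling combination, or a censored lower bound for combinations where
#' no FRET signal was detectable. A censored bound is derived from a
#' detection threshold on the efficiency (default E = 0.1) through the
#' distance conversion: any pair further apart than
#' `efficiency_to_distance(E_detect, R0)` would produce no detectable
#' signal.
#'
#' @param pairs Character vector of combination labels (e.g. `"T-T"`,
#'   `"T-H/H-T"`, `"H-H"`).
#' @param R_nm Measured distances in nm (`NA` for censored entries).
#' @param sigma_nm Distance uncertainties in nm (`NA` for censored).
#' @param censored Logical; censored entries carry a lower bound instead of
#'   a distance.
#' @param R_min_nm Lower bounds for censored entries (`NA` otherwise); when
#'   missing they are derived from `E_detect` and `R0`.
#' @param E_detect,R0 Detection threshold and Forster radius used to derive
#'   missing bounds.
#' @return data.frame of class `measured_distance_set`.
#' @export
measured_distance_set <- function(pairs, R_nm, sigma_nm,
                                  censored = is.na(R_nm), R_min_nm = NULL,
                                  E_detect = 0.1, R0 = 6.30) {
  stopifnot(length(pairs) == length(R_nm), length(R_nm) == length(sigma_nm))
  if (all(censored)) stop("need at least one uncensored distance")
  if (is.null(R_min_nm)) R_min_nm <- rep(NA_real_, length(pairs))
  derive <- censored & is.na(R_min_nm)
  R_min_nm[derive] <- efficiency_to_distance(E_detect, R0)
  out <- data.frame(pair = pairs, R_nm = R_nm, sigma_nm = sigma_nm,
                    censored = censored, R_min_nm = R_min_nm,
                    stringsAsFactors = FALSE)
  class(out) <- c("measured_distance_set", class(out))
  out
}

#' Chi-square agreement of a dimer-form prediction with measured distances
#'
#' Uncensored pairs contribute \eqn{((R_{meas} - R_{pred})/\sigma_R)^2}.
#' Censored ("no FRET") pairs contribute nothing when the predicted distance
#' respects the lower bound, and \eqn{((R_{min} - R_{pred})/\sigma_{floor})^2}
#' when it violates it.
#'
#' @param measured [measured_distance_set()].
#' @param predicted `dimer_form_prediction` or any data.frame with columns
#'   `pair` and a predicted distance column (`R_E_nm` preferred, `R_nm`
#'   accepted).
#' @param sigma_floor Uncertainty used for violated censored bounds;
#'   defaults to the mean uncensored sigma.
#' @return List of class `form_score`: `chisq`, `dof`, `residuals`
#'   (per-pair data.frame), `form`.
#' @export
score_form <- function(measured, predicted, sigma_floor = NULL) {
  pred_col <- intersect(c("R_E_nm", "R_nm", "R_pred_nm"), names(predicted))[1]
  if (is.na(pred_col)) stop("prediction lacks a distance column")
  common <- intersect(measured$pair, predicted$pair)
  if (length(common) == 0L) stop("no common pair keys")
  m <- measured[match(common, measured$pair), ]
  p <- predicted[match(common, predicted$pair), ]
  if (is.null(sigma_floor)) sigma_floor <- mean(m$sigma_nm[!m$censored])
  res <- numeric(length(common))
  for (i in seq_along(common)) {
    if (!m$censored[i]) {
      res[i] <- (m$R_nm[i] - p[[pred_col]][i]) / m$sigma_nm[i]
    } else if (p[[pred_col]][i] >= m$R_min_nm[i]) {
      res[i] <- 0
    } else {
      res[i] <- (m$R_min_nm[i] - p[[pred_col]][i]) / sigma_floor
    }
  }
  structure(list(
    chisq = sum(res^2), dof = sum(!m$censored),
    residuals = data.frame(pair = common, measured_R = m$R_nm,
                           predicted_R = p[[pred_col]], censored = m$censored,
                           residual = res),
    form = attr(predicted, "form") %||% "candidate"),
    class = "form_score")
}

#' Rank candidate dimer forms against measured distances
#'
#' Scores every candidate with [score_form()] and sorts ascending by
#' chi-square. The chi-square here is a descriptive selection statistic that
#' formalizes a comparison otherwise argued from the distance tables; ties
#' are reported explicitly, and a best candidate whose reduced chi-square
#' exceeds `quantitative_threshold` is flagged as lacking quantitative
#' agreement (a form can be favoured without matching within the stated
#' uncertainties).
#'
#' @param measured [measured_distance_set()].
#' @param predictions Named list of predictions (see [score_form()]).
#' @param sigma_floor Passed to [score_form()].
#' @param quantitative_threshold Reduced chi-square above which the best
#'   form is flagged (default 3).
#' @return List of class `form_ranking`: `table` (form, chisq, dof,
#'   delta_chisq), `scores`, `best`, `tie`, `quantitative_agreement`.
#' @export
select_form <- function(measured, predictions, sigma_floor = NULL,
                        quantitative_threshold = 3) {
  if (length(predictions) < 2L) stop("need at least two candidate forms")
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    names(predictions) <- vapply(predictions, function(p) {
      attr(p, "form") %||% "candidate"
    }, "")
  }
  scores <- lapply(predictions, score_form, measured = measured,
                   sigma_floor = sigma_floor)
  chis <- vapply(scores, `[[`, numeric(1), "chisq")
  ord <- order(chis)
  tab <- data.frame(form = names(predictions)[ord], chisq = chis[ord],
                    dof = vapply(scores, `[[`, numeric(1), "dof")[ord],
                    stringsAsFactors = FALSE)
  tab$delta_chisq <- tab$chisq - tab$chisq[1]
  best_red <- tab$chisq[1] / max(tab$dof[1], 1)
  tie <- nrow(tab) > 1L && abs(tab$chisq[2] - tab$chisq[1]) < 1e-9
  structure(list(table = tab, scores = scores, best = tab$form[1],
                 tie = tie,
                 quantitative_agreement = best_red <= quantitative_threshold),
            class = "form_ranking")
}

#' @export
print.form_ranking <- function(x, ...) {
  cat("Candidate dimer forms ranked by chi-square:\n")
  print(x$table, row.names = FALSE)
  if (x$tie) cat("NOTE: top candidates are tied.\n")
  if (!x$quantitative_agreement) {
    cat("Best form is favoured but shows no quantitative agreement",
        "(reduced chi-square above threshold).\n")
  }
  invisible(x)
}

#' Bootstrap uncertainty of a mean distance (or efficiency)
#'
#' Resamples the series with replacement `n_resamples` times, takes the mean
#' of each resample, and returns the standard deviation of the resampled
#' means. For efficiency series the conversion to distance can be applied
#' either to each value before averaging, or to the resampled means
#' afterwards (both orders are in use depending on how a pair's series was
#' assembled).
#'
#' @param series Numeric vector (length >= 2): distances, or efficiencies
#'   when `convert` is given.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Optional seed for reproducibility.
#' @param convert Optional conversion function (e.g.
#'   `function(E) efficiency_to_distance(E, 6.34)`).
#' @param convert_when `"before_mean"` (convert each value, then average) or
#'   `"after_mean"` (average efficiencies, convert the resampled means).
#' @return Standard deviation of the resampled means.
#' @export
bootstrap_distance_ci <- function(series, n_resamples = 1000L, seed = NULL,
                                  convert = NULL,
                                  convert_when = c("before_mean",
                                                   "after_mean")) {
  convert_when <- match.arg(convert_when)
  if (length(series) < 2L) stop("series must have length >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(convert) && convert_when == "before_mean") {
    series <- convert(series)
  }
  means <- vapply(seq_len(n_resamples), function(i) {
    mean(sample(series, replace = TRUE))
  }, numeric(1))
  if (!is.null(convert) && convert_when == "after_mean") {
    means <- convert(means)
  }
  sd(means)
}
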
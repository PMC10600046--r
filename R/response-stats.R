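#' Participant filtering by catch trials and accuracy outliers
#'
#' Two-stage exclusion mirroring standard crowdsourced-psychophysics
#' practice.  Stage one drops observers whose accuracy on catch trials
#' (easy, untransformed items flagged `is_catch`) falls below `catch_min`;
#' observers with no catch trials pass this stage.  Stage two computes
#' each remaining observer's overall accuracy on non-catch trials and
#' drops those deviating from the cohort median by more than
#' `mad_c` x MAD, where the MAD carries the usual 1.4826 consistency
#' constant ([stats::mad()]).  When the MAD is zero only observers with a
#' non-zero deviation are dropped, so a cohort of identical observers is
#' never excluded.
#'
#' @param trials a trial table: one row per response with columns
#'   `observer_id`, `observer_type`, `condition_id`, `true_class`,
#'   `predicted_class`, `confidence`, `is_catch` (see [simulate_trials()]
#'   for the full schema).
#' @param catch_min minimum catch-trial accuracy (default 2/3).
#' @param mad_c MAD multiplier (default 3).
#' @return a list with `trials` (rows of retained observers) and
#'   `exclusions` (tibble `observer_id`, `reason` in `{"catch", "mad"}`,
#'   `value` = the offending accuracy).
#' @export
filter_participants <- function(trials, catch_min = 2 / 3, mad_c = 3) {
  if (nrow(trials) == 0L) stop("trial table is empty", call. = FALSE)
  excl <- tibble::tibble(observer_id = character(), reason = character(),
                         value = numeric())

  catch <- trials[trials$is_catch, ]
  if (nrow(catch) > 0L) {
    cacc <- tapply(catch$predicted_class == catch$true_class,
                   catch$observer_id, mean)
    bad <- names(cacc)[cacc < catch_min]
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      observer_id = bad, reason = "catch", value = as.numeric(cacc[bad])))
    trials <- trials[!(trials$observer_id %in% bad), ]
  }

  main <- trials[!trials$is_catch, ]
  if (nrow(main) > 0L) {
    acc <- tapply(main$predicted_class == main$true_class,
                  main$observer_id, mean)
    med <- stats::median(acc)
    madv <- stats::mad(acc)          # constant = 1.4826
    dev <- abs(acc - med)
    bad <- names(acc)[dev > mad_c * madv]
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      observer_id = bad, reason = "mad", value = as.numeric(acc[bad])))
    trials <- trials[!(trials$observer_id %in% bad), ]
  }

  if (nrow(trials) == 0L)
    stop("all observers were excluded by the filters", call. = FALSE)
  list(trials = trials, exclusions = excl)
}

#' Per-condition accuracy and confidence summaries
#'
#' Aggregates a trial table to one row per (observer type, condition):
#' fraction correct, mean confidence and trial count.  Catch trials are
#' excluded from the summaries.  The transform family is recovered from
#' the condition id ([parse_condition_id()]).
#'
#' @inheritParams filter_participants
#' @return a tibble with columns `observer_type`, `condition_id`,
#'   `family`, `n_trials`, `accuracy`, `mean_confidence`.
#' @export
condition_accuracy <- function(trials) {
  main <- trials[!trials$is_catch, , drop = FALSE]
  key <- interaction(main$observer_type, main$condition_id, drop = TRUE,
                     sep = "\r")
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  keys <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- tibble::tibble(
    observer_type = keys[, 1], condition_id = keys[, 2],
    n_trials = as.integer(agg(rep(1L, nrow(main)), sum)),
    accuracy = agg(main$predicted_class == main$true_class, mean),
    mean_confidence = agg(main$confidence, mean))
  out$family <- parse_condition_id(out$condition_id)$family
  out[, c("observer_type", "condition_id", "family", "n_trials",
          "accuracy", "mean_confidence")]
}

#' Transform difficulty ranking
#'
#' Averages condition-level accuracy within each transform family (each
#' parameter setting weighted equally, as when ranking families by mean
#' observer performance) and sorts the families by decreasing mean
#' accuracy.  Exact ties are broken alphabetically and flagged in the
#' `tied` column.
#'
#' @param summaries output of [condition_accuracy()] (optionally filtered
#'   to one observer type first).
#' @return a tibble `family`, `mean_accuracy`, `n_conditions`, `rank`,
#'   `tied`, ordered best to worst.
#' @export
transform_ranking <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no summaries to rank", call. = FALSE)
  fam <- factor(summaries$family)
  out <- tibble::tibble(
    family = levels(fam),
    mean_accuracy = as.numeric(tapply(summaries$accuracy, fam, mean)),
    n_conditions = as.integer(tabulate(fam)))
  out <- out[order(-out$mean_accuracy, out$family, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$mean_accuracy) |
    duplicated(out$mean_accuracy, fromLast = TRUE)
  out
}

# Normalize paired inputs: numeric vectors (matched by name when both are
# named) or data frames carrying condition_id + accuracy.
paired_vectors <- function(a, b) {
  take <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$accuracy, x$condition_id) else x
  }
  a <- take(a); b <- take(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) < length(a) || length(common) < length(b))
      stop("conditions do not pair up: ",
           length(common), " shared of ", length(a), " and ", length(b),
           call. = FALSE)
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b))
    stop("paired inputs differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Paired comparison of matched per-condition accuracies
#'
#' Classical paired t test on the condition-wise differences: t equals the
#' mean difference over its standard error, with n - 1 degrees of freedom
#' by default.  The study this grid reproduces reported the statistic at 3
#' degrees of freedom (the number of independent variables in the
#' transform space); that convention is available through the `df`
#' override.  Identical inputs give t = 0; a non-zero mean difference with
#' zero variance is reported as an error rather than an infinite
#' statistic.
#'
#' @param a,b matched per-condition accuracies: numeric vectors (matched
#'   by name when named) or data frames with `condition_id` and
#'   `accuracy`.
#' @param df optional degrees-of-freedom override for the p value.
#' @return a one-row tibble `method`, `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference a - b), `n`.
#' @export
paired_comparison <- function(a, b, df = NULL) {
  v <- paired_vectors(a, b)
  d <- v$a - v$b
  n <- length(d)
  if (n < 2L) stop("need at least 2 matched pairs", call. = FALSE)
  if (all(d == 0))
    return(tibble::tibble(method = "paired_t", statistic = 0,
                          df = if (is.null(df)) n - 1 else df, p_value = 1,
                          estimate = 0, n = n))
  s <- stats::sd(d)
  if (s == 0)
    stop("differences have zero variance but non-zero mean; ",
         "t statistic is degenerate", call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  dfree <- if (is.null(df)) n - 1 else df
  tibble::tibble(method = "paired_t", statistic = t, df = dfree,
                 p_value = 2 * stats::pt(-abs(t), dfree),
                 estimate = mean(d), n = n)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor.test()] returning the tidy one-row form
#' used throughout this package, with explicit errors for degenerate
#' input (fewer than 3 pairs, or zero variance on either side).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a one-row tibble `method`, `statistic` (t), `df`, `p_value`,
#'   `estimate` (r), `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(method = "pearson", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 estimate = unname(ct$estimate), n = length(x))
}

#' Ordinary least squares between matched responses
#'
#' Simple linear regression `response ~ predictor` via [stats::lm()],
#' reporting slope, intercept, R^2 and the two-sided slope p value.  In
#' simple regression R^2 equals the squared Pearson correlation.
#'
#' @param response,predictor numeric vectors of equal length >= 3.
#' @return a one-row tibble `method`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
ols_fit <- function(response, predictor) {
  if (length(response) != length(predictor))
    stop("response and predictor differ in length", call. = FALSE)
  if (length(response) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(predictor) == 0)
    stop("singular fit: predictor is constant", call. = FALSE)
  fit <- stats::lm(response ~ predictor)
  sm <- summary(fit)
  tibble::tibble(method = "ols",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(response))
}

#' Confidence-accuracy correlation
#'
#' Pearson correlation between per-condition mean confidence and
#' per-condition accuracy for one observer type.  Human observers whose
#' confidence tracks how well they perform show r near 1; observers whose
#' confidence is unrelated to performance (as networks behave on these
#' transforms) show r near 0.
#'
#' @inheritParams filter_participants
#' @param observer_type `"human"` or `"network"` (any value present in
#'   the table).
#' @return as [pearson_r()].
#' @export
confidence_accuracy_correlation <- function(trials, observer_type) {
  cs <- condition_accuracy(trials)
  cs <- cs[cs$observer_type == observer_type, ]
  if (nrow(cs) < 3L)
    stop("need at least 3 conditions for observer type ", observer_type,
         call. = FALSE)
  pearson_r(cs$mean_confidence, cs$accuracy)
}

#' Read and write trial tables
#'
#' CSV with the canonical header `observer_id, observer_type,
#' condition_id, true_class, predicted_class, confidence, response_time,
#' is_catch`.
#'
#' @param path CSV path.
#' @param trials a trial tibble.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "observer_type", "condition_id", "true_class",
            "predicted_class", "confidence", "is_catch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$is_catch <- as.logical(d$is_catch)
  tibble::as_tibble(d)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
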
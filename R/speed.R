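#' Mean walking speed over the path
#'
#' @param path_length_m walked distance in metres (study walkway: 10 m).
#' @param duration_s time to cover it (s), must be > 0.
#' @return Speed in m/s.
#' @examples
#' mean_speed(10, 8)  # 1.25
#' @export
mean_speed <- function(path_length_m = 10, duration_s) {
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("duration_s must be positive and finite")
  path_length_m / duration_s
}

#' Fit the anthropometric walking-speed model
#'
#' Ordinary least squares of observed speed on body weight (kg) and height
#' (cm), with intercept. The fit scope is one regression per speed
#' condition (conditions differ systematically in speed, so pooling across
#' them would confound the normalization).
#'
#' @param data data frame with columns `observed_speed`, `weight_kg`,
#'   `height_cm` and (unless `scope = "pooled"`) `condition`.
#' @param scope `"condition"` (default) fits one model per condition;
#'   `"pooled"` fits a single model.
#' @return Object of class `speed_model`: a named list of `lm` fits plus
#'   the scope.
#' @export
fit_speed_model <- function(data, scope = c("condition", "pooled")) {
  scope <- match.arg(scope)
  need <- c("observed_speed", "weight_kg", "height_cm")
  if (!all(need %in% names(data)))
    stop("data must contain observed_speed, weight_kg, height_cm")
  fit_one <- function(d) {
    d <- d[stats::complete.cases(d[, need]), , drop = FALSE]
    if (nrow(d) < 3L) stop("need at least 3 complete rows to fit the speed model")
    X <- cbind(d$weight_kg, d$height_cm)
    if (qr(cbind(1, X))$rank < 3L)
      stop("collinear predictors: weight and height do not span the model")
    stats::lm(observed_speed ~ weight_kg + height_cm, data = d)
  }
  models <- if (scope == "pooled") {
    list(pooled = fit_one(data))
  } else {
    if (!"condition" %in% names(data)) stop("per-condition scope needs a condition column")
    sapply(unique(data$condition), function(cond)
      fit_one(data[data$condition == cond, , drop = FALSE]),
      simplify = FALSE)
  }
  structure(list(models = models, scope = scope), class = "speed_model")
}

#' @export
print.speed_model <- function(x, ...) {
  cat(sprintf("<speed_model> OLS speed ~ weight_kg + height_cm, scope: %s\n", x$scope))
  for (nm in names(x$models)) {
    cf <- stats::coef(x$models[[nm]])
    r2 <- summary(x$models[[nm]])$r.squared
    cat(sprintf("  %-12s intercept %8.4f  weight %9.5f  height %9.5f  r^2 %.3f\n",
                nm, cf[1L], cf[2L], cf[3L], r2))
  }
  invisible(x)
}

#' @export
coef.speed_model <- function(object, ...) {
  t(vapply(object$models, stats::coef, numeric(3L)))
}

#' @export
predict.speed_model <- function(object, newdata, ...) {
  if (object$scope == "pooled")
    return(stats::predict(object$models$pooled, newdata = newdata))
  if (!"condition" %in% names(newdata))
    stop("newdata needs a condition column for per-condition predictions")
  out <- rep(NA_real_, nrow(newdata))
  for (cond in unique(newdata$condition)) {
    m <- object$models[[cond]]
    if (is.null(m)) stop("no fitted model for condition: ", cond)
    sel <- newdata$condition == cond
    out[sel] <- stats::predict(m, newdata = newdata[sel, , drop = FALSE])
  }
  out
}

#' Normalize individual speed by its anthropometric prediction
#'
#' Each observed speed is divided by the speed predicted from the
#' participant's weight and height under the fitted regression, yielding a
#' dimensionless ratio whose within-scope mean is close to 1. Rows with a
#' non-positive prediction are flagged and get `NA` (with a logged
#' message) rather than being silently dropped.
#'
#' @param data data frame with `observed_speed`, `weight_kg`, `height_cm`
#'   (and `condition` for per-condition models).
#' @param model a [fit_speed_model()] result.
#' @return `data` with added columns `predicted_speed` and
#'   `normalized_speed`.
#' @export
normalize_speed <- function(data, model) {
  if (!inherits(model, "speed_model")) stop("model must be a speed_model")
  pred <- predict(model, newdata = data)
  bad <- which(is.finite(pred) & pred <= 0)
  if (length(bad)) {
    message(sprintf("normalize_speed: %d record(s) with non-positive predicted speed flagged and excluded",
                    length(bad)))
    pred[bad] <- NA_real_
  }
  data$predicted_speed <- pred
  data$normalized_speed <- data$observed_speed / pred
  data
}
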
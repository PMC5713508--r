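#' Treatment-stratified calibration/validation split
#'
#' For every treatment one repetition is chosen at random (seeded) and all
#' of its observations — across every flight — go to validation; the
#' remaining observations form the calibration set.  With four treatments
#' of four repetitions this realizes a 25% validation fraction (the
#' "one repetition per treatment" rule, applied as stated, yields 1/4
#' rather than exactly 20%); the realized fraction is reported.
#'
#' @param table feature table with `treatment`, `repetition` and `row_id`
#'   columns (a `row_id` is added if absent).
#' @param seed integer seed.
#' @return An object of class `split_plan`: `calibration_rows`,
#'   `validation_rows` (integer row indices into `table`),
#'   `validation_reps` (data frame treatment/repetition),
#'   `validation_fraction`, `seed`.
#' @export
split_calibration_validation <- function(table, seed = 1L) {
  stopifnot(all(c("treatment", "repetition") %in% names(table)))
  set.seed(as.integer(seed) %% 2147483647)
  treatments <- sort(unique(table$treatment))
  val_rows <- integer(0)
  chosen <- list()
  for (tr in treatments) {
    reps <- sort(unique(table$repetition[table$treatment == tr]))
    if (length(reps) < 2)
      stop("treatment ", tr, " has a single repetition; cannot hold one out")
    pick <- reps[sample.int(length(reps), 1L)]
    chosen[[tr]] <- data.frame(treatment = tr, repetition = pick,
                               stringsAsFactors = FALSE)
    val_rows <- c(val_rows,
                  which(table$treatment == tr & table$repetition == pick))
  }
  val_rows <- sort(val_rows)
  cal_rows <- setdiff(seq_len(nrow(table)), val_rows)
  structure(list(calibration_rows = cal_rows,
                 validation_rows = val_rows,
                 validation_reps = do.call(rbind, chosen),
                 validation_fraction = length(val_rows) / nrow(table),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %d calibration / %d validation rows (%.1f%% validation)\n",
    length(x$calibration_rows), length(x$validation_rows),
    100 * x$validation_fraction))
  invisible(x)
}

#' Linear index baseline
#'
#' Ordinary least squares of psi on a single spectral-index value:
#' `psi = a + b * index`, with the two-sided t-test p-value for the slope.
#'
#' @param table feature table with a `psi_mpa` column.
#' @param index_values numeric vector, one index value per row of `table`.
#' @return List of class `index_baseline`: `a` (intercept), `b` (slope),
#'   `r_squared`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
linear_baseline <- function(table, index_values) {
  y <- table$psi_mpa
  x <- index_values
  if (length(x) != length(y)) stop("index_values length mismatch")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 observations")
  if (stats::sd(x[ok]) == 0) stop("index has zero variance")
  fit <- stats::lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  sm <- summary(fit)
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = sum(ok), fit = fit),
            class = "index_baseline")
}

#' @export
print.index_baseline <- function(x, ...) {
  cat(sprintf(
    "<index_baseline> psi = %.4g + %.4g * index  (R2 %.3f, slope p %.3g, n %d)\n",
    x$a, x$b, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Validation statistics for observed vs predicted psi
#'
#' Computes the agreement statistics used to judge a water-status model:
#' \describe{
#'   \item{MAE}{`mean(|P - O|)`, MPa.}
#'   \item{RMSE}{`sqrt(mean((P - O)^2))`, MPa.}
#'   \item{RE}{`100 * mean((P - O) / O)`, percent.  With negative psi, a
#'     model that overestimates (predicts less negative than observed)
#'     yields a negative RE.}
#'   \item{d}{modified (absolute-value) index of agreement,
#'     `1 - sum(|O - P|) / sum(|P - mean(O)| + |O - mean(O)|)`, in
#'     \[0, 1\], 1 = perfect.}
#'   \item{R2}{squared Pearson correlation of observed and predicted (the
#'     observed-vs-predicted regression line); `NA` if either side has
#'     zero variance.}
#' }
#'
#' @param observed,predicted equal-length numeric vectors (>= 2); observed
#'   values must be nonzero (RE is undefined at 0).
#' @param model_id identifier recorded in the report.
#' @return An object of class `eval_report`: `n`, `r_squared`, `mae`,
#'   `rmse`, `re_pct`, `d`, `model_id`.
#' @export
#' @examples
#' evaluate(c(-1.0, -1.2), c(-0.9, -1.1))  # MAE = RMSE = 0.1, RE = -9.17%
evaluate <- function(observed, predicted, model_id = "model") {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2) stop("need at least 2 observations")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values in input")
  if (any(observed == 0)) stop("observed value of exactly 0: RE undefined")
  err <- predicted - observed
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  re <- 100 * mean(err / observed)
  obar <- mean(observed)
  denom <- sum(abs(predicted - obar) + abs(observed - obar))
  d <- if (denom == 0) {
    if (all(err == 0)) 1 else 0
  } else 1 - sum(abs(err)) / denom
  r2 <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    NA_real_ else stats::cor(observed, predicted)^2
  structure(list(n = length(observed), r_squared = r2, mae = mae,
                 rmse = rmse, re_pct = re, d = d, model_id = model_id),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s (n = %d): R2 %s, MAE %.4f MPa, RMSE %.4f MPa, RE %.2f%%, d %.3f\n",
    x$model_id, x$n,
    if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
    x$mae, x$rmse, x$re_pct, x$d))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(model_id = x$model_id, n = x$n, r_squared = x$r_squared,
             mae = x$mae, rmse = x$rmse, re_pct = x$re_pct, d = x$d,
             stringsAsFactors = FALSE)
}
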
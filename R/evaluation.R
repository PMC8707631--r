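#' Root-mean-square error between estimated and actual force
#'
#' \eqn{\sqrt{\frac1N \sum (F_E - F_A)^2}} in newtons.
#'
#' @param est Estimated series.
#' @param act Actual series, same length.
#' @return Scalar RMSE.
#' @export
rmse <- function(est, act) {
  if (length(est) != length(act)) stop("series lengths differ")
  if (length(est) < 1) stop("empty series")
  sqrt(mean((est - act)^2))
}

#' Squared sample correlation between estimated and actual force
#'
#' The squared Pearson correlation coefficient, the estimation-accuracy
#' metric; reported either as a fraction in `[0, 1]` or as a percentage
#' (`100 * r2`).
#'
#' @inheritParams rmse
#' @return Scalar in `[0, 1]`.
#' @export
r_squared <- function(est, act) {
  if (length(est) != length(act)) stop("series lengths differ")
  if (length(est) < 2) stop("need at least 2 samples")
  if (stats::sd(est) == 0 || stats::sd(act) == 0)
    stop("zero-variance series: correlation undefined")
  stats::cor(est, act)^2
}

#' Per-trial metrics and aggregates
#'
#' Computes RMSE and squared correlation per trial and their mean/min/max
#' across trials -- the across-trial summary of estimation performance.
#'
#' @param trials List of trials, each a list with elements `est` and `act`
#'   (and optionally `id`).
#' @return List with `per_trial` (data.frame: trial, n, rmse, r2) and
#'   `summary` (mean/min/max of both metrics).
#' @export
summarize_trials <- function(trials) {
  stopifnot(length(trials) >= 1)
  per <- do.call(rbind, lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    data.frame(trial = tr$id %||% k, n = length(tr$est),
               rmse = rmse(tr$est, tr$act),
               r2 = r_squared(tr$est, tr$act))
  }))
  list(per_trial = per,
       summary = list(
         rmse = list(mean = mean(per$rmse), min = min(per$rmse),
                     max = max(per$rmse)),
         r2 = list(mean = mean(per$r2), min = min(per$r2),
                   max = max(per$r2))))
}

#' Bilateral mean absolute error
#'
#' Mean of `|F_health - F_affected|`, the average bilateral force error used
#' to compare training conditions.
#'
#' @param f_health,f_affected Force series, N, equal length.
#' @return Scalar MAE, N.
#' @export
bilateral_mae <- function(f_health, f_affected) {
  if (length(f_health) != length(f_affected)) stop("series lengths differ")
  if (length(f_health) < 1) stop("empty series")
  mean(abs(f_health - f_affected))
}
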
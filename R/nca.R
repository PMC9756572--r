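#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax, AUC to the last quantifiable sample (linear-up/log-down
#' trapezoidal rule) and AUC extrapolated to infinity
#' (`AUC_inf = AUC_last + C_last / lambda_z`), with the terminal slope
#' `lambda_z` estimated by log-linear regression over the last
#' `n_lambda_z` quantifiable points.
#'
#' @param time Sampling times (h), sorted.
#' @param conc Concentrations (any consistent unit).
#' @param t_last Optional truncation time; samples after it are ignored.
#' @param n_lambda_z Number of terminal points for the lambda-z regression.
#' @return An object of class `pk_metrics`: list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, and `auc_inf_missing` (TRUE when no
#'   valid terminal slope could be estimated, in which case `auc_inf` is
#'   `NA`).
#' @export
#' @examples
#' t <- seq(0, 24, 0.1)
#' m <- nca(t, 10 * exp(-0.2 * t))
#' c(m$auc_inf, 10 / 0.2) # within 1%
nca <- function(time, conc, t_last = NULL, n_lambda_z = 4) {
  stopifnot(length(time) == length(conc), !is.unsorted(time))
  if (!is.null(t_last)) {
    keep <- time <= t_last + 1e-12
    time <- time[keep]
    conc <- conc[keep]
  }
  if (all(conc <= 0)) stop("profile contains no positive concentrations")
  cmax <- max(conc)
  tmax <- time[which.max(conc)]
  # linear-up/log-down trapezoid
  auc <- 0
  for (i in seq_len(length(time) - 1L)) {
    dt <- time[i + 1L] - time[i]
    c1 <- conc[i]
    c2 <- conc[i + 1L]
    auc <- auc + if (c2 < c1 && c2 > 0) {
      (c1 - c2) / log(c1 / c2) * dt
    } else {
      (c1 + c2) / 2 * dt
    }
  }
  # terminal slope over the last n quantifiable points
  pos <- which(conc > 0)
  lambda_z <- NA_real_
  auc_inf <- NA_real_
  missing <- TRUE
  if (length(pos) >= n_lambda_z) {
    idx <- utils::tail(pos, n_lambda_z)
    fit <- lm(log(conc[idx]) ~ time[idx])
    slope <- unname(coef(fit)[2L])
    if (is.finite(slope) && slope < 0) {
      lambda_z <- -slope
      c_last <- conc[utils::tail(pos, 1L)]
      auc_inf <- auc + c_last / lambda_z
      missing <- FALSE
    }
  }
  structure(
    list(
      cmax = cmax, tmax = tmax, auc_last = auc, auc_inf = auc_inf,
      lambda_z = lambda_z, auc_inf_missing = missing
    ),
    class = "pk_metrics"
  )
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(
    "<pk_metrics> Cmax %.4g (t = %.3g h) | AUC_last %.4g | AUC_inf %s | lambda_z %s\n",
    x$cmax, x$tmax, x$auc_last,
    if (x$auc_inf_missing) "NA" else sprintf("%.4g", x$auc_inf),
    if (is.na(x$lambda_z)) "NA" else sprintf("%.4g /h", x$lambda_z)
  ))
  invisible(x)
}
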
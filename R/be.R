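#' Bioequivalence assessment on log-transformed PK metrics
#'
#' Parallel-design comparison: each metric is log-transformed, arm means are
#' compared with an unpooled-variance (Welch) two-sample interval, and the
#' 90% confidence interval is exponentiated back to the geometric-mean-ratio
#' scale. A metric passes when its CI lies entirely within the acceptance
#' limits (default 80-125%). When both arms have zero variance (e.g. a
#' shared-population reference-vs-reference run) the CI degenerates to the
#' point GMR.
#'
#' @param test,ref Data frames of per-subject metrics with columns `matrix`
#'   (e.g. `"plasma"`, `"dermis"`) and one column per metric.
#' @param metrics Metric columns to assess.
#' @param limits Acceptance limits in percent.
#' @param conf_level Confidence level of the two-sided interval.
#' @return A data frame of class `be_result`: one row per matrix x metric
#'   with `gmr_pct`, `ci90_lower`, `ci90_upper`, `pass`, `n_test`, `n_ref`.
#' @export
#' @examples
#' m <- data.frame(matrix = "plasma", cmax = exp(rnorm(12)))
#' be_assessment(m, m)$gmr_pct # exactly 100
be_assessment <- function(test, ref,
                          metrics = c("cmax", "auc_last", "auc_inf"),
                          limits = c(80, 125), conf_level = 0.90) {
  stopifnot(all(metrics %in% names(test)), all(metrics %in% names(ref)))
  matrices <- intersect(unique(test$matrix), unique(ref$matrix))
  rows <- list()
  for (mx in matrices) {
    for (met in metrics) {
      xt <- test[[met]][test$matrix == mx]
      xr <- ref[[met]][ref$matrix == mx]
      dropn <- sum(!is.finite(xt) | xt <= 0) + sum(!is.finite(xr) | xr <= 0)
      if (dropn > 0) {
        warning(sprintf(
          "%s/%s: %d non-positive or missing values excluded", mx, met, dropn
        ), call. = FALSE)
      }
      xt <- xt[is.finite(xt) & xt > 0]
      xr <- xr[is.finite(xr) & xr > 0]
      if (length(xt) < 2 || length(xr) < 2) {
        stop("need at least 2 usable subjects per arm for ", mx, "/", met)
      }
      lt <- log(xt)
      lr <- log(xr)
      d <- mean(lt) - mean(lr)
      v <- var(lt) / length(lt) + var(lr) / length(lr)
      if (v > 0) {
        df <- v^2 / ((var(lt) / length(lt))^2 / (length(lt) - 1) +
          (var(lr) / length(lr))^2 / (length(lr) - 1))
        half <- qt(1 - (1 - conf_level) / 2, df) * sqrt(v)
      } else {
        half <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        matrix = mx, metric = met,
        gmr_pct = 100 * exp(d),
        ci90_lower = 100 * exp(d - half),
        ci90_upper = 100 * exp(d + half),
        pass = 100 * exp(d - half) >= limits[1] &&
          100 * exp(d + half) <= limits[2],
        n_test = length(xt), n_ref = length(xr),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("be_result", class(out))
  out
}

#' @export
print.be_result <- function(x, ...) {
  cat("<be_result> 90% CI vs 80-125% limits\n")
  df <- as.data.frame(x)
  for (cc in intersect(c("gmr_pct", "ci90_lower", "ci90_upper"), names(df))) {
    df[[cc]] <- round(df[[cc]], 2)
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats var
NULL
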
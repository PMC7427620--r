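#' Analytic maximum-statistic threshold (i.i.d. null)
#'
#' Family-wise-error-controlling two-sided |z| cutoff under the i.i.d.
#' standard-normal null: the value `t` solving
#' `P(max of m i.i.d. |N(0,1)| <= t) = 1 - alpha`, i.e.
#' `t = qnorm((1 + (1 - alpha)^(1/m)) / 2)`.  Increasing in `m`, decreasing
#' in `alpha`; conservative (an upper bound on the needed cutoff) when the
#' field is positively dependent.
#'
#' @param m number of comparisons (e.g. channels x bins).
#' @param alpha nominal family-wise error level in (0, 1).
#' @return An object of class `maxstat_threshold` with fields `value`,
#'   `alpha`, `m`, `method = "analytic_iid"`.
#' @export
max_stat_threshold_iid <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  v <- stats::qnorm((1 + (1 - alpha)^(1 / m)) / 2)
  structure(list(value = v, alpha = alpha, m = as.integer(m),
                 method = "analytic_iid"),
            class = "maxstat_threshold")
}

#' Empirical maximum-statistic threshold from null z-fields
#'
#' The corrected cutoff is the inclusive (type-7) `1 - alpha` quantile of
#' the per-field maximum |z| over a collection of null fields — typically
#' the standardized residual fields retained by [fit_norm_model()].  Under
#' positive dependence within fields this lies below the analytic i.i.d.
#' cutoff (the empirical route is less conservative).
#'
#' @param null_zfields numeric array `[field x location x bin]` (or a matrix
#'   `[field x m]`, or a list of z matrices) of null z-values; at least 20
#'   fields.
#' @param alpha nominal family-wise error level.
#' @return A `maxstat_threshold` with `method = "empirical"`.
#' @export
max_stat_threshold_empirical <- function(null_zfields, alpha = 0.05) {
  if (is.list(null_zfields))
    null_zfields <- do.call(rbind, lapply(null_zfields, as.vector))
  if (is.array(null_zfields) && length(dim(null_zfields)) == 3L) {
    d <- dim(null_zfields)
    null_zfields <- matrix(null_zfields, d[1], d[2] * d[3])
  }
  null_zfields <- as.matrix(null_zfields)
  if (nrow(null_zfields) < 20L)
    stop("at least 20 null fields are required (got ", nrow(null_zfields), ")",
         call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  mx <- apply(abs(null_zfields), 1L, max)
  v <- as.numeric(stats::quantile(mx, probs = 1 - alpha, type = 7, names = FALSE))
  structure(list(value = v, alpha = alpha, m = ncol(null_zfields),
                 method = "empirical", n_fields = nrow(null_zfields)),
            class = "maxstat_threshold")
}

#' @export
print.maxstat_threshold <- function(x, ...) {
  cat(sprintf("<maxstat_threshold> |z| >= %.4f (alpha %.3g, m = %d, %s)\n",
              x$value, x$alpha, x$m, x$method))
  invisible(x)
}

#' Apply a corrected threshold to z-maps
#'
#' Marks entries with `|z| >= threshold` as suprathreshold (two-sided:
#' excess and deficit are both clinically meaningful) and records the
#' threshold in the map object.
#'
#' @param zm a [z_maps] object.
#' @param thr a `maxstat_threshold`.
#' @return The `z_maps` with `$mask` (logical matrix) and `$threshold` set.
#' @export
apply_threshold <- function(zm, thr) {
  stopifnot(inherits(zm, "z_maps"), inherits(thr, "maxstat_threshold"))
  if (!all(is.finite(zm$z))) stop("z-maps contain non-finite values", call. = FALSE)
  zm$mask <- abs(zm$z) >= thr$value
  zm$threshold <- thr
  zm
}
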
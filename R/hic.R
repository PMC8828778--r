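#' Load a loci-pair Hi-C signal table
#'
#' Reads a small curated CSV of per-loci-pair normalized contact frequencies
#' (one row per engineered pair, signal = 10-kb bin-pair contact frequency
#' from published matrices). Replica columns are any columns matching
#' `signal`/`hic`/`rep`; `hic_signal` is their row mean.
#'
#' @param path CSV path with columns `pair_id`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b` and one or more numeric replica signal columns.
#' @return Data frame with the input columns plus `hic_signal`.
#' @export
load_pair_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pair_id", "chrom_a", "pos_a", "chrom_b", "pos_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("pair table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sig_cols <- grep("^(signal|hic|rep)", names(df), value = TRUE)
  sig_cols <- setdiff(sig_cols, "hic_signal")
  if (!length(sig_cols)) stop("no replica signal columns found", call. = FALSE)
  for (cc in c("pos_a", "pos_b", sig_cols)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", cc, bad[1]),
           call. = FALSE)
    }
    df[[cc]] <- as.numeric(df[[cc]])
  }
  bad <- which(df$pos_a <= 0 | df$pos_b <= 0)
  if (length(bad)) stop(sprintf("non-positive position at row %d", bad[1]), call. = FALSE)
  df$hic_signal <- rowMeans(df[, sig_cols, drop = FALSE])
  if (any(df$hic_signal < 0)) stop("negative Hi-C signal", call. = FALSE)
  df
}

#' Summarize a loci pair's contact metrics
#'
#' Derives the four per-pair quantities regressed against Hi-C signal:
#' initial mean inter-dot distance (from t = 0 measurements), initial
#' co-localization probability `P(0) = a1`, efficiency from the fitted
#' plateau, and half-time `ln2 / k1`.
#'
#' @param fit A `cici_convfit` from [fit_timecourse].
#' @param initial_distances Inter-dot distances (um) measured at t = 0;
#'   their mean is reported.
#' @param pair_id Pair label.
#' @return One-row data frame: `pair_id`, `initial_distance`,
#'   `initial_coloc`, `efficiency`, `half_time`.
#' @export
summarize_pair <- function(fit, initial_distances, pair_id = NA) {
  stopifnot(inherits(fit, "cici_convfit"))
  d0 <- initial_distances[is.finite(initial_distances)]
  if (!length(d0)) stop("no t = 0 distance measurements supplied", call. = FALSE)
  data.frame(pair_id = pair_id,
             initial_distance = mean(d0),
             initial_coloc = fit$p_initial,
             efficiency = fit$efficiency,
             half_time = fit$half_time)
}

#' Coefficient of determination of a simple linear regression
#'
#' Ordinary least squares of `y` on `x`; `R^2 = 1 - SS_res / SS_tot`.
#' An optional log10 transform of `x` is available (contact frequencies span
#' orders of magnitude).
#'
#' @param x,y Numeric vectors (>= 3 points; `x` not constant).
#' @param log_x Regress on `log10(x)` instead of `x`.
#' @return Scalar R-squared.
#' @examples
#' regress_r2(1:6, 2 * (1:6) + 1)  # 1
#' @export
regress_r2 <- function(x, y, log_x = FALSE) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (log_x) x <- log10(x)
  if (stats::sd(x) == 0) stop("`x` is constant: regression undefined", call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("`y` is constant: R^2 set to 0 by convention")
    return(0)
  }
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
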
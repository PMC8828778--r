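#' HMR donor-usage fraction from gel band intensities
#'
#' In the mating-type switching readout, the undigested band reports HML
#' usage (MATalpha product) and the two digested bands report HMR usage
#' (MATalpha-B product, cut by BamHI). The HMR usage fraction is the summed
#' intensity of the two digested bands over the total of all three.
#'
#' @param undigested Intensity of the undigested (HML) band.
#' @param digested_upper,digested_lower Intensities of the two digested
#'   (HMR) bands.
#' @return Fraction in `[0, 1]`.
#' @examples
#' hmr_usage_fraction(3, 1, 0)  # 0.25
#' @export
hmr_usage_fraction <- function(undigested, digested_upper, digested_lower) {
  v <- c(undigested, digested_upper, digested_lower)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("band intensities must be finite and >= 0", call. = FALSE)
  }
  total <- undigested + digested_upper + digested_lower
  if (any(total <= 0)) stop("total band intensity must be > 0", call. = FALSE)
  (digested_upper + digested_lower) / total
}

#' Summarize HMR usage across conditions
#'
#' Per-condition mean and standard error of the mean of the band fraction
#' across biological replicates.
#'
#' @param bands Data frame with columns `condition`, `replicate`,
#'   `undigested`, `digested_upper`, `digested_lower`.
#' @return Data frame: `condition`, `mean_fraction`, `sem`, `n`. `sem` is 0
#'   with a warning for single-replicate conditions.
#' @export
summarize_conditions <- function(bands) {
  need <- c("condition", "replicate", "undigested", "digested_upper",
            "digested_lower")
  miss <- setdiff(need, names(bands))
  if (length(miss)) stop("bands table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  frac <- hmr_usage_fraction(bands$undigested, bands$digested_upper,
                             bands$digested_lower)
  rows <- lapply(unique(bands$condition), function(cond) {
    f <- frac[bands$condition == cond]
    n <- length(f)
    if (n == 1L) {
      warning(sprintf("condition '%s' has a single replicate: SEM set to 0", cond))
      sem <- 0
    } else {
      sem <- stats::sd(f) / sqrt(n)
    }
    data.frame(condition = cond, mean_fraction = mean(f), sem = sem, n = n)
  })
  do.call(rbind, rows)
}
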
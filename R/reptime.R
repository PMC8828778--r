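#' Relative DNA dose from a Ct difference
#'
#' Dose of a target region relative to a control region, assuming perfect
#' (2-fold per cycle) amplification: `2^(ct_control - ct_target)`.
#'
#' @param ct_target,ct_control Ct values, cycles.
#' @return Dimensionless relative dose.
#' @examples
#' relative_dose(19, 20)  # 2: one cycle earlier = twice the template
#' @export
relative_dose <- function(ct_target, ct_control) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_control))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^(ct_control - ct_target)
}

#' Relative copy-number curves from a qPCR Ct table
#'
#' Per replicate and locus, computes the dose relative to the control locus
#' at the same timepoint ([relative_dose]), then corrects primer bias by
#' normalizing to the t = 0 value, so `r(0) = 1` by construction. Replicates
#' are averaged afterwards; the per-time SE across replicates is reported.
#'
#' @param qpcr Data frame with columns `strain`, `replicate`, `locus`,
#'   `time_min`, `ct` (as from [simulate_qpcr]).
#' @param control_locus Name of the late-replicating control region.
#' @return Data frame: `strain`, `locus`, `time_min`, `r` (mean relative
#'   copy number), `se`, `n_replicates`. The control locus itself is not
#'   reported (its r is identically 1).
#' @export
qpcr_curves <- function(qpcr, control_locus) {
  need <- c("strain", "replicate", "locus", "time_min", "ct")
  miss <- setdiff(need, names(qpcr))
  if (length(miss)) stop("qPCR table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!control_locus %in% qpcr$locus) {
    stop(sprintf("control locus '%s' absent from table", control_locus), call. = FALSE)
  }
  per_rep <- list()
  for (st in unique(qpcr$strain)) {
    ds <- qpcr[qpcr$strain == st, ]
    for (rp in unique(ds$replicate)) {
      dr <- ds[ds$replicate == rp, ]
      ctrl <- dr[dr$locus == control_locus, ]
      for (loc in setdiff(unique(dr$locus), control_locus)) {
        dl <- dr[dr$locus == loc, ]
        dl <- dl[order(dl$time_min), ]
        ct_ctrl <- ctrl$ct[match(dl$time_min, ctrl$time_min)]
        if (any(is.na(ct_ctrl))) {
          stop(sprintf("control Ct missing for strain %s replicate %s at some time",
                       st, rp), call. = FALSE)
        }
        dose <- relative_dose(dl$ct, ct_ctrl)
        i0 <- which(dl$time_min == 0)
        if (!length(i0)) {
          stop(sprintf("missing t = 0 record for replicate %s, locus %s", rp, loc),
               call. = FALSE)
        }
        per_rep[[length(per_rep) + 1L]] <- data.frame(
          strain = st, replicate = rp, locus = loc,
          time_min = dl$time_min, r = dose / dose[i0[1]]
        )
      }
    }
  }
  pr <- do.call(rbind, per_rep)
  agg <- stats::aggregate(r ~ strain + locus + time_min, pr, mean)
  sds <- stats::aggregate(r ~ strain + locus + time_min, pr, stats::sd)
  ns <- stats::aggregate(r ~ strain + locus + time_min, pr, length)
  agg$se <- sds$r / sqrt(ns$r)
  agg$n_replicates <- ns$r
  agg[order(agg$strain, agg$locus, agg$time_min), ]
}

#' Mean relative copy number in a time window
#'
#' @param curve Data frame with `time_min` and `r` (one strain/locus).
#' @param t_lo,t_hi Inclusive window bounds, minutes (default 30-40 min
#'   after G1 release).
#' @return Mean `r` over in-window timepoints.
#' @export
window_mean <- function(curve, t_lo = 30, t_hi = 40) {
  keep <- curve$time_min >= t_lo & curve$time_min <= t_hi
  if (!any(keep)) stop("no timepoints inside the window", call. = FALSE)
  mean(curve$r[keep])
}

#' Anchor-based drift correction of copy-number curves
#'
#' Corrects systematic drift (e.g. uneven G1 release) in a strain's curves by
#' matching the difference between two unperturbed anchor loci to the
#' background strain. Per timepoint, every locus of the strain is scaled by
#' `s(t) = (r_Xbg(t) - r_Ybg(t)) / (r_X(t) - r_Y(t))` with anchors
#' `(X, Y)`; `s` is clipped to `[0.5, 2]` with a warning. With
#' `per_timepoint = FALSE` a single scale, the ratio of the time-averaged
#' anchor differences, is applied to the whole curve.
#'
#' @param strain_curves Curves (as from [qpcr_curves]) for the strain to
#'   correct.
#' @param background_curves Curves for the background strain, same loci and
#'   times.
#' @param anchor_pair Character vector `c(locus_early, locus_late)` of the
#'   unperturbed anchors.
#' @param per_timepoint Apply the scale per timepoint (default) or globally.
#' @return `strain_curves` with corrected `r` and an added `scale` column.
#' @export
drift_correct <- function(strain_curves, background_curves, anchor_pair,
                          per_timepoint = TRUE) {
  stopifnot(length(anchor_pair) == 2L)
  get_anchor <- function(curves, locus) {
    d <- curves[curves$locus == locus, ]
    if (!nrow(d)) stop(sprintf("anchor locus '%s' absent", locus), call. = FALSE)
    d[order(d$time_min), c("time_min", "r")]
  }
  ax <- get_anchor(strain_curves, anchor_pair[1])
  ay <- get_anchor(strain_curves, anchor_pair[2])
  bx <- get_anchor(background_curves, anchor_pair[1])
  by <- get_anchor(background_curves, anchor_pair[2])
  times <- ax$time_min
  if (!identical(times, ay$time_min) || !identical(times, bx$time_min) ||
      !identical(times, by$time_min)) {
    stop("anchor curves must share the same time grid", call. = FALSE)
  }
  diff_strain <- ax$r - ay$r
  diff_bg <- bx$r - by$r
  if (per_timepoint) {
    # where both anchor differences vanish (notably t = 0, where r = 1 by
    # construction) the ratio is 0/0: borrow the nearest defined scale; a
    # vanishing strain difference against a non-vanishing background one
    # leaves the scale undefined
    live <- abs(diff_bg) >= 1e-9
    if (any(live & abs(diff_strain) < 1e-9)) {
      stop("anchor difference ~ 0 in the strain: scale undefined", call. = FALSE)
    }
    if (!any(live)) {
      s <- rep(1, length(times))
    } else {
      s <- vapply(seq_along(times), function(i) {
        j <- which(live)[which.min(abs(times[live] - times[i]))]
        diff_bg[j] / diff_strain[j]
      }, 0)
      s[live] <- diff_bg[live] / diff_strain[live]
    }
  } else {
    if (abs(mean(diff_strain)) < 1e-9) {
      stop("anchor difference ~ 0 in the strain: scale undefined", call. = FALSE)
    }
    s <- rep(mean(diff_bg) / mean(diff_strain), length(times))
  }
  clipped <- s < 0.5 | s > 2
  if (any(clipped)) {
    warning(sprintf("%d drift scale(s) clipped to [0.5, 2]", sum(clipped)))
    s <- pmin(pmax(s, 0.5), 2)
  }
  out <- strain_curves
  out$scale <- s[match(out$time_min, times)]
  if (any(is.na(out$scale))) stop("strain curve times not covered by anchors", call. = FALSE)
  out$r <- out$r * out$scale
  out
}

#' Compare replication timing between strains
#'
#' Student's t-test on per-replicate window means (Welch's variant by
#' default; `pooled = TRUE` reproduces the classical equal-variance test).
#'
#' @param group_a,group_b Numeric vectors of replicate window means
#'   (>= 2 each).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param pooled Use the pooled-variance (classical Student) test.
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_timing <- function(group_a, group_b,
                           alternative = c("two.sided", "less", "greater"),
                           pooled = FALSE) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 replicates", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, alternative = alternative,
                      var.equal = pooled)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(group_a), mean_b = mean(group_b))
}
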
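## qPCR analysis: second-derivative-maximum Cq calling, standard-curve
## fitting, efficiency, absolute quantification, and titration-based
## determination of a minimal safe input volume.

#' Call the quantification cycle by the second-derivative maximum
#'
#' The quantification cycle is the sub-cycle position at which the
#' amplification curve's second derivative is maximal. Noisy
#' (non-monotone) curves are first smoothed with a Savitzky-Golay local
#' quadratic filter (window 5). The slope of the curve is estimated at
#' each interior cycle by fourth-order central differences, extended past
#' the recorded cycles by geometric tails (the amplification slope decays
#' roughly geometrically into baseline and plateau), and the second
#' derivative is reconstructed on a fine sub-cycle grid by Fourier
#' interpolation with exact compensation of the difference-kernel
#' response. On noise-free sigmoids this locates the analytic
#' second-derivative maximum to within about 0.01 cycles.
#'
#' Curves with a fluorescence range below `noise_floor` are flagged as
#' no-amplification; curves without a positive second-derivative peak
#' are flagged as invalid.
#'
#' @param fluorescence numeric fluorescence values, one per cycle
#'   (cycles assumed consecutive and unit-spaced).
#' @param cycles cycle indices (default `seq_along(fluorescence)`).
#' @param smooth apply Savitzky-Golay smoothing (default: only when the
#'   curve is non-monotone, i.e. visibly noisy).
#' @param noise_floor minimum fluorescence range for an amplifying curve.
#' @return list with `cp` (numeric, `NA` when flagged) and `flag`
#'   (`"ok"`, `"no_amplification"` or `"invalid"`).
#' @export
call_cp <- function(fluorescence, cycles = seq_along(fluorescence),
                    smooth = NULL, noise_floor = 0.1) {
  stopifnot(length(fluorescence) == length(cycles))
  n <- length(cycles)
  if (n < 10L) stop("need at least 10 cycles to call a Cq")
  rng <- diff(range(fluorescence))
  if (!is.finite(rng) || rng < noise_floor) {
    return(list(cp = NA_real_, flag = "no_amplification"))
  }
  y <- fluorescence
  if (is.null(smooth)) smooth <- is.unsorted(y, strictly = FALSE)
  if (isTRUE(smooth) && n >= 5L) {
    y <- signal::sgolayfilt(y, p = 2, n = 5)
  }
  # an amplification curve rises from baseline to plateau; curves that do
  # not gain fluorescence overall have no real second-derivative peak
  k <- min(5L, n)
  if (mean(y[(n - k + 1L):n]) - mean(y[1:k]) < noise_floor) {
    return(list(cp = NA_real_, flag = "invalid"))
  }
  i <- 3:(n - 2L)
  d1 <- (y[i - 2L] - 8 * y[i - 1L] + 8 * y[i + 1L] - y[i + 2L]) / 12
  m <- length(d1)
  # geometric extension of the slope into baseline/plateau avoids
  # truncation artefacts in the spectral reconstruction
  ext <- 40L
  right <- numeric(ext); left <- numeric(ext)
  if (d1[m] > 0 && d1[m - 1L] > 0 && d1[m] < d1[m - 1L]) {
    r <- d1[m] / d1[m - 1L]; right <- d1[m] * r^(1:ext)
  }
  if (d1[1L] > 0 && d1[2L] > 0 && d1[1L] < d1[2L]) {
    r <- d1[1L] / d1[2L]; left <- rev(d1[1L] * r^(1:ext))
  }
  dz <- c(left, d1, right)
  dz <- c(dz, rep(0, max(0L, 256L - length(dz))))
  M <- length(dz)
  w <- 2 * pi * (0:(M - 1L)) / M
  w <- ifelse(w > pi, w - 2 * pi, w)
  # divide out the difference-kernel response, multiply by i*w
  F1 <- (8 * sin(w) - sin(2 * w)) / 6
  corr <- ifelse(abs(F1) < 1e-9, 0, w / F1)
  D2 <- stats::fft(dz) * corr * 1i * w
  fine <- 200L
  MM <- M * fine
  half <- floor(M / 2)
  Dp <- complex(MM)
  Dp[1:(half + 1L)] <- D2[1:(half + 1L)]
  Dp[(MM - half + 2L):MM] <- D2[(M - half + 2L):M]
  d2fine <- Re(stats::fft(Dp, inverse = TRUE)) / M
  xf <- (cycles[i][1L] - ext) + (0:(MM - 1L)) / fine
  keep <- xf >= min(cycles) + 1 & xf <= max(cycles) - 1
  # a real amplification knee has curvature on the order of the
  # fluorescence range; near-zero "peaks" are numerical noise
  if (max(d2fine[keep]) <= 1e-3 * rng) {
    return(list(cp = NA_real_, flag = "invalid"))
  }
  list(cp = xf[keep][which.max(d2fine[keep])], flag = "ok")
}

#' Call Cq values for a set of amplification curves
#'
#' @param curves a `qpcr_curves` object from [simulate_qpcr()], or a
#'   matrix (cycles x reactions).
#' @param ... passed to [call_cp()].
#' @return data.frame with columns `reaction`, `true_copies` (if known),
#'   `cp`, `flag`.
#' @export
call_cp_set <- function(curves, ...) {
  if (inherits(curves, "qpcr_curves")) {
    fl <- curves$fluorescence
    cyc <- curves$cycles
    tc <- curves$true_copies
  } else {
    fl <- as.matrix(curves)
    cyc <- seq_len(nrow(fl))
    tc <- rep(NA_real_, ncol(fl))
  }
  res <- lapply(seq_len(ncol(fl)), function(j) call_cp(fl[, j], cyc, ...))
  data.frame(
    reaction = colnames(fl) %||% sprintf("rxn%d", seq_len(ncol(fl))),
    true_copies = tc,
    cp = vapply(res, `[[`, numeric(1L), "cp"),
    flag = vapply(res, `[[`, character(1L), "flag"),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq against log10 input copies over a
#' dilution series: `Cq = b + m * log10(copies)`. The amplification
#' efficiency is `E = 10^(-1/m) - 1`.
#'
#' @param copies known input copy numbers (> 0).
#' @param cp called quantification cycles (flagged/NA entries dropped).
#' @return a `qpcr_standard_curve`: list with `m` (slope), `b`
#'   (intercept), `efficiency`, `r_squared`, `n`.
#' @export
fit_standard_curve <- function(copies, cp) {
  keep <- is.finite(copies) & copies > 0 & is.finite(cp)
  copies <- copies[keep]; cp <- cp[keep]
  lg <- log10(copies)
  if (length(unique(lg)) < 3L) {
    stop("standard curve needs at least 3 distinct concentrations")
  }
  fit <- lm(cp ~ lg)
  m <- unname(coef(fit)[2L])
  b <- unname(coef(fit)[1L])
  if (!is.finite(m) || m == 0) stop("degenerate standard curve (zero slope)")
  ss_tot <- sum((cp - mean(cp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(
    list(m = m, b = b, efficiency = 10^(-1 / m) - 1,
         r_squared = r2, n = length(cp)),
    class = "qpcr_standard_curve"
  )
}

#' @export
print.qpcr_standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n",
              x$b, x$m))
  cat(sprintf("  efficiency %.1f%%, r^2 = %.5f, n = %d\n",
              x$efficiency * 100, x$r_squared, x$n))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the fitted regression: `copies = 10^((b - Cq) / (-m))`.
#'
#' @param cp quantification cycle(s); replicates of the same reaction
#'   should be averaged beforehand (see [quantify_replicates()]).
#' @param curve a [fit_standard_curve()] result.
#' @return estimated copy numbers (`NA` for flagged/NA Cq values).
#' @export
quantify_copies <- function(cp, curve) {
  stopifnot(inherits(curve, "qpcr_standard_curve"))
  if (curve$m >= 0) stop("invalid standard curve: slope must be negative")
  10^((curve$b - cp) / (-curve$m))
}

#' Average replicate Cq values, then quantify
#'
#' Reactions are typically run in duplicate; replicate Cq values are
#' averaged before conversion to copy numbers.
#'
#' @param cp numeric Cq values.
#' @param replicate_of grouping factor (one level per biological sample).
#' @param curve a [fit_standard_curve()] result.
#' @return named numeric copy estimates per group.
#' @export
quantify_replicates <- function(cp, replicate_of, curve) {
  means <- tapply(cp, replicate_of, mean, na.rm = TRUE)
  setNames(quantify_copies(as.numeric(means), curve), names(means))
}

#' Safe input volume from a titration series
#'
#' For each contaminant assay, fits `log10(cpm) = alpha + beta *
#' log10(V)` across the titration libraries (zero observations replaced
#' by a pseudo-cpm floor of half a read equivalent) and reports the
#' smallest volume at which the predicted cpm falls to or below
#' `threshold_cpm`, alongside the smallest tested volume satisfying the
#' threshold empirically (mean across replicates). The overall safe
#' volume is the maximum across contaminants. Fitted slopes outside
#' `[-1.5, -0.5]` are flagged as departing from the inverse-volume law;
#' assays never observed are flagged `unconstrained`.
#'
#' @param rpm matrix of contaminant relative abundances (assays x
#'   libraries, in cpm/rpm).
#' @param volumes plasma input volume per library (uL).
#' @param library_sizes retained reads per library (for the pseudo-cpm
#'   floor).
#' @param threshold_cpm contamination tolerance (cpm).
#' @param floor_reads pseudo-count (read equivalents) replacing zeros.
#' @return a `titration_fit`: list with `per_assay` (data.frame `assay`,
#'   `slope`, `intercept`, `safe_volume`, `safe_volume_tested`, `flag`),
#'   `overall_safe_volume`, `overall_safe_volume_tested`,
#'   `threshold_cpm`.
#' @export
safe_input_volume <- function(rpm, volumes, library_sizes,
                              threshold_cpm = 100, floor_reads = 0.5) {
  rpm <- as.matrix(rpm)
  stopifnot(ncol(rpm) == length(volumes), length(volumes) == length(library_sizes))
  vols <- sort(unique(volumes))
  per <- lapply(rownames(rpm) %||% sprintf("assay%d", seq_len(nrow(rpm))),
                function(a) a)
  res <- data.frame(assay = unlist(per), slope = NA_real_,
                    intercept = NA_real_, safe_volume = NA_real_,
                    safe_volume_tested = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rpm))) {
    y <- rpm[i, ]
    if (all(y == 0)) {
      res$safe_volume[i] <- min(vols)
      res$safe_volume_tested[i] <- min(vols)
      res$flag[i] <- "unconstrained"
      next
    }
    floor_cpm <- floor_reads / library_sizes * 1e6
    yf <- pmax(y, floor_cpm)
    if (length(unique(volumes)) < 3L) {
      stop("titration fit needs at least 3 distinct volumes")
    }
    fit <- lm(log10(yf) ~ log10(volumes))
    a <- unname(coef(fit)[1L]); b <- unname(coef(fit)[2L])
    res$slope[i] <- b
    res$intercept[i] <- a
    if (b < 0) {
      v_pred <- 10^((log10(threshold_cpm) - a) / b)
      res$safe_volume[i] <- v_pred
    } else {
      # contamination not decreasing with volume: no fitted safe volume
      res$flag[i] <- "non_decreasing"
    }
    if (b < -1.5 || b > -0.5) res$flag[i] <- "slope_outside_inverse_law"
    mean_by_vol <- tapply(y, volumes, mean)
    ok_vols <- as.numeric(names(mean_by_vol))[mean_by_vol <= threshold_cpm]
    if (length(ok_vols)) res$safe_volume_tested[i] <- min(ok_vols)
  }
  # the overall safe volume is constrained by every assay: NA when any
  # assay never meets the threshold (fit or tested range, respectively)
  structure(
    list(per_assay = res,
         overall_safe_volume = suppressWarnings(max(res$safe_volume)),
         overall_safe_volume_tested = suppressWarnings(max(res$safe_volume_tested)),
         threshold_cpm = threshold_cpm),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Titration fit (threshold", x$threshold_cpm, "cpm):\n")
  print(x$per_assay, row.names = FALSE)
  cat("Overall safe volume (fit):", x$overall_safe_volume, "uL;",
      "smallest tested volume meeting threshold:",
      x$overall_safe_volume_tested, "uL\n")
  invisible(x)
}
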
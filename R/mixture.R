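#' Per-segment log2 ratio between two tracks
#'
#' @param segments grid-aligned segment `data.frame`.
#' @param track_num,track_den tracks on one grid.
#' @param pseudocount added to both means before the ratio.
#' @return numeric vector of per-segment log2 ratios.
#' @export
segment_log2_ratio <- function(segments, track_num, track_den,
                               pseudocount = 0.01) {
  if (!grids_identical(track_num$grid, track_den$grid)) {
    stop("tracks on different grids")
  }
  if (nrow(segments) == 0) return(numeric(0))
  log2((segment_means(track_num, segments) + pseudocount) /
         (segment_means(track_den, segments) + pseudocount))
}

bimodal_curve <- function(x, p) {
  p["A0"] * exp(-((x - p["A1"]) / p["A2"])^2) +
    p["A3"] * exp(-((x - p["A4"]) / p["A5"])^2)
}

# deterministic jitter multipliers for fit restarts (no RNG)
restart_jitter <- rbind(
  c(1.00, 0.00, 1.00, 1.00, 0.00, 1.00),
  c(1.00, -0.10, 0.70, 1.00, 0.10, 0.70),
  c(0.70, 0.10, 1.30, 1.30, -0.10, 1.30),
  c(1.30, -0.20, 1.00, 0.70, 0.20, 1.00),
  c(1.00, 0.20, 0.50, 1.00, -0.20, 0.50),
  c(0.50, 0.00, 1.50, 1.50, 0.00, 1.50),
  c(1.50, -0.30, 0.80, 0.50, 0.30, 0.80),
  c(0.80, 0.30, 1.20, 1.20, -0.30, 1.20),
  c(1.20, -0.05, 0.90, 0.90, 0.05, 0.90),
  c(0.90, 0.05, 1.10, 1.10, -0.05, 1.10))

#' Fit a two-Gaussian curve to a log2-ratio distribution
#'
#' Bins the values into an equal-width histogram and fits the density by
#' nonlinear least squares with the two-exponential model
#' `y = A0*exp(-((x-A1)/A2)^2) + A3*exp(-((x-A4)/A5)^2)`
#' (A1, A4 are the component means; A2, A5 the component widths).
#' Initialization takes the two strongest separated kernel-density peaks
#' (falling back to the 25th/75th percentiles), widths from half the
#' inter-peak distance, amplitudes from the peak densities, and runs a
#' fixed set of jittered restarts keeping the lowest residual sum of
#' squares.  Components are canonically ordered so that `A1 <= A4`.
#' The three-group boundaries are derived from the fit: `cut_high` is the
#' x between the means where the two component curves cross (midpoint of
#' the means when they do not cross) and `cut_low = A1 - A2`.
#'
#' @param values numeric vector (>= 100 values).
#' @param n_bins number of histogram bins (>= 20).
#' @return A `BimodalFit` object: list with `A` (named A0..A5), `rss`,
#'   `cut_low`, `cut_high`, `n`, `n_bins`, `converged`.
#' @export
fit_bimodal <- function(values, n_bins = 60) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 finite values")
  if (n_bins < 20) stop("n_bins must be >= 20")
  h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                           length.out = n_bins + 1),
                      plot = FALSE)
  x <- h$mids
  y <- h$density
  init <- bimodal_init(values, x, y)
  dat <- data.frame(x = x, y = y)
  span <- diff(range(values))
  best <- NULL
  for (r in seq_len(nrow(restart_jitter))) {
    j <- restart_jitter[r, ]
    start <- c(A0 = max(init["A0"] * j[1], 1e-6),
               A1 = unname(init["A1"] + j[2] * span / 4),
               A2 = max(init["A2"] * j[3], 1e-3),
               A3 = max(init["A3"] * j[4], 1e-6),
               A4 = unname(init["A4"] + j[5] * span / 4),
               A5 = max(init["A5"] * j[6], 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A0 * exp(-((x - A1) / A2)^2) + A3 * exp(-((x - A4) / A5)^2),
        data = dat, start = as.list(start),
        lower = c(0, min(x) - span, 1e-4, 0, min(x) - span, 1e-4),
        upper = c(Inf, max(x) + span, 10 * span, Inf, max(x) + span,
                  10 * span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    stop("two-component fit did not converge from any restart")
  }
  p <- best$coef
  if (p["A1"] > p["A4"]) {
    p <- stats::setNames(p[c(4, 5, 6, 1, 2, 3)],
                         c("A0", "A1", "A2", "A3", "A4", "A5"))
  }
  structure(list(A = p, rss = best$rss,
                 cut_low = unname(p["A1"] - p["A2"]),
                 cut_high = component_crossing(p),
                 n = length(values), n_bins = n_bins, converged = TRUE),
            class = "BimodalFit")
}

bimodal_init <- function(values, x, y) {
  kde <- stats::density(values)
  dy <- kde$y
  peaks <- which(diff(sign(diff(dy))) == -2) + 1
  if (length(peaks) >= 2) {
    # strongest peak, then the strongest peak at least half the data
    # range's quarter away from it
    peaks <- peaks[order(dy[peaks], decreasing = TRUE)]
    p1 <- peaks[1]
    min_sep <- diff(range(values)) / 8
    far <- peaks[abs(kde$x[peaks] - kde$x[p1]) >= min_sep]
    p2 <- if (length(far) > 0) far[1] else peaks[2]
    m <- sort(c(kde$x[p1], kde$x[p2]))
  } else {
    m <- unname(stats::quantile(values, c(0.25, 0.75)))
  }
  wdt <- max((m[2] - m[1]) / 2, diff(range(values)) / 20)
  amp <- vapply(m, function(mm) max(y[which.min(abs(x - mm))], 1e-4),
                numeric(1))
  c(A0 = amp[1], A1 = m[1], A2 = wdt, A3 = amp[2], A4 = m[2], A5 = wdt)
}

# x in (A1, A4) where the two fitted component curves are equal;
# midpoint of the means when they do not cross in the open interval.
component_crossing <- function(p) {
  f <- function(x) {
    p["A0"] * exp(-((x - p["A1"]) / p["A2"])^2) -
      p["A3"] * exp(-((x - p["A4"]) / p["A5"])^2)
  }
  lo <- unname(p["A1"])
  hi <- unname(p["A4"])
  if (hi - lo < 1e-9) return((lo + hi) / 2)
  eps <- (hi - lo) * 1e-6
  flo <- f(lo + eps)
  fhi <- f(hi - eps)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) {
    return((lo + hi) / 2)
  }
  unname(stats::uniroot(f, c(lo + eps, hi - eps), tol = 1e-9)$root)
}

#' @export
print.BimodalFit <- function(x, ...) {
  cat("BimodalFit: means", signif(x$A["A1"], 4), "/",
      signif(x$A["A4"], 4), " widths", signif(x$A["A2"], 4), "/",
      signif(x$A["A5"], 4), "\n  cuts [", signif(x$cut_low, 4), ",",
      signif(x$cut_high, 4), "], rss", signif(x$rss, 4), ", n =", x$n,
      "\n")
  invisible(x)
}

#' Single-Gaussian reference fit
#'
#' Least-squares fit of one exponential term to the same histogram; used
#' as the nested-model baseline for the two-component fit.
#'
#' @inheritParams fit_bimodal
#' @return list with `A` (A0, A1, A2) and `rss`.
#' @export
fit_unimodal <- function(values, n_bins = 60) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 finite values")
  h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                           length.out = n_bins + 1),
                      plot = FALSE)
  dat <- data.frame(x = h$mids, y = h$density)
  span <- diff(range(values))
  best <- NULL
  for (mstart in unname(stats::quantile(values, c(0.25, 0.5, 0.75)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A0 * exp(-((x - A1) / A2)^2), data = dat,
        start = list(A0 = max(dat$y), A1 = mstart,
                     A2 = stats::sd(values)),
        lower = c(0, min(dat$x) - span, 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(A = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) stop("one-component fit did not converge")
  best
}

#' Partition values into three groups by the fitted cut points
#'
#' `CL1`: x < cut_low (strong loss); `CL2`: cut_low <= x < cut_high;
#' `CL3`: x >= cut_high (gain).  Every value receives exactly one label.
#'
#' @param values numeric vector.
#' @param fit a converged `BimodalFit`.
#' @return character vector of labels.
#' @export
partition_groups <- function(values, fit) {
  stopifnot(inherits(fit, "BimodalFit"), isTRUE(fit$converged))
  ifelse(values < fit$cut_low, "CL1",
         ifelse(values < fit$cut_high, "CL2", "CL3"))
}
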
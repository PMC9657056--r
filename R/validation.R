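#' Estimate stiffness from a load-displacement record
#'
#' Ordinary least-squares slope of load against displacement over the linear
#' region. When no window is given, the contiguous window containing at
#' least half of the samples with the highest R-squared is selected, which
#' discards toe-in or settling segments automatically.
#'
#' @param record Data frame with columns `load_kn` and `disp_mm`, at least 3
#'   samples, displacements non-negative.
#' @param window Optional numeric `c(lo, hi)` load range (kN) to fit within.
#' @return List: `stiffness_kn_per_mm`, `r_squared`, `window_used` (load
#'   range actually fitted), `n_used`.
#' @export
fit_stiffness <- function(record, window = NULL) {
  stopifnot(all(c("load_kn", "disp_mm") %in% names(record)))
  if (nrow(record) < 3) stop("need at least 3 load-displacement samples")
  if (any(record$disp_mm < 0)) stop("displacements must be non-negative")
  record <- record[order(record$load_kn), ]

  fit_one <- function(sub) {
    if (stats::var(sub$disp_mm) == 0)
      stop("degenerate record: displacement has zero variance in the window")
    fit <- stats::lm(load_kn ~ disp_mm, data = sub)
    # R^2 computed directly: summary.lm warns on noiseless records
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((sub$load_kn - mean(sub$load_kn))^2)
    list(k = unname(stats::coef(fit)[2]),
         r2 = 1 - ss_res / ss_tot)
  }

  if (!is.null(window)) {
    sub <- record[record$load_kn >= window[1] & record$load_kn <= window[2], ]
    if (nrow(sub) < 3) stop("fewer than 3 samples in the requested window")
    f <- fit_one(sub)
    return(list(stiffness_kn_per_mm = f$k, r_squared = f$r2,
                window_used = range(sub$load_kn), n_used = nrow(sub)))
  }

  n <- nrow(record)
  min_len <- max(3L, ceiling(n / 2))
  best <- NULL
  for (i in seq_len(n - min_len + 1L)) {
    for (j in seq(i + min_len - 1L, n)) {
      sub <- record[i:j, ]
      f <- tryCatch(fit_one(sub), error = function(e) NULL)
      if (is.null(f)) next
      # prefer higher R^2; among near-ties keep the longer window
      if (is.null(best) || f$r2 > best$r2 + 1e-12 ||
          (abs(f$r2 - best$r2) <= 1e-12 && (j - i) > (best$j - best$i))) {
        best <- c(f, list(i = i, j = j))
      }
    }
  }
  if (is.null(best)) stop("degenerate record: no fittable window")
  list(stiffness_kn_per_mm = best$k, r_squared = best$r2,
       window_used = range(record$load_kn[best$i:best$j]),
       n_used = best$j - best$i + 1L)
}

#' Simulate a load-displacement record for a stem of known stiffness
#'
#' Linear response `disp = load / k` with optional toe-in compliance at low
#' load (a settling artifact common in compression tests) and seeded Gaussian
#' displacement noise.
#'
#' @param stiffness_kn_per_mm True stiffness in kN/mm.
#' @param loads_n Load protocol in N (default 500-1200 N in 100 N steps).
#' @param noise_sd_mm Displacement noise standard deviation in mm.
#' @param toe_mm Extra settling displacement approached exponentially at low
#'   load (0 disables it).
#' @param seed Integer seed.
#' @return Data frame with `load_kn`, `disp_mm`.
#' @export
simulate_load_displacement <- function(stiffness_kn_per_mm,
                                       loads_n = seq(500, 1200, by = 100),
                                       noise_sd_mm = 0.001, toe_mm = 0,
                                       seed = 1L) {
  stopifnot(stiffness_kn_per_mm > 0)
  set.seed(as.integer(seed))
  load_kn <- loads_n / 1000
  disp <- load_kn / stiffness_kn_per_mm +
    toe_mm * (1 - exp(-load_kn / 0.2)) +
    stats::rnorm(length(load_kn), sd = noise_sd_mm)
  data.frame(load_kn = load_kn, disp_mm = pmax(disp, 0))
}

#' Bland-Altman agreement between measured and predicted values
#'
#' Differences are measured minus predicted; the bias is their mean and the
#' 95% limits of agreement are `bias +- 1.96 * sd` with the sample (n-1)
#' standard deviation. Agreement in the sense used for model validation means
#' no point falls outside the limits.
#'
#' @param measured,predicted Equal-length numeric vectors (n >= 2).
#' @return An object of class `agreement_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, `n_outside`, `agreement`
#'   (logical), and the per-point `mean`/`difference` table for plotting.
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("measured and predicted must have the same length")
  if (length(measured) < 2) stop("need at least 2 paired values")
  d <- measured - predicted
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sd_d
  outside <- d < loa[1] | d > loa[2]
  structure(
    list(bias = bias, sd_diff = sd_d, loa_low = loa[1], loa_high = loa[2],
         n = length(d), n_outside = sum(outside), agreement = !any(outside),
         points = data.frame(mean = (measured + predicted) / 2,
                             difference = d)),
    class = "agreement_result")
}
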
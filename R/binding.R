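## Dilution-series binding curves and the specific-binding-with-Hill-slope
## model F(c) = F0 + A * c^h / (Kd^h + c^h), as used for microscale
## thermophoresis (MST) titrations of a reader domain against reconstituted
## K36me0/2/3 nucleosomes.

#' Geometric dilution series
#'
#' `c_i = top / ratio^(steps - 1 - i)`, ascending. The measured design (16
#' steps, 2:1 ratio, topping at 16 uM) bottoms out at ~0.49 nM.
#'
#' @param top highest concentration (molar).
#' @param ratio dilution ratio (> 1).
#' @param steps number of concentrations (>= 2).
#' @return ascending numeric vector of length `steps`.
#' @examples
#' dilutionSeries(16e-6, 2, 16)[1] * 1e9   # ~0.488 nM
#' @export
dilutionSeries <- function(top, ratio = 2, steps = 16) {
  stopifnot(top > 0, ratio > 1, steps >= 2)
  top / ratio^(steps - 1 - seq(0, steps - 1))
}

#' Nucleosome binding presets
#'
#' Measured dissociation constants of the JASPer PWWP reader for mono-
#' nucleosomes: Kd = 0.32 uM (K36me2), 0.60 uM (K36me3) and 4.00 uM
#' (unmodified K36me0), all with Hill slope 1, baseline 0 and unit amplitude.
#'
#' @param name one of `"K36me0"`, `"K36me2"`, `"K36me3"`.
#' @return named numeric vector: `Kd` (molar), `h`, `A`, `F0`.
#' @export
mstPreset <- function(name = c("K36me2", "K36me3", "K36me0")) {
  name <- match.arg(name)
  kd <- c(K36me2 = 0.32e-6, K36me3 = 0.60e-6, K36me0 = 4.00e-6)
  c(Kd = unname(kd[name]), h = 1, A = 1, F0 = 0)
}

hillF <- function(c, Kd, h, A, F0) F0 + A * c^h / (Kd^h + c^h)

#' Simulate an MST-style concentration-response curve
#'
#' Responses are `F(c) * (1 + eps)` with `eps ~ Normal(0, noise_cv)`; all
#' replicate points share the concentration grid.
#'
#' @param params named vector/list with `Kd`, `h`, `A`, `F0` (see
#'   [mstPreset()]).
#' @param concentrations molar concentrations (see [dilutionSeries()]).
#' @param noiseCv coefficient of variation of the multiplicative noise.
#' @param replicates number of replicate series.
#' @param seed seed; identical seeds reproduce responses exactly.
#' @return data.frame: `concentration_M`, `response`, `replicate`.
#' @export
simulateMstCurve <- function(params, concentrations, noiseCv = 0.05,
                             replicates = 1, seed = NULL) {
  stopifnot(noiseCv >= 0, all(concentrations > 0))
  p <- as.list(params)
  withSeed(seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      f <- hillF(concentrations, p$Kd, p$h, p$A, p$F0)
      data.frame(concentration_M = concentrations,
                 response = f * (1 + stats::rnorm(length(f), 0, noiseCv)),
                 replicate = r)
    })
    do.call(rbind, rows)
  })
}

#' Fit the specific-binding-with-Hill-slope model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) pooling all points:
#' initialization takes Kd at the concentration nearest the half-range
#' response, h = 1, F0 = min response, A = response range; bounds are
#' `Kd in [c_min/10, c_max*10]` and `h in [0.5, 4]` (A may be negative for
#' monotone-decreasing responses). Standard errors come from the curvature
#' at the optimum. Up to 5 jittered restarts; a response range below 3x the
#' replicate noise estimate raises a "no binding detected" error.
#'
#' @param curve data.frame with `concentration_M`, `response` (and optionally
#'   `replicate`), >= 6 distinct concentrations.
#' @param seed seed for restart jitter.
#' @return a [HillFit-class].
#' @export
fitHill <- function(curve, seed = 1) {
  stopifnot(all(c("concentration_M", "response") %in% colnames(curve)))
  conc <- curve$concentration_M
  resp <- curve$response
  if (length(unique(conc)) < 6)
    stop("need at least 6 distinct concentrations")
  rng <- diff(range(resp))
  noiseEst <- if (!is.null(curve$replicate) &&
                  any(duplicated(curve[c("concentration_M")]))) {
    sds <- tapply(resp, conc, stats::sd)
    sqrt(mean(sds^2, na.rm = TRUE))      # pooled replicate noise
  } else NA_real_
  ## flat response: the spread of per-concentration mean responses is within
  ## the replicate noise
  rngMeans <- diff(range(tapply(resp, conc, mean)))
  if (is.finite(noiseEst) && noiseEst > 0 && rngMeans < 3 * noiseEst)
    stop("no binding detected: response range below 3x the noise estimate")
  half <- min(resp) + rng / 2
  start <- list(Kd = conc[which.min(abs(resp - half))], h = 1,
                F0 = min(resp), A = rng)
  if (stats::cor(log(conc), resp) < 0) {         # decreasing response
    start$F0 <- max(resp); start$A <- -rng
  }
  lower <- c(Kd = min(conc) / 10, h = 0.5, F0 = -Inf, A = -Inf)
  upper <- c(Kd = max(conc) * 10, h = 4, F0 = Inf, A = Inf)
  fit <- NULL
  withSeed(seed, {
    for (r in 0:5) {
      st <- if (r == 0) start else {
        s <- start
        s$Kd <- min(max(start$Kd * stats::rlnorm(1, 0, 1), lower["Kd"]),
                    upper["Kd"])
        s$h <- stats::runif(1, 0.6, 2)
        s
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(response ~ F0 + A * concentration_M^h /
                            (Kd^h + concentration_M^h),
                          data = curve, start = st, lower = lower,
                          upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
  })
  if (is.null(fit))
    stop("Hill fit failed to converge after restarts; last residual range: ",
         paste(signif(range(resp - mean(resp)), 3), collapse = " .. "))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 4), names(cf)))
  new("HillFit",
      estimate = c(Kd = unname(cf["Kd"]), h = unname(cf["h"]),
                   A = unname(cf["A"]), F0 = unname(cf["F0"])),
      se = c(Kd = unname(se["Kd"]), h = unname(se["h"]),
             A = unname(se["A"]), F0 = unname(se["F0"])),
      converged = TRUE, rss = sum(stats::resid(fit)^2),
      data = curve[, c("concentration_M", "response")])
}

setMethod("show", "HillFit", function(object) {
  e <- object@estimate; s <- object@se
  cat("HillFit (specific binding with Hill slope)\n")
  cat(sprintf("  Kd = %.4g M (se %.2g), h = %.3g, A = %.4g, F0 = %.4g\n",
              e["Kd"], s["Kd"], e["h"], e["A"], e["F0"]))
  cat(sprintf("  RSS = %.4g over %d points\n", object@rss, nrow(object@data)))
})

#' @rdname HillFit-class
#' @param fit a HillFit
#' @export
hillParams <- function(fit) fit@estimate

#' @rdname HillFit-class
#' @export
hillSe <- function(fit) fit@se
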
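# Pollen morphometry: particle filtering and two-component Gaussian mixture
# analysis of grain areas (the small-pollen phenotype).

#' Filter particle measurements by size and circularity windows
#'
#' Windows are inclusive on both ends; defaults match a standard pollen
#' particle-analysis setup (area 2000-14000 um^2, circularity 0.75-1.00).
#'
#' @param particles data.frame with `area` and `circularity` columns.
#' @param size_range inclusive area window (um^2).
#' @param circ_range inclusive circularity window.
#' @return the kept rows.
#' @export
filter_particles <- function(particles, size_range = c(2000, 14000),
                             circ_range = c(0.75, 1.00)) {
  .assert(length(size_range) == 2L && size_range[1] <= size_range[2] &&
            length(circ_range) == 2L && circ_range[1] <= circ_range[2],
          "invalid ranges")
  keep <- particles$area >= size_range[1] & particles$area <= size_range[2] &
    particles$circularity >= circ_range[1] &
    particles$circularity <= circ_range[2]
  particles[keep, , drop = FALSE]
}

#' Fit a two-component Gaussian mixture to pollen areas
#'
#' EM fit on the raw area scale (components labeled so the small mean comes
#' first). The verdict is "unimodal" when BIC favors a single Gaussian or
#' when the small component's weight falls below `min_weight`; otherwise
#' "bimodal". The implied volume reduction assumes spherical grains
#' (volume proportional to area^(3/2)):
#' `1 - (mean_small / mean_large)^1.5`.
#'
#' @param areas numeric vector of particle areas (>= 50).
#' @param min_weight minimum small-component weight for bimodality (0.05).
#' @param max_iter,tol EM controls.
#' @param log_scale fit on log(area) instead of raw areas.
#' @return list with `means`, `sds`, `weights` (small component first),
#'   `small_weight`, `area_ratio` (small/large mean), `volume_ratio`
#'   (= area_ratio^1.5), `implied_volume_reduction`, `verdict`
#'   ("bimodal"/"unimodal"), `converged`, `loglik`, `bic_2`, `bic_1`.
#' @export
fit_bimodal_areas <- function(areas, min_weight = 0.05, max_iter = 500L,
                              tol = 1e-8, log_scale = FALSE) {
  .assert(length(areas) >= 50L, "need at least 50 areas")
  x <- if (log_scale) log(areas) else areas
  fit <- gmm2_em(x, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning("EM did not converge; best iterate returned")
  n <- length(x)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  bic1 <- -2 * .loglik_1gauss(x) + 2 * log(n)
  means <- if (log_scale) exp(fit$means + fit$sds^2 / 2) else fit$means
  ratio <- means[1] / means[2]
  verdict <- if (bic1 <= bic2 || fit$weights[1] < min_weight ||
                 fit$weights[2] < min_weight) "unimodal" else "bimodal"
  list(means = means, sds = fit$sds, weights = fit$weights,
       small_weight = fit$weights[1], area_ratio = ratio,
       volume_ratio = ratio^1.5,
       implied_volume_reduction = 1 - ratio^1.5,
       verdict = verdict, converged = fit$converged, loglik = fit$loglik,
       loglik_trace = fit$loglik_trace, bic_2 = bic2, bic_1 = bic1)
}
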
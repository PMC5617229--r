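#' rDNA copies per haploid genome from a duplexed well
#'
#' The core estimator: the ratio of the rDNA-channel concentration to the
#' single-copy-reference concentration is the rDNA copy number per haploid
#' genome. Because both channels share the droplet volume, the ratio is
#' independent of it. The confidence interval is built by the delta method on
#' the log-ratio, treating the two channel estimates as independent (in a
#' duplexed partition the channels are conditionally independent given the
#' droplets), and the per-reaction standard deviation follows the
#' CI-width convention \code{(CImax - CImin) / (2 * 1.96)} used to report
#' technical error from a single well.
#'
#' @param rdna \code{\link{target_estimate}} for the rDNA (multicopy) channel.
#' @param ref \code{\link{target_estimate}} for the single-copy reference
#'   channel; its occupancy must be positive.
#' @param sample_id Identifier carried into the result.
#' @return An object of class \code{copy_number_estimate} with fields
#'   \code{sample_id}, \code{copies_per_genome}, \code{ci95}, \code{sd}
#'   (CI-width standard deviation, in copies) and \code{n_droplets}.
#' @examples
#' rd <- target_estimate(20000, 18500)
#' rf <- target_estimate(20000, 380)
#' copy_number(rd, rf)
#' @seealso \code{\link{quantify_sample}} to go from raw well counts to a
#'   copy-number estimate in one call.
#' @export
copy_number <- function(rdna, ref, sample_id = "sample") {
  stopifnot(inherits(rdna, "target_estimate"), inherits(ref, "target_estimate"))
  if (ref$lambda_hat <= 0) {
    stop("reference channel has no positive droplets: ratio undefined",
         call. = FALSE)
  }
  # ratio of occupancies: identical to the concentration ratio but exactly
  # free of the droplet-volume factor
  ratio <- rdna$lambda_hat / ref$lambda_hat
  # delta method on log(ratio): var(log lambda_hat) ~ (e^lambda - 1)/(n lambda^2)
  v_log <- function(est) {
    (exp(est$lambda_hat) - 1) / (est$n_droplets * est$lambda_hat^2)
  }
  level <- ref$level
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_log <- sqrt(v_log(rdna) + v_log(ref))
  ci <- ratio * exp(c(-z, z) * se_log)
  names(ci) <- c("CImin", "CImax")
  structure(list(
    sample_id = sample_id,
    copies_per_genome = ratio,
    ci95 = ci,
    sd = sd_from_ci(ci),
    n_droplets = rdna$n_droplets,
    level = level
  ), class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: %.1f rDNA copies per haploid genome\n  %.0f%% CI [%.1f, %.1f], SD %.2f copies (%d droplets)\n",
    x$sample_id, x$copies_per_genome, 100 * x$level,
    x$ci95[1], x$ci95[2], x$sd, x$n_droplets))
  invisible(x)
}

#' @export
coef.copy_number_estimate <- function(object, ...) {
  c(copies_per_genome = unname(object$copies_per_genome))
}

#' @export
confint.copy_number_estimate <- function(object, parm, level, ...) {
  ci <- matrix(object$ci95, nrow = 1,
               dimnames = list("copies_per_genome",
                               c("CImin", "CImax")))
  ci
}

#' Standard deviation from a 95% confidence interval
#'
#' Converts a reported 95% CI into a standard deviation via
#' \code{(CImax - CImin) / (2 * 1.96)}, the convention used to express the
#' technical error of a single ddPCR reaction from its own droplet data.
#'
#' @param ci95 Numeric length-2 vector \code{(CImin, CImax)}.
#' @return Standard deviation on the same scale as the interval.
#' @examples
#' sd_from_ci(c(85, 105))         # 5.102
#' sd_from_ci(c(70.65, 119.35))   # 12.423
#' @export
sd_from_ci <- function(ci95) {
  stopifnot(is.numeric(ci95), length(ci95) == 2L)
  if (ci95[2] < ci95[1]) stop("inverted confidence interval", call. = FALSE)
  unname((ci95[2] - ci95[1]) / (2 * 1.96))
}

#' Quantify a sample's copy number from raw well counts
#'
#' Pools all wells of the sample (summing droplet tallies), estimates both
#' channels, and forms the duplexed ratio.
#'
#' @param wells Well-counts data frame (one or more rows, one sample).
#' @param config An \code{\link{assay_config}}.
#' @param level Confidence level.
#' @param force Passed to \code{\link{merge_wells}}.
#' @return A \code{\link{copy_number}} estimate.
#' @export
quantify_sample <- function(wells, config = assay_config(), level = 0.95,
                            force = FALSE) {
  w <- merge_wells(wells, force = force)
  copy_number(
    target_estimate(w$total_droplets, w$positives_rdna, config, level),
    target_estimate(w$total_droplets, w$positives_ref, config, level),
    sample_id = w$sample_id
  )
}

#' Technical error across replicate estimates
#'
#' Summarises replicate-to-replicate spread as the relative standard
#' deviation (percent) of \code{copies_per_genome} across wells, alongside
#' each well's own CI-derived relative SD. In a well-behaved assay the two
#' agree, which is what justifies reporting a single reaction's CI-derived
#' error in place of running technical replicates.
#'
#' @param estimates List of \code{copy_number_estimate} objects (>= 2).
#' @return A list with \code{rsd_percent} (100 * sample SD / mean across
#'   replicates) and \code{per_well_rsd_percent} (100 * sd / estimate, one
#'   per well).
#' @export
replicate_error <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 2L)
  ok <- vapply(estimates, inherits, logical(1), "copy_number_estimate")
  if (!all(ok)) stop("all elements must be copy_number_estimate objects",
                     call. = FALSE)
  cn <- vapply(estimates, `[[`, numeric(1), "copies_per_genome")
  m <- mean(cn)
  if (m == 0) stop("mean copy number is zero: relative SD undefined",
                   call. = FALSE)
  list(
    rsd_percent = 100 * stats::sd(cn) / m,
    per_well_rsd_percent = vapply(
      estimates, function(e) 100 * e$sd / e$copies_per_genome, numeric(1))
  )
}
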
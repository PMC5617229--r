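#' Poisson occupancy estimate from droplet counts
#'
#' In digital PCR a target's mean molecules-per-droplet (the occupancy
#' \eqn{\lambda}) is recovered from the fraction of negative droplets via
#' \eqn{\hat\lambda = -\ln((n - k)/n)} for \eqn{k} positive droplets out of
#' \eqn{n}. This is the maximum-likelihood estimate under the binomial
#' likelihood with success probability \eqn{1 - e^{-\lambda}}.
#'
#' @param n_total Total droplets (>= 1). Vectorised.
#' @param n_positive Positive droplets, \code{0 <= n_positive < n_total}.
#' @return Estimated occupancy \eqn{\hat\lambda} (molecules per droplet).
#' @examples
#' estimate_lambda(20000, 12642)  # ~1.0
#' @export
estimate_lambda <- function(n_total, n_positive) {
  check_counts(n_total, n_positive)
  if (any(n_positive == n_total)) {
    stop("all droplets positive: occupancy is unbounded (saturated well); ",
         "dilute input or merge with unsaturated replicates", call. = FALSE)
  }
  -log((n_total - n_positive) / n_total)
}

check_counts <- function(n_total, n_positive) {
  if (any(!is.finite(n_total)) || any(n_total < 1)) {
    stop("n_total must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(n_positive)) || any(n_positive < 0)) {
    stop("n_positive must be >= 0", call. = FALSE)
  }
  if (any(n_positive > n_total)) {
    stop("n_positive exceeds n_total", call. = FALSE)
  }
  invisible(TRUE)
}

#' Confidence interval for the occupancy estimate
#'
#' Delta-method normal interval on \eqn{\hat\lambda} with variance
#' \eqn{(e^{\hat\lambda} - 1)/n}, the standard digital-PCR partition-
#' statistics result (the negative-droplet count is binomial with
#' \eqn{p = e^{-\lambda}}). Truncated below at zero. With
#' \code{log_scale = TRUE} the interval is built on \eqn{\log\hat\lambda}
#' and back-transformed, which cannot go negative and is slightly asymmetric.
#'
#' @param n_total,n_positive Droplet counts, \code{0 < n_positive < n_total}
#'   for a two-sided interval; boundary counts give a degenerate interval
#'   with a warning.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param log_scale Build the interval on the log-occupancy scale.
#' @return Numeric vector \code{c(low, high)} on the \eqn{\lambda} scale.
#' @examples
#' lambda_ci(20000, 12642)
#' @export
lambda_ci <- function(n_total, n_positive, level = 0.95, log_scale = FALSE) {
  check_counts(n_total, n_positive)
  stopifnot(length(level) == 1L, level > 0, level < 1)
  if (n_positive == 0) {
    warning("no positive droplets: degenerate (one-sided) interval",
            call. = FALSE)
    return(c(low = 0, high = 0))
  }
  lam <- estimate_lambda(n_total, n_positive)  # errors if saturated
  se <- sqrt((exp(lam) - 1) / n_total)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (log_scale) {
    half <- z * se / lam
    ci <- lam * exp(c(-half, half))
  } else {
    ci <- c(max(0, lam - z * se), lam + z * se)
  }
  names(ci) <- c("low", "high")
  ci
}

#' Convert occupancy to absolute concentration
#'
#' Divides \eqn{\lambda}-scale values (molecules per droplet) by the droplet
#' volume in microlitres, yielding copies per uL of reaction.
#'
#' @param lambda Occupancy value(s); estimates or CI bounds.
#' @param config An \code{\link{assay_config}} supplying the droplet volume.
#' @return Concentration(s) in copies per uL.
#' @examples
#' concentration(0.85, assay_config(droplet_volume = 0.85))  # 1000 copies/uL
#' @export
concentration <- function(lambda, config = assay_config()) {
  config <- validate_assay_config(config)
  lambda / droplet_volume_ul(config)
}

#' Per-target estimate for one well
#'
#' Bundles occupancy, concentration and confidence interval for a single
#' fluorescence channel of a well (or of pooled replicate wells).
#'
#' @param n_total,n_positive Droplet counts for the channel.
#' @param config An \code{\link{assay_config}}.
#' @param level Confidence level for the interval.
#' @param log_scale Passed to \code{\link{lambda_ci}}.
#' @return An object of class \code{target_estimate} with fields
#'   \code{lambda_hat}, \code{concentration}, \code{ci95} (on the
#'   concentration scale), \code{n_droplets}, \code{n_positive}.
#' @examples
#' target_estimate(20000, 380)
#' @export
target_estimate <- function(n_total, n_positive, config = assay_config(),
                            level = 0.95, log_scale = FALSE) {
  lam <- estimate_lambda(n_total, n_positive)
  ci <- if (n_positive == 0) c(low = 0, high = 0) else
    lambda_ci(n_total, n_positive, level = level, log_scale = log_scale)
  structure(list(
    lambda_hat = lam,
    concentration = concentration(lam, config),
    ci95 = concentration(ci, config),
    n_droplets = as.integer(n_total),
    n_positive = as.integer(n_positive),
    level = level
  ), class = "target_estimate")
}

#' @export
print.target_estimate <- function(x, ...) {
  cat(sprintf(
    "target estimate: lambda = %.4f (%d/%d positive)\n  %.1f copies/uL [%.1f, %.1f] (%.0f%% CI)\n",
    x$lambda_hat, x$n_positive, x$n_droplets, x$concentration,
    x$ci95[1], x$ci95[2], 100 * x$level))
  invisible(x)
}

#' Pool replicate wells by summing droplet tallies
#'
#' Pooling the droplet counts of technical replicates before estimation is
#' the sufficient-statistic treatment: the merged estimate has variance no
#' larger than any single well's.
#'
#' @param wells Data frame of well counts (well-counts CSV schema) sharing
#'   one \code{sample_id}.
#' @param force Allow mixed sample ids (the first id is kept).
#' @return A one-row well-counts data frame with summed tallies.
#' @export
merge_wells <- function(wells, force = FALSE) {
  if (!is.data.frame(wells) || nrow(wells) == 0L) {
    stop("merge_wells needs a non-empty well-counts data frame", call. = FALSE)
  }
  ids <- unique(wells$sample_id)
  if (length(ids) > 1L && !force) {
    stop("wells carry different sample ids (",
         paste(ids, collapse = ", "), "); use force = TRUE to pool anyway",
         call. = FALSE)
  }
  data.frame(
    sample_id = ids[1L],
    well = paste(wells$well, collapse = "+"),
    total_droplets = sum(wells$total_droplets),
    positives_rdna = sum(wells$positives_rdna),
    positives_ref = sum(wells$positives_ref),
    stringsAsFactors = FALSE
  )
}
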
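#' Assay configuration for a duplexed ddPCR reaction
#'
#' Collects the physical parameters of one droplet digital PCR well. The
#' defaults describe a QX200-style duplexed yeast assay: ~20,000 droplets of
#' 0.85 nL in a 20 uL reaction charged with 0.005 ng of genomic DNA from a
#' 12.1 Mb haploid genome. At an average mass of 1.079e-21 g per base pair
#' this corresponds to roughly 383 haploid genome equivalents per well.
#'
#' @param n_droplets Number of droplets the reaction is partitioned into.
#' @param droplet_volume Volume of one droplet, in nanolitres.
#' @param reaction_volume Total reaction volume, in microlitres.
#' @param input_mass DNA mass loaded per reaction, in nanograms.
#' @param genome_size Haploid genome length, in base pairs.
#' @param mass_per_bp Average mass of one base pair, in grams.
#'
#' @return An object of class \code{assay_config}.
#' @examples
#' cfg <- assay_config()
#' genome_equivalents_mean(cfg)  # ~383
#' @export
assay_config <- function(n_droplets = 20000,
                         droplet_volume = 0.85,
                         reaction_volume = 20,
                         input_mass = 0.005,
                         genome_size = 12.1e6,
                         mass_per_bp = 1.079e-21) {
  cfg <- list(
    n_droplets = n_droplets,
    droplet_volume = droplet_volume,
    reaction_volume = reaction_volume,
    input_mass = input_mass,
    genome_size = genome_size,
    mass_per_bp = mass_per_bp
  )
  class(cfg) <- "assay_config"
  validate_assay_config(cfg)
}

validate_assay_config <- function(cfg) {
  stopifnot(inherits(cfg, "assay_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("n_droplets", "droplet_volume", "reaction_volume",
              "genome_size", "mass_per_bp")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("assay_config field '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (!num1(cfg$input_mass) || cfg$input_mass < 0) {
    stop("assay_config field 'input_mass' must be a single non-negative number",
         call. = FALSE)
  }
  if (cfg$n_droplets < 1) stop("n_droplets must be >= 1", call. = FALSE)
  cfg$n_droplets <- as.integer(round(cfg$n_droplets))
  # droplet_volume is nL, reaction_volume is uL
  if (cfg$droplet_volume * 1e-3 * cfg$n_droplets > cfg$reaction_volume) {
    stop("total droplet volume exceeds reaction volume", call. = FALSE)
  }
  cfg
}

#' @export
print.assay_config <- function(x, ...) {
  cat("ddPCR assay configuration\n")
  cat(sprintf("  droplets per well : %d x %.2f nL\n",
              x$n_droplets, x$droplet_volume))
  cat(sprintf("  reaction volume   : %.1f uL\n", x$reaction_volume))
  cat(sprintf("  DNA input         : %g ng (genome %.3g bp)\n",
              x$input_mass, x$genome_size))
  cat(sprintf("  genome equivalents: %.1f expected per well\n",
              genome_equivalents_mean(x)))
  invisible(x)
}

#' Expected number of haploid genome equivalents per well
#'
#' The mean of the sub-sampling distribution:
#' \code{input_mass / (genome_size * mass_per_bp)} with input mass converted
#' from nanograms to grams.
#'
#' @param config An \code{\link{assay_config}}.
#' @return Expected genome-equivalent count (a single number).
#' @export
genome_equivalents_mean <- function(config) {
  config <- validate_assay_config(config)
  (config$input_mass * 1e-9) / (config$genome_size * config$mass_per_bp)
}

#' Droplet volume in microlitres
#' @param config An \code{\link{assay_config}}.
#' @return Droplet volume in uL.
#' @keywords internal
droplet_volume_ul <- function(config) {
  config$droplet_volume * 1e-3
}
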
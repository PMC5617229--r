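#' Simulate droplet digital PCR wells and plates
#'
#' The simulator reproduces the two error sources that dominate a well-run
#' ddPCR assay: sub-sampling (the finite number of target molecules pipetted
#' into the reaction) and partitioning (random assignment of molecules to
#' droplets). With \eqn{\mu} = \code{input_mass / (genome_size * mass_per_bp)}
#' genome equivalents expected per well, the single-copy reference channel
#' carries \eqn{G \sim \mathrm{Poisson}(\mu)} molecules and the rDNA channel
#' an independent \eqn{\mathrm{Poisson}(\mu \cdot CN)} draw: extraction
#' fragments the DNA and restriction digestion separates the tandem repeats,
#' so individual target fragments are sub-sampled into the dilute aliquot
#' independently rather than as intact genomes. Every molecule is then
#' assigned to one of \code{n_droplets} droplets independently and uniformly.
#' A droplet is positive in a channel if it
#' received at least one molecule of that channel's target; optional
#' false-positive / false-negative flip rates model misclassified droplets
#' ("rain"). Both channels are scored on the same droplet partition, as in a
#' duplexed reaction.
#'
#' @name simulate_droplets
NULL

#' Specification of one simulated well
#'
#' @param true_copy_number True rDNA copies per haploid genome (> 0).
#' @param config An \code{\link{assay_config}}.
#' @param false_positive_rate Probability that an empty droplet reads
#'   positive, per channel, in [0, 1).
#' @param false_negative_rate Probability that an occupied droplet reads
#'   negative, per channel, in [0, 1).
#' @param seed Integer RNG seed; the same spec and seed always produce
#'   identical counts.
#' @param sample_id,well Identifiers copied into the output row.
#' @return An object of class \code{well_spec}.
#' @export
well_spec <- function(true_copy_number, config = assay_config(),
                      false_positive_rate = 0, false_negative_rate = 0,
                      seed = 1L, sample_id = "sample", well = "A01") {
  stopifnot(is.numeric(true_copy_number), length(true_copy_number) == 1L,
            true_copy_number > 0)
  for (r in c(false_positive_rate, false_negative_rate)) {
    if (!is.numeric(r) || length(r) != 1L || r < 0 || r >= 1) {
      stop("flip rates must lie in [0, 1)", call. = FALSE)
    }
  }
  config <- validate_assay_config(config)
  structure(list(true_copy_number = true_copy_number, config = config,
                 false_positive_rate = false_positive_rate,
                 false_negative_rate = false_negative_rate,
                 seed = as.integer(seed), sample_id = sample_id, well = well),
            class = "well_spec")
}

#' Draw the number of genome equivalents sub-sampled into a well
#'
#' Poisson draw with mean \code{input_mass / (genome_size * mass_per_bp)},
#' the classical model for molecule counts in a pipetted aliquot. Uses the
#' current RNG state; seed the generator (or call through
#' \code{\link{simulate_well}}) for reproducibility.
#'
#' @param config An \code{\link{assay_config}}.
#' @return Integer count of haploid genome equivalents.
#' @examples
#' set.seed(1)
#' genome_equivalents(assay_config())
#' @export
genome_equivalents <- function(config) {
  mu <- genome_equivalents_mean(config)
  if (mu == 0) return(0L)
  if (!is.finite(mu) || mu < 0) {
    stop("non-positive genome-equivalent mean; check assay_config",
         call. = FALSE)
  }
  stats::rpois(1L, mu)
}

# positive droplets for one channel: m molecules thrown uniformly into
# n droplets, then per-droplet flips applied
partition_positives <- function(m, n, fp, fn) {
  occupied <- if (m > 0) {
    sum(tabulate(sample.int(n, m, replace = TRUE), nbins = n) > 0L)
  } else 0L
  pos <- occupied
  if (fn > 0) pos <- pos - stats::rbinom(1L, occupied, fn)
  if (fp > 0) pos <- pos + stats::rbinom(1L, n - occupied, fp)
  as.integer(pos)
}

#' Simulate one duplexed ddPCR well
#'
#' @param spec A \code{\link{well_spec}}.
#' @return A one-row data frame with columns \code{sample_id}, \code{well},
#'   \code{total_droplets}, \code{positives_rdna}, \code{positives_ref}.
#' @examples
#' simulate_well(well_spec(150, seed = 7))
#' @export
simulate_well <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  cfg <- spec$config
  n <- cfg$n_droplets
  mu <- genome_equivalents_mean(cfg)
  if (mu * max(1, spec$true_copy_number) / n > 50) {
    warning("expected occupancy > 50 molecules per droplet: ",
            "nearly all droplets will be positive (saturation)",
            call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  g <- genome_equivalents(cfg)
  m_rdna <- stats::rpois(1L, mu * spec$true_copy_number)
  fp <- spec$false_positive_rate
  fn <- spec$false_negative_rate
  data.frame(
    sample_id = spec$sample_id,
    well = spec$well,
    total_droplets = n,
    positives_rdna = partition_positives(m_rdna, n, fp, fn),
    positives_ref = partition_positives(g, n, fp, fn),
    stringsAsFactors = FALSE
  )
}

#' Specification of a simulated screen plate
#'
#' @param wells Data frame with columns \code{well}, \code{strain},
#'   \code{role} (one of \code{"mutant"}, \code{"wt_control"},
#'   \code{"copy_control"}) and \code{true_copy_number}; well ids must be
#'   unique.
#' @param config Shared \code{\link{assay_config}}.
#' @param seed Plate-level seed. Per-well seeds are derived from it and a
#'   stable hash of the well id, so adding wells to a plate does not perturb
#'   the counts of existing wells.
#' @param false_positive_rate,false_negative_rate Per-channel flip rates
#'   shared by all wells.
#' @return An object of class \code{plate_spec}.
#' @export
plate_spec <- function(wells, config = assay_config(), seed = 1L,
                       false_positive_rate = 0, false_negative_rate = 0) {
  stopifnot(is.data.frame(wells))
  needed <- c("well", "strain", "role", "true_copy_number")
  missing_cols <- setdiff(needed, names(wells))
  if (length(missing_cols)) {
    stop("plate wells table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(wells$well)) {
    stop("duplicate well id(s): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(wells$role),
                      c("mutant", "wt_control", "copy_control"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  structure(list(wells = wells, config = validate_assay_config(config),
                 seed = as.integer(seed),
                 false_positive_rate = false_positive_rate,
                 false_negative_rate = false_negative_rate),
            class = "plate_spec")
}

# stable 31-adic string hash folded into [0, 2^31 - 2]; used to derive
# per-well seeds so that well order and plate composition do not matter
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

well_seed <- function(plate_seed, well_id) {
  as.integer((plate_seed %% 2147483647 + stable_hash(well_id)) %% 2147483647)
}

#' Simulate every well of a screen plate
#'
#' @param plate A \code{\link{plate_spec}}.
#' @return A data frame of well counts (one row per well) in the well-counts
#'   CSV schema; \code{sample_id} carries the strain id.
#' @examples
#' wells <- data.frame(well = c("A01", "A02"), strain = c("wt1", "mut1"),
#'                     role = c("wt_control", "mutant"),
#'                     true_copy_number = c(150, 60))
#' simulate_plate(plate_spec(wells, seed = 3))
#' @export
simulate_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_spec"))
  w <- plate$wells
  if (nrow(w) == 0L) {
    return(data.frame(sample_id = character(), well = character(),
                      total_droplets = integer(), positives_rdna = integer(),
                      positives_ref = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(w)), function(i) {
    simulate_well(well_spec(
      true_copy_number = w$true_copy_number[i],
      config = plate$config,
      false_positive_rate = plate$false_positive_rate,
      false_negative_rate = plate$false_negative_rate,
      seed = well_seed(plate$seed, as.character(w$well[i])),
      sample_id = as.character(w$strain[i]),
      well = as.character(w$well[i])
    ))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard 96-well screen plate layout
#'
#' Convenience generator for a plate holding wild-type control wells plus
#' mutant wells, mirroring a re-arrayed screen plate that reserves space for
#' control strains.
#'
#' @param n_controls Number of wild-type control wells.
#' @param mutant_cn Vector of true copy numbers for the mutant wells (its
#'   length sets the number of mutants; at most \code{96 - n_controls}).
#' @param wt_cn True copy number of the wild-type controls.
#' @return A wells data frame suitable for \code{\link{plate_spec}}.
#' @export
plate_layout_96 <- function(n_controls = 16, mutant_cn, wt_cn = 150) {
  n_mut <- length(mutant_cn)
  if (n_controls + n_mut > 96) stop("more than 96 wells requested",
                                    call. = FALSE)
  ids <- paste0(rep(LETTERS[1:8], each = 12),
                sprintf("%02d", rep(1:12, 8)))[seq_len(n_controls + n_mut)]
  data.frame(
    well = ids,
    strain = c(sprintf("wt_%02d", seq_len(n_controls)),
               sprintf("mut_%03d", seq_len(n_mut))),
    role = c(rep("wt_control", n_controls), rep("mutant", n_mut)),
    true_copy_number = c(rep(wt_cn, n_controls), mutant_cn),
    stringsAsFactors = FALSE
  )
}
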
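#' Read a well-counts CSV
#'
#' The well-counts table is the pipeline's interchange format for droplet
#' tallies: one row per well with columns \code{sample_id}, \code{well},
#' \code{total_droplets}, \code{positives_rdna}, \code{positives_ref}.
#' Count invariants (non-negative, positives not exceeding totals) are
#' validated and violations reported with the offending well.
#'
#' @param path Path to a CSV file with the required header.
#' @return A data frame of validated well counts.
#' @export
read_well_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character",
                                      well = "character"))
  needed <- c("sample_id", "well", "total_droplets", "positives_rdna",
              "positives_ref")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("well-counts file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- d[, needed]
  for (col in c("total_droplets", "positives_rdna", "positives_ref")) {
    bad <- !is.finite(d[[col]]) | d[[col]] < 0 | d[[col]] != round(d[[col]])
    if (any(bad)) {
      stop("well ", d$well[which(bad)[1]], ": column '", col,
           "' must be a non-negative integer", call. = FALSE)
    }
    d[[col]] <- as.integer(d[[col]])
  }
  if (nrow(d)) {
    bad <- d$total_droplets < 1
    if (any(bad)) stop("well ", d$well[which(bad)[1]],
                       ": total_droplets must be >= 1", call. = FALSE)
    for (col in c("positives_rdna", "positives_ref")) {
      bad <- d[[col]] > d$total_droplets
      if (any(bad)) {
        stop("well ", d$well[which(bad)[1]], ": ", col,
             " exceeds total_droplets", call. = FALSE)
      }
    }
  }
  d
}

#' Write a well-counts CSV
#'
#' @param counts Well-counts data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_well_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate-layout CSV
#'
#' Columns \code{plate}, \code{well}, \code{strain}, \code{role} and
#' (optionally, for simulation) \code{true_copy_number}.
#'
#' @param path Path to the layout CSV.
#' @return A data frame.
#' @export
read_plate_layout <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("well", "strain", "role")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("plate-layout file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !d$role %in% c("mutant", "wt_control", "copy_control")
  if (any(bad)) {
    stop("well ", d$well[which(bad)[1]], ": unknown role '",
         d$role[which(bad)[1]], "'", call. = FALSE)
  }
  d
}

#' Write the screen's hit table
#'
#' One row per strain: strain, copy number, CI-derived SD, category and
#' aneuploidy flag, sorted by category severity (significant, then moderate,
#' then no change), ascending copy number, and strain id as the final
#' tie-break, so repeated runs serialize identically.
#'
#' @param hits Hit table (from an \code{rdna_screen} object's \code{$hits},
#'   or any data frame with the same columns).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("strain", "copies_per_genome", "sd", "ci_low", "ci_high",
            "category", "aneuploidy_flag", "chr_ratio")
  cols <- intersect(cols, names(hits))
  out <- sort_hits(as.data.frame(hits))[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A run configuration holds the assay parameters plus pipeline settings:
#' \code{assay} (fields of \code{\link{assay_config}}), \code{ci_level},
#' \code{aneuploidy_band} (length-2, straddling 1), and optional \code{seed}.
#' Absent fields take the package defaults.
#'
#' @param path Path to a YAML file, or \code{NULL} for all defaults.
#' @return List with elements \code{assay} (an \code{assay_config}),
#'   \code{ci_level}, \code{aneuploidy_band}, \code{seed}.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  assay <- do.call(assay_config, as.list(raw$assay))
  ci_level <- if (is.null(raw$ci_level)) 0.95 else raw$ci_level
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  band <- if (is.null(raw$aneuploidy_band)) c(0.8, 1.25)
  else as.numeric(raw$aneuploidy_band)
  if (length(band) != 2L || !(band[1] < 1 && 1 < band[2])) {
    stop("aneuploidy_band must be (low, high) with low < 1 < high",
         call. = FALSE)
  }
  list(assay = assay, ci_level = ci_level, aneuploidy_band = band,
       seed = raw$seed)
}
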
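#' Hit-calling thresholds from wild-type controls
#'
#' The screen categorises each mutant by where its copy number falls relative
#' to the wild-type controls: within mean +/- 1 SD is no change, between the
#' 1 SD and 2 SD bounds is a moderate change, and strictly beyond 2 SD is a
#' significant change (the two-sided 2 SD rule corresponds to p < 0.05 under
#' a normal error model). Integer display cutoffs are the floors of the
#' mean -/+ 2 SD bounds, matching how significance cutoffs are quoted on a
#' copy-number histogram.
#'
#' @param wt_estimates Numeric vector of copies-per-genome values measured on
#'   wild-type control wells (>= 2 values), or a list of
#'   \code{copy_number_estimate} objects.
#' @return An object of class \code{screen_thresholds} with fields
#'   \code{wt_mean}, \code{wt_sd} (sample SD, n-1 denominator),
#'   \code{bounds} (mean -/+ 2 SD, -/+ 1 SD), \code{cutoffs} (integer
#'   low/high significance cutoffs) and \code{n_controls}.
#' @examples
#' compute_thresholds(c(95 - 12.175, 95, 95 + 12.175))
#' @export
compute_thresholds <- function(wt_estimates) {
  if (is.list(wt_estimates)) {
    wt_estimates <- vapply(wt_estimates, function(e) {
      if (inherits(e, "copy_number_estimate")) e$copies_per_genome
      else as.numeric(e)
    }, numeric(1))
  }
  stopifnot(is.numeric(wt_estimates))
  if (length(wt_estimates) < 2L) {
    stop("need >= 2 wild-type control values to set thresholds",
         call. = FALSE)
  }
  m <- mean(wt_estimates)
  s <- stats::sd(wt_estimates)
  if (s == 0) {
    stop("wild-type controls are all identical: degenerate SD", call. = FALSE)
  }
  bounds <- c(low2 = m - 2 * s, low1 = m - s, high1 = m + s, high2 = m + 2 * s)
  structure(list(
    wt_mean = m, wt_sd = s, bounds = bounds,
    cutoffs = c(low = floor(bounds[["low2"]]), high = floor(bounds[["high2"]])),
    n_controls = length(wt_estimates)
  ), class = "screen_thresholds")
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat(sprintf("screen thresholds from %d wild-type controls\n", x$n_controls))
  cat(sprintf("  WT copy number: %.2f +/- %.3f\n", x$wt_mean, x$wt_sd))
  cat(sprintf("  no change     : [%.2f, %.2f]\n",
              x$bounds[["low1"]], x$bounds[["high1"]]))
  cat(sprintf("  significant   : < %d or > %d copies\n",
              x$cutoffs[["low"]], x$cutoffs[["high"]]))
  invisible(x)
}

hit_categories <- c("significant_low", "moderate_low", "no_change",
                    "moderate_high", "significant_high")

#' Categorise one copy-number measurement against screen thresholds
#'
#' Values within mean +/- 1 SD (inclusive) are \code{no_change}; values
#' strictly between the 1 SD and 2 SD bounds are \code{moderate_low}/
#' \code{moderate_high}; values strictly beyond the 2 SD bounds are
#' \code{significant_low}/\code{significant_high}. Boundary values take the
#' less extreme category, since the inequalities defining the more extreme
#' class are strict.
#'
#' @param estimate A \code{copy_number_estimate} or a plain copies-per-genome
#'   number.
#' @param thresholds A \code{\link{compute_thresholds}} result.
#' @param strain Strain label for the call (defaults to the estimate's
#'   sample id).
#' @return An object of class \code{hit_call}: a one-row data frame with
#'   \code{strain}, \code{copies_per_genome}, \code{category},
#'   \code{aneuploidy_flag}, \code{chr_ratio}.
#' @examples
#' th <- compute_thresholds(c(95 - 12.175, 95, 95 + 12.175))
#' call_hit(65, th, strain = "mutX")   # significant_low
#' call_hit(110, th, strain = "mutY")  # moderate_high
#' @export
call_hit <- function(estimate, thresholds, strain = NULL) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (inherits(estimate, "copy_number_estimate")) {
    if (is.null(strain)) strain <- estimate$sample_id
    x <- estimate$copies_per_genome
  } else {
    x <- as.numeric(estimate)
    if (is.null(strain)) strain <- "sample"
  }
  b <- thresholds$bounds
  category <- if (x < b[["low2"]]) "significant_low"
  else if (x < b[["low1"]]) "moderate_low"
  else if (x <= b[["high1"]]) "no_change"
  else if (x <= b[["high2"]]) "moderate_high"
  else "significant_high"
  out <- data.frame(strain = strain, copies_per_genome = x,
                    category = factor(category, levels = hit_categories),
                    aneuploidy_flag = FALSE, chr_ratio = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_call", class(out))
  out
}

#' Chromosome XII / XIII dosage ratio for aneuploidy flagging
#'
#' A duplexed assay for one target on chromosome XII (which carries the rDNA
#' array) and one on chromosome XIII gives a concentration ratio near 1 in
#' euploid cells. Strains whose ratio falls outside the euploid band are
#' flagged, because a whole-chromosome dosage change would confound the
#' rDNA/reference ratio; flagged strains are excluded from hit lists
#' downstream, not silently dropped.
#'
#' @param chr12,chr13 \code{\link{target_estimate}}s (or plain
#'   concentrations) for the two chromosome targets; chromosome XIII must be
#'   positive.
#' @param band Closed euploid band for the ratio; ratios at the band edge are
#'   not flagged.
#' @param strain Strain label.
#' @return An object of class \code{karyotype_result} with fields
#'   \code{strain}, \code{chr12_concentration}, \code{chr13_concentration},
#'   \code{ratio}, \code{flagged}.
#' @examples
#' karyotype(2000, 1000, strain = "disomeXII")  # ratio 2, flagged
#' @export
karyotype <- function(chr12, chr13, band = c(0.8, 1.25), strain = "sample") {
  conc <- function(x) if (inherits(x, "target_estimate")) x$concentration
  else as.numeric(x)
  c12 <- conc(chr12)
  c13 <- conc(chr13)
  if (!is.finite(c13) || c13 <= 0) {
    stop("chromosome XIII concentration must be positive: ratio undefined",
         call. = FALSE)
  }
  stopifnot(length(band) == 2L, band[1] < band[2])
  ratio <- c12 / c13
  structure(list(strain = strain, chr12_concentration = c12,
                 chr13_concentration = c13, ratio = ratio,
                 flagged = ratio < band[1] || ratio > band[2],
                 band = band),
            class = "karyotype_result")
}

#' @export
print.karyotype_result <- function(x, ...) {
  cat(sprintf("%s: chrXII/chrXIII = %.3f [%s euploid band %.2f-%.2f]\n",
              x$strain, x$ratio, if (x$flagged) "OUTSIDE" else "within",
              x$band[1], x$band[2]))
  invisible(x)
}

#' Two-condition comparison of copy-number measurements
#'
#' Standard two-sample, two-tailed t test between two groups of copy-number
#' values, with the significance stars used in screen figures
#' (* p < 0.05, ** p < 0.01).
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param var.equal Pooled-variance t test (default); set \code{FALSE} for
#'   Welch.
#' @return List with \code{t}, \code{p_value}, \code{stars} (\code{""},
#'   \code{"*"} or \code{"**"}) and \code{df}.
#' @examples
#' compare_conditions(c(150, 148, 152), c(120, 119, 121))
#' @export
compare_conditions <- function(group_a, group_b, var.equal = TRUE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    # both groups degenerate: no evidence of a difference beyond the means
    tt <- list(statistic = c(t = if (mean(group_a) == mean(group_b)) 0 else Inf),
               p.value = if (mean(group_a) == mean(group_b)) 1 else 0,
               parameter = c(df = length(group_a) + length(group_b) - 2))
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = var.equal,
                        alternative = "two.sided")
  }
  p <- tt$p.value
  list(t = unname(tt$statistic), p_value = p,
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
       df = unname(tt$parameter))
}

#' Run the full screen pipeline on a plate of well counts
#'
#' Quantifies every well, sets thresholds from the wild-type control wells,
#' pools replicate wells per mutant strain, categorises each mutant, and
#' (when chromosome counts are supplied) flags aneuploid strains and excludes
#' them from the category tallies.
#'
#' @param counts Well-counts data frame (well-counts CSV schema).
#' @param layout Plate-layout data frame with columns \code{well},
#'   \code{strain}, \code{role}; must designate >= 2 \code{wt_control} wells.
#' @param config An \code{\link{assay_config}}.
#' @param level Confidence level for per-well intervals.
#' @param karyotype_counts Optional data frame with columns \code{strain},
#'   \code{total_droplets}, \code{positives_chr12}, \code{positives_chr13}
#'   from the chromosome-dosage assay.
#' @param band Euploid band for the chromosome ratio.
#' @return An object of class \code{rdna_screen} with the thresholds, a
#'   per-strain hit table (sorted by category severity then copy number),
#'   per-category tallies, and the per-well quantifications.
#' @examples
#' wells <- plate_layout_96(n_controls = 4, mutant_cn = c(150, 40))
#' counts <- simulate_plate(plate_spec(wells, seed = 11))
#' scr <- screen_pipeline(counts, wells)
#' summary(scr)
#' @export
screen_pipeline <- function(counts, layout, config = assay_config(),
                            level = 0.95, karyotype_counts = NULL,
                            band = c(0.8, 1.25)) {
  stopifnot(is.data.frame(counts), is.data.frame(layout))
  for (col in c("well", "strain", "role")) {
    if (!col %in% names(layout)) {
      stop("layout lacks column '", col, "'", call. = FALSE)
    }
  }
  merged <- merge(counts, layout[, c("well", "strain", "role")], by = "well")
  unmatched <- setdiff(counts$well, layout$well)
  if (length(unmatched)) {
    stop("well(s) missing from layout: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }

  # per-well quantification (controls are never pooled across isolates)
  quantify_row <- function(i) {
    row <- merged[i, , drop = FALSE]
    tryCatch(
      quantify_sample(row, config = config, level = level, force = TRUE),
      error = function(e) stop("well ", row$well, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  ests <- lapply(seq_len(nrow(merged)), quantify_row)
  merged$copies_per_genome <- vapply(ests, `[[`, numeric(1),
                                     "copies_per_genome")

  wt <- merged$role == "wt_control"
  if (sum(wt) < 2L) {
    stop("insufficient controls: layout must designate >= 2 wt_control wells",
         call. = FALSE)
  }
  thresholds <- compute_thresholds(merged$copies_per_genome[wt])

  # pool replicate wells per mutant strain, then call
  mut <- merged[merged$role == "mutant", , drop = FALSE]
  hit_rows <- lapply(split(mut, mut$strain), function(d) {
    est <- quantify_sample(d[, c("sample_id", "well", "total_droplets",
                                 "positives_rdna", "positives_ref")],
                           config = config, level = level, force = TRUE)
    h <- call_hit(est, thresholds, strain = d$strain[1])
    h$sd <- est$sd
    h$ci_low <- est$ci95[[1]]
    h$ci_high <- est$ci95[[2]]
    h
  })
  hits <- if (length(hit_rows)) {
    do.call(rbind, hit_rows)
  } else {
    empty <- call_hit(thresholds$wt_mean, thresholds, strain = "none")
    empty$sd <- NA_real_; empty$ci_low <- NA_real_; empty$ci_high <- NA_real_
    empty[0, , drop = FALSE]
  }

  if (!is.null(karyotype_counts) && nrow(hits)) {
    for (col in c("strain", "total_droplets", "positives_chr12",
                  "positives_chr13")) {
      if (!col %in% names(karyotype_counts)) {
        stop("karyotype_counts lacks column '", col, "'", call. = FALSE)
      }
    }
    for (i in seq_len(nrow(karyotype_counts))) {
      k <- karyotype_counts[i, ]
      idx <- which(hits$strain == k$strain)
      if (!length(idx)) next
      kr <- karyotype(
        target_estimate(k$total_droplets, k$positives_chr12, config, level),
        target_estimate(k$total_droplets, k$positives_chr13, config, level),
        band = band, strain = k$strain)
      hits$chr_ratio[idx] <- kr$ratio
      hits$aneuploidy_flag[idx] <- kr$flagged
    }
  }

  hits <- sort_hits(hits)
  rownames(hits) <- NULL
  callable <- hits[!hits$aneuploidy_flag, , drop = FALSE]
  tallies <- table(callable$category)

  structure(list(
    thresholds = thresholds,
    hits = hits,
    tallies = tallies,
    n_excluded_aneuploid = sum(hits$aneuploidy_flag),
    wells = merged,
    config = config,
    level = level
  ), class = "rdna_screen")
}

# category severity (significant first), then ascending copy number,
# then lexicographic strain id for a deterministic ordering
sort_hits <- function(hits) {
  severity <- c(significant_low = 1, significant_high = 2,
                moderate_low = 3, moderate_high = 4, no_change = 5)
  hits[order(severity[as.character(hits$category)],
             hits$copies_per_genome, hits$strain), , drop = FALSE]
}

#' @export
print.rdna_screen <- function(x, ...) {
  cat(sprintf("rDNA copy-number screen: %d wells, %d mutant strains\n",
              nrow(x$wells), nrow(x$hits)))
  cat(sprintf("  WT: %.1f +/- %.2f copies (%d controls); significant < %d or > %d\n",
              x$thresholds$wt_mean, x$thresholds$wt_sd,
              x$thresholds$n_controls,
              x$thresholds$cutoffs[["low"]], x$thresholds$cutoffs[["high"]]))
  t <- x$tallies
  cat("  calls:", paste(sprintf("%s %d", names(t), as.integer(t)),
                        collapse = ", "), "\n")
  if (x$n_excluded_aneuploid > 0) {
    cat(sprintf("  %d strain(s) flagged aneuploid and excluded from tallies\n",
                x$n_excluded_aneuploid))
  }
  invisible(x)
}

#' @export
summary.rdna_screen <- function(object, ...) {
  print(object)
  sig <- object$hits[!object$hits$aneuploidy_flag &
                       grepl("significant", object$hits$category), ,
                     drop = FALSE]
  if (nrow(sig)) {
    cat("significant hits:\n")
    print(sig[, c("strain", "copies_per_genome", "sd", "category")],
          row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.rdna_screen <- function(object, ...) {
  c(wt_mean = object$thresholds$wt_mean, wt_sd = object$thresholds$wt_sd)
}

#' Copy-number histogram with screen thresholds
#'
#' Histogram of mutant copy numbers with the wild-type mean and the
#' 1 SD / 2 SD category bounds overlaid.
#'
#' @param x An \code{rdna_screen} object.
#' @param ... Passed to \code{\link[graphics]{hist}}.
#' @export
plot.rdna_screen <- function(x, ...) {
  cn <- x$hits$copies_per_genome
  graphics::hist(cn, breaks = 30, col = "grey80", border = "white",
                 main = "rDNA copy number across screened strains",
                 xlab = "rDNA copies per haploid genome", ...)
  b <- x$thresholds$bounds
  graphics::abline(v = x$thresholds$wt_mean, col = "black", lwd = 2)
  graphics::abline(v = b[c("low1", "high1")], col = "orange", lty = 2)
  graphics::abline(v = b[c("low2", "high2")], col = "red", lty = 2)
  invisible(x)
}
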
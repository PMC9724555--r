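#' Construct a genetic map
#'
#' A genetic map is a monotone piecewise-linear mapping between physical
#' position (bp) and genetic position (cM) along one chromosome. Physical
#' positions must be strictly increasing and genetic positions non-decreasing;
#' at least two points are required.
#'
#' @param pos_bp Integer/numeric vector of physical positions (bp).
#' @param pos_cm Numeric vector of genetic positions (cM), same length.
#' @param chrom Chromosome label.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map(c(0, 1e6, 3e6), c(0, 1.0, 1.5))
#' bp_to_cm(gm, 2e6) # 1.25
#' @export
genetic_map <- function(pos_bp, pos_cm, chrom = "1") {
  if (length(pos_bp) != length(pos_cm)) {
    stop("pos_bp and pos_cm must have the same length")
  }
  if (length(pos_bp) < 2) {
    stop("a genetic map needs at least 2 points")
  }
  o <- order(pos_bp)
  pos_bp <- as.numeric(pos_bp[o])
  pos_cm <- as.numeric(pos_cm[o])
  if (any(diff(pos_bp) <= 0)) {
    stop("map bp positions must be strictly increasing")
  }
  if (any(diff(pos_cm) < 0)) {
    bad <- which(diff(pos_cm) < 0)[1] + 1L
    stop(sprintf("map cM positions decrease at point %d (bp %.0f)", bad, pos_bp[bad]))
  }
  structure(
    list(chrom = as.character(chrom), pos_bp = pos_bp, pos_cm = pos_cm),
    class = "genetic_map"
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "<genetic_map> chrom %s: %d points, %.0f-%.0f bp, %.4f-%.4f cM (%.4f cM total)\n",
    x$chrom, length(x$pos_bp), x$pos_bp[1], x$pos_bp[length(x$pos_bp)],
    x$pos_cm[1], x$pos_cm[length(x$pos_cm)], map_total_cm(x)
  ))
  invisible(x)
}

#' Total genetic length of a map
#'
#' @param map A `genetic_map`.
#' @return Last cM minus first cM.
#' @export
map_total_cm <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  map$pos_cm[length(map$pos_cm)] - map$pos_cm[1]
}

#' Interpolate genetic position at physical positions
#'
#' Piecewise-linear interpolation of the map. Positions outside the mapped bp
#' range are clamped to the terminal cM values rather than extrapolated, which
#' avoids negative or inflated genetic lengths near the ends of sparse maps.
#'
#' @param map A `genetic_map`.
#' @param pos_bp Numeric vector of physical positions (bp).
#' @return Numeric vector of genetic positions (cM).
#' @export
bp_to_cm <- function(map, pos_bp) {
  stopifnot(inherits(map, "genetic_map"))
  stats::approx(map$pos_bp, map$pos_cm, xout = as.numeric(pos_bp),
                rule = 2, ties = "ordered")$y
}

#' Invert a genetic map at genetic positions
#'
#' Requires strictly increasing cM (no zero-recombination plateaus). Used by
#' the synthetic-data generators to place segments drawn in cM space.
#'
#' @param map A `genetic_map`.
#' @param pos_cm Numeric vector of genetic positions (cM).
#' @return Numeric vector of physical positions (bp).
#' @export
cm_to_bp <- function(map, pos_cm) {
  stopifnot(inherits(map, "genetic_map"))
  if (any(diff(map$pos_cm) <= 0)) {
    stop("cm_to_bp requires a map with strictly increasing cM")
  }
  stats::approx(map$pos_cm, map$pos_bp, xout = as.numeric(pos_cm),
                rule = 2, ties = "ordered")$y
}

#' A uniform-rate genetic map
#'
#' Convenience constructor for a constant recombination rate (default
#' 1 cM/Mb), used throughout the synthetic generators.
#'
#' @param region_bp Chromosome length in bp.
#' @param cm_per_mb Recombination rate in cM per megabase.
#' @param chrom Chromosome label.
#' @return A `genetic_map`.
#' @export
uniform_map <- function(region_bp, cm_per_mb = 1, chrom = "1") {
  genetic_map(c(0, region_bp), c(0, region_bp / 1e6 * cm_per_mb), chrom = chrom)
}

# ---- haplotype pairs -------------------------------------------------------

# Canonical order for a haplotype pair: lexicographic on (sample_id, hap_index).
# Returns a logical vector: TRUE where (sample2, hap2) < (sample1, hap1).
.pair_swap_needed <- function(sample1, hap1, sample2, hap2) {
  (sample2 < sample1) | (sample2 == sample1 & hap2 < hap1)
}

#' Canonicalize haplotype pair columns
#'
#' Orders each pair so that (sample1, hap1) <= (sample2, hap2) under the
#' lexicographic total order on (sample id, haplotype index). Haplotype pairs
#' are unordered: a segment between A.0 and B.1 is the same as one between
#' B.1 and A.0.
#'
#' @param df Data frame with columns sample1, hap1, sample2, hap2.
#' @return The data frame with pairs in canonical order.
#' @export
canonicalize_pairs <- function(df) {
  swap <- .pair_swap_needed(df$sample1, df$hap1, df$sample2, df$hap2)
  if (any(swap)) {
    s1 <- df$sample1[swap]; h1 <- df$hap1[swap]
    df$sample1[swap] <- df$sample2[swap]
    df$hap1[swap] <- df$hap2[swap]
    df$sample2[swap] <- s1
    df$hap2[swap] <- h1
  }
  df
}

# Pair key strings under a pair mode. In "haplotype" mode segments are
# comparable only within the identical unordered haplotype pair; in
# "individual" mode within the unordered sample pair (all 4 haplotype
# combinations pooled).
.pair_keys <- function(df, pair_mode = "haplotype") {
  if (pair_mode == "haplotype") {
    paste(df$sample1, df$hap1, df$sample2, df$hap2, sep = "\036")
  } else {
    s1 <- pmin(df$sample1, df$sample2)
    s2 <- pmax(df$sample1, df$sample2)
    paste(s1, s2, sep = "\036")
  }
}

# ---- IBD segment table -----------------------------------------------------

#' Construct an IBD segment table
#'
#' The central container: one row per shared segment between an unordered pair
#' of haplotypes. Physical intervals are half-open `[start_bp, end_bp)`;
#' genetic coordinates, when present, must satisfy `end_cm >= start_cm` and a
#' derived `length_cm = end_cm - start_cm` column is maintained.
#'
#' @param sample1,hap1,sample2,hap2 Pair identity (hap indices 0/1).
#' @param chrom Chromosome label (recycled).
#' @param start_bp,end_bp Physical bounds, `end_bp > start_bp`.
#' @param start_cm,end_cm Genetic bounds (optional, NA allowed).
#' @param length_cm Genetic length; computed from bounds when those are
#'   present, otherwise may be supplied directly (e.g. from a call file that
#'   reports only a length).
#' @return A data frame of class `ibd_segments`, pairs canonicalized.
#' @examples
#' ibd_segments("A", 0, "B", 0, "1", 0L, 1e6L, 0, 1)
#' @export
ibd_segments <- function(sample1 = character(), hap1 = integer(),
                         sample2 = character(), hap2 = integer(),
                         chrom = character(), start_bp = integer(),
                         end_bp = integer(), start_cm = NA_real_,
                         end_cm = NA_real_, length_cm = NULL) {
  n <- length(start_bp)
  df <- data.frame(
    sample1 = as.character(sample1), hap1 = as.integer(hap1),
    sample2 = as.character(sample2), hap2 = as.integer(hap2),
    chrom = rep_len(as.character(chrom), n),
    start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
    start_cm = rep_len(as.numeric(start_cm), n),
    end_cm = rep_len(as.numeric(end_cm), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (any(!df$hap1 %in% 0:1) || any(!df$hap2 %in% 0:1)) {
      stop("haplotype indices must be 0 or 1")
    }
    if (any(df$end_bp <= df$start_bp)) {
      stop("end_bp must exceed start_bp for every segment")
    }
    ok <- !is.na(df$start_cm) & !is.na(df$end_cm)
    if (any(ok & (df$end_cm < df$start_cm))) {
      stop("end_cm must be >= start_cm")
    }
    same <- df$sample1 == df$sample2 & df$hap1 == df$hap2
    if (any(same)) stop("a segment cannot pair a haplotype with itself")
  }
  df <- canonicalize_pairs(df)
  if (is.null(length_cm)) {
    df$length_cm <- df$end_cm - df$start_cm
  } else {
    lc <- rep_len(as.numeric(length_cm), n)
    have <- !is.na(df$end_cm) & !is.na(df$start_cm)
    df$length_cm <- ifelse(have, df$end_cm - df$start_cm, lc)
  }
  class(df) <- c("ibd_segments", "data.frame")
  df
}

# rebless a plain data frame that already has the segment columns
.as_ibd_segments <- function(df) {
  df <- as.data.frame(df)
  if (!"length_cm" %in% names(df)) df$length_cm <- df$end_cm - df$start_cm
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Attach genetic coordinates to segments
#'
#' Recomputes `start_cm`, `end_cm` and `length_cm` from a genetic map. All
#' call sets scored in one benchmark should pass through the same map so that
#' every tool is measured in one genetic coordinate system.
#'
#' @param segments An `ibd_segments` table.
#' @param map A `genetic_map`.
#' @return The table with genetic coordinates filled in.
#' @export
add_genetic_coords <- function(segments, map) {
  segments$start_cm <- bp_to_cm(map, segments$start_bp)
  segments$end_cm <- bp_to_cm(map, segments$end_bp)
  segments$length_cm <- segments$end_cm - segments$start_cm
  .as_ibd_segments(segments)
}

#' Genetic overlap between two segments
#'
#' Length in cM of the intersection of the genetic intervals of `x` and `y`.
#' Returns 0 when the segments are disjoint, lie on different chromosomes, or
#' belong to different pairs under `pair_mode`.
#'
#' @param x,y Single-row `ibd_segments` tables (or lists with the same
#'   fields).
#' @param pair_mode `"haplotype"` (pairs must match exactly) or
#'   `"individual"` (sample pair must match).
#' @return Non-negative overlap in cM.
#' @export
overlap_cm <- function(x, y, pair_mode = c("haplotype", "individual")) {
  pair_mode <- match.arg(pair_mode)
  x <- as.data.frame(x); y <- as.data.frame(y)
  stopifnot(nrow(x) == 1, nrow(y) == 1)
  if (x$chrom != y$chrom) return(0)
  if (.pair_keys(x, pair_mode) != .pair_keys(y, pair_mode)) return(0)
  max(0, min(x$end_cm, y$end_cm) - max(x$start_cm, y$start_cm))
}

# ---- metric configuration --------------------------------------------------

#' Configuration for segment evaluation
#'
#' Houses the coverage threshold (a reported/truth segment counts as covered
#' when its single best match overlaps at least this fraction of its length),
#' the length-bin edges, and the pair comparison mode.
#'
#' @param coverage_threshold Fraction in (0, 1]; default 0.5.
#' @param bin_edges_cm Strictly increasing bin edges in cM; consecutive edges
#'   form half-open bins and the last bin is open-ended. Default
#'   `c(2,3,4,5,6,7)` giving \[2,3) ... \[6,7), \[7,Inf).
#' @param pair_mode `"haplotype"` or `"individual"`; see [overlap_cm()].
#' @param bins Optional explicit bin list (each element `c(lo, hi)`, `hi` may
#'   be `Inf`), overriding `bin_edges_cm`; allows non-contiguous bin sets.
#' @param length_accuracy_matched_only If TRUE, length accuracy averages over
#'   matched reported segments only; default FALSE averages over all reported
#'   segments with unmatched ones contributing 0.
#' @param penalize_unmatched_discrepancy If TRUE, unmatched reported segments
#'   enter the length-discrepancy RMS with their full length; default FALSE
#'   excludes them (no best-matching segment exists).
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(coverage_threshold = 0.5,
                          bin_edges_cm = c(2, 3, 4, 5, 6, 7),
                          pair_mode = c("haplotype", "individual"),
                          bins = NULL,
                          length_accuracy_matched_only = FALSE,
                          penalize_unmatched_discrepancy = FALSE) {
  pair_mode <- match.arg(pair_mode)
  if (coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("coverage_threshold must be in (0, 1]")
  }
  if (is.null(bins)) {
    if (length(bin_edges_cm) < 1 || any(diff(bin_edges_cm) <= 0)) {
      stop("bin_edges_cm must be strictly increasing")
    }
    lo <- bin_edges_cm
    hi <- c(bin_edges_cm[-1], Inf)
    bins <- Map(c, lo, hi)
  } else {
    bad <- vapply(bins, function(b) length(b) != 2 || b[2] <= b[1], logical(1))
    if (any(bad)) stop("each bin must be c(lo, hi) with hi > lo")
  }
  structure(
    list(coverage_threshold = coverage_threshold,
         bins = bins,
         pair_mode = pair_mode,
         length_accuracy_matched_only = length_accuracy_matched_only,
         penalize_unmatched_discrepancy = penalize_unmatched_discrepancy),
    class = "metric_config"
  )
}

.bin_label <- function(b) {
  if (is.infinite(b[2])) sprintf("[%g,Inf)", b[1]) else sprintf("[%g,%g)", b[1], b[2])
}
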
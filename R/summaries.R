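#' Per-site IBD coverage profile
#'
#' Counts, at each panel marker position, how many IBD segments of genetic
#' length at least `min_length_cm` cover that position (half-open bp
#' intervals). Comparing a detector's profile against the truth profile shows
#' which chromosomal regions a tool over- or under-calls.
#'
#' @param segments An `ibd_segments` table.
#' @param sites_bp Sorted marker positions (bp).
#' @param min_length_cm Length cutoff; only segments at least this long
#'   contribute (default 2 cM).
#' @return An object of class `coverage_profile` with `pos_bp`, `count`,
#'   `min_length_cm`.
#' @export
coverage_profile <- function(segments, sites_bp, min_length_cm = 2.0) {
  s <- as.numeric(sites_bp)
  if (is.unsorted(s)) stop("sites_bp must be sorted")
  q <- segments[!is.na(segments$length_cm) &
                  segments$length_cm >= min_length_cm, , drop = FALSE]
  delta <- numeric(length(s) + 1L)
  if (nrow(q) > 0) {
    lo <- findInterval(q$start_bp - 0.5, s) + 1L  # first site >= start_bp
    hi <- findInterval(q$end_bp - 0.5, s)         # last site < end_bp
    ok <- hi >= lo
    for (i in which(ok)) {
      delta[lo[i]] <- delta[lo[i]] + 1
      delta[hi[i] + 1L] <- delta[hi[i] + 1L] - 1
    }
  }
  structure(
    list(pos_bp = s, count = as.integer(cumsum(delta[-length(delta)])),
         min_length_cm = min_length_cm),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d sites, cutoff %.1f cM, max count %d\n",
              length(x$pos_bp), x$min_length_cm,
              if (length(x$count)) max(x$count) else 0L))
  invisible(x)
}

#' Total IBD sharing per individual pair
#'
#' Sums genetic segment lengths over every unordered sample pair, pooling all
#' haplotype combinations between the two individuals.
#'
#' @param segments An `ibd_segments` table.
#' @return Data frame `sample1, sample2, total_cm` (pairs with no segments
#'   are absent, i.e. total 0), sorted by pair.
#' @export
total_ibd_per_pair <- function(segments) {
  if (nrow(segments) == 0) {
    return(data.frame(sample1 = character(), sample2 = character(),
                      total_cm = numeric()))
  }
  dt <- data.table(
    sample1 = pmin(segments$sample1, segments$sample2),
    sample2 = pmax(segments$sample1, segments$sample2),
    length_cm = segments$length_cm
  )
  out <- dt[, .(total_cm = sum(length_cm)), by = .(sample1, sample2)]
  setorder(out, sample1, sample2)
  as.data.frame(out)
}

#' Configuration for relatedness-degree inference
#'
#' The kinship coefficient is estimated from total autosomal IBD sharing as
#' `phi = total_cm / (4 * genome_length_cm)`; degree d covers
#' `phi` in `(2^-(d+3/2), 2^-(d+1/2)]` (the standard kinship ranges: degree 1
#' is (0.177, 0.354], etc.), overridable via `kinship_bounds`. No adjustment
#' is made for detector power loss.
#'
#' @param genome_length_cm Total genetic length of the genome (or of the
#'   region over which IBD was called).
#' @param max_degree Most distant degree assigned (default 4); smaller
#'   kinship is "unrelated".
#' @param kinship_bounds Optional data frame `degree, lower, upper` replacing
#'   the defaults (intervals `(lower, upper]`, disjoint, decreasing with
#'   degree).
#' @return An object of class `relatedness_config`.
#' @export
relatedness_config <- function(genome_length_cm, max_degree = 4L,
                               kinship_bounds = NULL) {
  stopifnot(genome_length_cm > 0, max_degree >= 1)
  if (is.null(kinship_bounds)) {
    d <- seq_len(max_degree)
    kinship_bounds <- data.frame(degree = d,
                                 lower = 2^-(d + 1.5),
                                 upper = 2^-(d + 0.5))
  }
  kb <- kinship_bounds[order(kinship_bounds$degree), , drop = FALSE]
  if (any(kb$upper <= kb$lower) ||
      (nrow(kb) > 1 && any(kb$lower[-nrow(kb)] < kb$upper[-1]))) {
    stop("kinship bounds must be disjoint and decreasing with degree")
  }
  structure(list(genome_length_cm = genome_length_cm,
                 max_degree = as.integer(max_degree),
                 kinship_bounds = kb),
            class = "relatedness_config")
}

#' Assign a relatedness degree from total IBD sharing
#'
#' Vectorised. Kinship `phi = total_cm / (4 * genome_length_cm)`; degree d is
#' assigned when `phi` lies in `(lower_d, upper_d]` (upper bound inclusive);
#' values above the degree-1 upper bound (duplicates, inflated calls) clamp
#' to degree 1; at or below the most distant lower bound the pair is
#' `"unrelated"`.
#'
#' @param total_cm Non-negative total IBD sharing per pair (cM).
#' @param cfg A [relatedness_config()].
#' @return Factor with levels `"1" ... "<max_degree>", "unrelated"`.
#' @export
assign_degree <- function(total_cm, cfg) {
  if (any(total_cm < 0)) stop("total_cm must be non-negative")
  phi <- total_cm / (4 * cfg$genome_length_cm)
  kb <- cfg$kinship_bounds
  breaks <- c(-Inf, rev(kb$lower), Inf)
  labels <- c("unrelated", rev(as.character(kb$degree)))
  cut(phi, breaks = breaks, labels = labels, right = TRUE)
}

#' Degree histograms for truth vs reported calls
#'
#' Computes total IBD per individual pair in each segment set, assigns
#' degrees, and tabulates the number of pairs per degree for side-by-side
#' comparison. Pairs present in either set are counted in both tables (a
#' pair absent from one set has total 0 there).
#'
#' @param truth_segments,reported_segments `ibd_segments` tables over the
#'   same cohort.
#' @param cfg A [relatedness_config()].
#' @return List with `pairs` (per-pair totals and degrees for both sets) and
#'   `counts` (data frame `degree, n_truth, n_reported`).
#' @export
relatedness_table <- function(truth_segments, reported_segments, cfg) {
  tt <- total_ibd_per_pair(truth_segments)
  tr <- total_ibd_per_pair(reported_segments)
  all_pairs <- merge(tt, tr, by = c("sample1", "sample2"), all = TRUE,
                     suffixes = c("_truth", "_reported"))
  all_pairs$total_cm_truth[is.na(all_pairs$total_cm_truth)] <- 0
  all_pairs$total_cm_reported[is.na(all_pairs$total_cm_reported)] <- 0
  all_pairs$degree_truth <- assign_degree(all_pairs$total_cm_truth, cfg)
  all_pairs$degree_reported <- assign_degree(all_pairs$total_cm_reported, cfg)
  lev <- levels(all_pairs$degree_truth)
  counts <- data.frame(
    degree = lev,
    n_truth = as.integer(table(all_pairs$degree_truth)[lev]),
    n_reported = as.integer(table(all_pairs$degree_reported)[lev]),
    stringsAsFactors = FALSE
  )
  list(pairs = all_pairs, counts = counts)
}
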
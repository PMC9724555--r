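# Shared fixture builders. All segment coordinates are built on an implicit
# uniform 1 cM/Mb map so cM values are easy to read off.

# segments from cM bounds (vectorised); bp = cM * 1e6
cm_seg <- function(start_cm, end_cm, sample1 = "A", sample2 = "B",
                   hap1 = 0L, hap2 = 0L, chrom = "1") {
  ibd_segments(sample1 = rep_len(sample1, length(start_cm)),
               hap1 = rep_len(hap1, length(start_cm)),
               sample2 = rep_len(sample2, length(start_cm)),
               hap2 = rep_len(hap2, length(start_cm)),
               chrom = chrom,
               start_bp = round(start_cm * 1e6), end_bp = round(end_cm * 1e6),
               start_cm = start_cm, end_cm = end_cm)
}

bind_segs <- function(...) {
  df <- rbind(...)
  class(df) <- c("ibd_segments", "data.frame")
  df
}

# random monotone genetic map
rand_map <- function(seed, n_points = 8) {
  withr::with_seed(seed, {
    bp <- sort(sample.int(1e7, n_points))
    cm <- cumsum(runif(n_points, 0, 2))
    genetic_map(bp, cm)
  })
}

# a randomised perturbation scenario (sizes kept small)
rand_spec <- function(seed, max_pairs = 8, segments_per_pair = 1:2) {
  withr::with_seed(seed * 7919 + 13, {
    scenario_spec(
      n_pairs = sample(2:max_pairs, 1),
      segments_per_pair = segments_per_pair,
      boundary_jitter_cm = runif(1, 0, 0.5),
      fragmentation_prob = runif(1),
      gap_cm = runif(1, 0, 0.5),
      false_positive_rate = runif(1, 0, 0.4),
      drop_rate = runif(1, 0, 0.3),
      seed = seed
    )
  })
}

# a small random local-tree track
rand_track <- function(seed, n_haplotypes = NULL, region_bp = NULL,
                       mean_segment_bp = NULL) {
  withr::with_seed(seed * 104729 + 7, {
    if (is.null(n_haplotypes)) n_haplotypes <- sample(c(4, 6, 8, 10, 12), 1)
    if (is.null(region_bp)) region_bp <- sample(2:4, 1) * 1e5
    if (is.null(mean_segment_bp)) mean_segment_bp <- sample(2:6, 1) * 1e4
  })
  gen_track(n_haplotypes, region_bp, mean_segment_bp, seed = seed)
}

# sort a segment table into a canonical row order for set comparisons
sort_segs <- function(df) {
  df <- as.data.frame(df)
  df <- df[order(df$sample1, df$hap1, df$sample2, df$hap2,
                 df$start_bp, df$end_bp), ]
  rownames(df) <- NULL
  df
}
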
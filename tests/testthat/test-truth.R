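mk_two_tree_track <- function(split_bp = 3e6, region_bp = 5e6) {
  runs <- data.frame(sample1 = "a", hap1 = 0L, sample2 = "b", hap2 = 0L,
                     start_bp = c(0, split_bp), end_bp = c(split_bp, region_bp),
                     label = c(101L, 202L))
  local_tree_track(runs, region_bp)
}

test_that("MRCA labels follow the local tree containing each position", {
  # single tree: constant labels
  one <- local_tree_track(
    data.frame(sample1 = "a", hap1 = 0L, sample2 = "b", hap2 = 0L,
               start_bp = 0, end_bp = 1e6, label = 7L), 1e6)
  expect_equal(mrca_labels(one, list(sample1 = "a", hap1 = 0L,
                                     sample2 = "b", hap2 = 0L),
                           c(0, 5e5, 999999)), c(7L, 7L, 7L))

  tr <- mk_two_tree_track()
  pair <- list(sample1 = "a", hap1 = 0L, sample2 = "b", hap2 = 0L)
  expect_equal(mrca_labels(tr, pair, c(0, 2.5e6, 4e6)), c(101L, 101L, 202L))
  # interval boundary belongs to the right-hand (half-open) interval
  expect_equal(mrca_labels(tr, pair, 3e6), 202L)
  expect_error(mrca_labels(tr, pair, 5e6), "within")
  # unordered pair lookup
  expect_equal(mrca_labels(tr, list(sample1 = "b", hap1 = 0L,
                                    sample2 = "a", hap2 = 0L), 0), 101L)
})

test_that("truth extraction finds MRCA runs and applies the length filter", {
  map <- uniform_map(5e6)  # 1 cM/Mb
  tr <- mk_two_tree_track()
  segs <- extract_truth_ibd(tr, map, sample_step_bp = 5000, min_length_cm = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$length_cm, c(3.0, 2.0))
  expect_equal(segs$start_bp, c(0, 3e6))
  expect_equal(segs$end_bp, c(3e6, 5e6))   # terminal run closes at L

  # a 0.5 cM run is dropped by the >= 1 cM filter
  tr2 <- local_tree_track(
    data.frame(sample1 = "a", hap1 = 0L, sample2 = "b", hap2 = 0L,
               start_bp = c(0, 5e5), end_bp = c(5e5, 5e6), label = 1:2), 5e6)
  segs2 <- extract_truth_ibd(tr2, map)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$start_bp, 5e5)

  # single MRCA across the region: exactly one spanning segment
  one <- local_tree_track(
    data.frame(sample1 = "a", hap1 = 0L, sample2 = "b", hap2 = 0L,
               start_bp = 0, end_bp = 5e6, label = 9L), 5e6)
  segs3 <- extract_truth_ibd(one, map)
  expect_equal(nrow(segs3), 1)
  expect_equal(c(segs3$start_bp, segs3$end_bp), c(0, 5e6))
})

test_that("extraction agrees with the per-position oracle on random tracks", {
  for (s in 1:10) {
    tr <- rand_track(s)
    map <- uniform_map(tr$region_bp, cm_per_mb = 10)
    a <- extract_truth_ibd(tr, map, sample_step_bp = 5000, min_length_cm = 0.5)
    b <- extract_truth_ibd_oracle(tr, map, sample_step_bp = 5000,
                                  min_length_cm = 0.5)
    expect_equal(sort_segs(a), sort_segs(b), tolerance = 1e-12)
  }
})

test_that("degenerate length filters behave at both extremes", {
  tr <- rand_track(4)
  map <- uniform_map(tr$region_bp, cm_per_mb = 10)
  expect_equal(nrow(extract_truth_ibd(tr, map, min_length_cm = Inf)), 0)
  expect_equal(nrow(extract_truth_ibd_oracle(tr, map, min_length_cm = Inf)), 0)
  all_runs <- extract_truth_ibd(tr, map, min_length_cm = 0)
  # with no filter, sampled runs per pair must cover the whole region
  dt <- data.table::as.data.table(all_runs)
  span <- dt[, .(tot = sum(end_bp - start_bp)),
             by = .(sample1, hap1, sample2, hap2)]
  expect_true(all(span$tot == tr$region_bp))
})

test_that("per-pair truth segments never overlap", {
  # adjacent MRCA runs yield touching segments (shared boundary, gap 0);
  # a dropped sub-threshold run leaves a gap of at least one step
  for (s in 1:5) {
    tr <- rand_track(s + 100)
    map <- uniform_map(tr$region_bp, cm_per_mb = 10)
    segs <- extract_truth_ibd(tr, map, sample_step_bp = 5000, min_length_cm = 0.5)
    dt <- data.table::as.data.table(segs)
    gaps <- dt[, if (.N > 1) .(gap = start_bp[-1] - end_bp[-.N]) else NULL,
               by = .(sample1, hap1, sample2, hap2)]
    if (nrow(gaps) > 0) {
      expect_true(all(gaps$gap >= 0))
      expect_true(all(gaps$gap == 0 | gaps$gap >= 5000))
    }
    expect_true(all(segs$length_cm >= 0.5))
  }
})

test_that("refining the sampling step never merges segments and drifts less than a step", {
  for (s in 1:5) {
    tr <- rand_track(s + 200, n_haplotypes = 6)
    map <- uniform_map(tr$region_bp, cm_per_mb = 10)
    coarse <- extract_truth_ibd(tr, map, sample_step_bp = 5000, min_length_cm = 0)
    fine <- extract_truth_ibd(tr, map, sample_step_bp = 1000, min_length_cm = 0)
    expect_gte(nrow(fine), nrow(coarse))
    # every coarse boundary has a fine boundary within the old step
    ck <- paste(coarse$sample1, coarse$hap1, coarse$sample2, coarse$hap2)
    fk <- paste(fine$sample1, fine$hap1, fine$sample2, fine$hap2)
    for (k in unique(ck)) {
      cb <- sort(unique(c(coarse$start_bp[ck == k], coarse$end_bp[ck == k])))
      fb <- sort(unique(c(fine$start_bp[fk == k], fine$end_bp[fk == k])))
      drift <- vapply(cb, function(x) min(abs(fb - x)), numeric(1))
      expect_true(all(drift < 5000))
    }
  }
})
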
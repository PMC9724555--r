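test_that("best match maximizes overlap with documented tie-breaks", {
  subj <- cm_seg(12, 18)
  bm <- best_match(subj, cm_seg(10, 20))
  expect_equal(bm$best_overlap_cm, 6)
  expect_true(bm$covered)

  # two candidates tie on overlap 4; equal |length diff| too, so the earlier
  # start wins; 4/10 < 0.5 so not covered
  subj2 <- cm_seg(0, 10)
  cands <- cm_seg(c(0, 5), c(4, 9))
  bm2 <- best_match(subj2, cands)
  expect_equal(bm2$best_overlap_cm, 4)
  expect_false(bm2$covered)
  expect_equal(bm2$best$start_cm, 0)

  bm3 <- best_match(subj, cm_seg(10, 20, sample2 = "Z"))
  expect_null(bm3$best)
  expect_false(bm3$covered)
})

test_that("reported-side metrics match hand-computed values", {
  # nested call: fully covered, discrepancy |6 - 10| = 4
  out <- evaluate_reported(cm_seg(12, 18), cm_seg(10, 20))
  expect_equal(out$accuracy, 1.0)
  expect_equal(out$length_accuracy, 1.0)
  expect_equal(out$length_discrepancy_cm, 4.0)

  # two fragments of one truth segment
  out2 <- evaluate_reported(cm_seg(c(0, 5), c(4, 9)), cm_seg(0, 10))
  expect_equal(out2$accuracy, 1.0)
  expect_equal(out2$length_accuracy, 1.0)
  expect_equal(out2$length_discrepancy_cm, 6.0)  # sqrt((6^2 + 6^2)/2)

  # disjoint from truth: zero accuracy, undefined discrepancy
  out3 <- evaluate_reported(cm_seg(50, 55), cm_seg(0, 10))
  expect_equal(out3$accuracy, 0.0)
  expect_equal(out3$length_accuracy, 0.0)
  expect_true(is.na(out3$length_discrepancy_cm))

  out4 <- evaluate_reported(ibd_segments(), cm_seg(0, 10))
  expect_true(is.na(out4$accuracy))
  expect_equal(out4$n_reported, 0L)
})

test_that("truth-side metrics match hand-computed values", {
  truth <- cm_seg(0, 10)
  rep2 <- cm_seg(c(0, 5), c(4, 9))
  out <- evaluate_truth(truth, rep2)
  expect_equal(out$recall, 0.0)              # best single 4/10 < 0.5
  expect_equal(out$power, 0.4)
  expect_equal(out$accumulative_power, 0.8)  # union (4 + 4)/10

  out2 <- evaluate_truth(truth, cm_seg(0, 10))
  expect_equal(unlist(out2[1:3]), c(recall = 1, power = 1,
                                    accumulative_power = 1))

  # exactly 50% coverage counts ("at least" boundary inclusive)
  out3 <- evaluate_truth(truth, cm_seg(0, 5))
  expect_equal(out3$recall, 1.0)

  out4 <- evaluate_truth(ibd_segments(), rep2)
  expect_true(is.na(out4$recall))
})

test_that("overlapping reported segments are not double-counted in accumulative power", {
  truth <- cm_seg(0, 10)
  rep3 <- cm_seg(c(0, 2, 20), c(6, 8, 30))
  out <- evaluate_truth(truth, rep3)
  expect_equal(out$power, 0.6)
  expect_equal(out$accumulative_power, 0.8)  # union [0,8), not 6+6
})

test_that("segments bin by genetic length into half-open bins", {
  segs <- cm_seg(c(0, 0, 0), c(2.9, 7.5, 1.5))
  bins <- bin_segments(segs)
  expect_equal(bins[["[2,3)"]]$length_cm, 2.9)
  expect_equal(bins[["[7,Inf)"]]$length_cm, 7.5)
  expect_equal(sum(vapply(bins, nrow, integer(1))), 2L)  # 1.5 cM excluded
})

test_that("full-set reference rescues near-boundary matches that per-bin reference loses", {
  truth <- cm_seg(0, 3.0)
  rep1 <- cm_seg(0.05, 2.95)  # 2.9 cM call for a 3.0 cM truth segment
  full <- evaluate_binned(truth, rep1, reference = "full")
  perbin <- evaluate_binned(truth, rep1, reference = "bin")
  expect_equal(full$accuracy[full$bin == "[2,3)"], 1.0)
  expect_equal(perbin$accuracy[perbin$bin == "[2,3)"], 0.0)
  # truth sits in [3,4): full-set reference finds the reported match
  expect_equal(full$recall[full$bin == "[3,4)"], 1.0)
})

test_that("identical truth and reported sets score perfectly in every populated bin", {
  withr::with_seed(5, {
    s <- runif(30, 0, 80)
    segs <- cm_seg(s, s + runif(30, 2, 10),
                   sample1 = sprintf("a%d", 1:30),
                   sample2 = sprintf("b%d", 1:30))
  })
  rep <- evaluate_binned(segs, segs)
  pop <- rep[rep$n_truth > 0, ]
  expect_true(all(pop$accuracy == 1 & pop$recall == 1 & pop$power == 1 &
                    pop$accumulative_power == 1))
  expect_true(all(pop$length_discrepancy_cm == 0))
})

test_that("metrics are invariant under segment order permutation", {
  sc <- gen_scenario(rand_spec(31))
  a <- evaluate_binned(sc$truth, sc$reported)
  withr::with_seed(1, {
    tperm <- sc$truth[sample(nrow(sc$truth)), ]
    rperm <- sc$reported[sample(nrow(sc$reported)), ]
  })
  b <- evaluate_binned(bind_segs(tperm), bind_segs(rperm))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("individual pair mode pools haplotype combinations", {
  truth <- cm_seg(0, 10, hap1 = 0, hap2 = 0)
  rep_other_hap <- cm_seg(0, 10, hap1 = 1, hap2 = 1)
  expect_equal(evaluate_truth(truth, rep_other_hap)$power, 0)
  cfg_ind <- metric_config(pair_mode = "individual")
  expect_equal(evaluate_truth(truth, rep_other_hap, cfg_ind)$power, 1)
})

test_that("engine equals the naive oracle across random scenarios and modes", {
  for (s in 1:60) {
    sc <- gen_scenario(rand_spec(s + 500))   # expected computed by oracle
    got <- evaluate_binned(sc$truth, sc$reported)
    expect_equal(got, sc$expected, tolerance = 1e-12)
  }
  # per-bin reference and individual mode agree with the oracle too
  for (s in 1:10) {
    sp <- rand_spec(s + 900)
    sc <- gen_scenario(sp)
    for (cfg in list(metric_config(pair_mode = "individual"),
                     metric_config(length_accuracy_matched_only = TRUE),
                     metric_config(penalize_unmatched_discrepancy = TRUE))) {
      expect_equal(evaluate_binned(sc$truth, sc$reported, cfg),
                   oracle_metric_report(sc$truth, sc$reported, cfg),
                   tolerance = 1e-12)
    }
    expect_equal(evaluate_binned(sc$truth, sc$reported, reference = "bin"),
                 oracle_metric_report(sc$truth, sc$reported, reference = "bin"),
                 tolerance = 1e-12)
  }
})

test_that("metric reports serialize to TSV and JSON", {
  sc <- gen_scenario(rand_spec(77))
  rep <- evaluate_binned(sc$truth, sc$reported)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, tsv)
  write_metric_report(rep, js)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(rep))
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-9)
  expect_equal(length(jsonlite::read_json(js)), nrow(rep))
})
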
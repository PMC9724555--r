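# panel with hand-set allele counts per site
panel_from_counts <- function(counts, n_hap, pos = NULL) {
  A <- t(vapply(counts, function(k) {
    c(rep(1L, k), rep(0L, n_hap - k))
  }, integer(n_hap)))
  if (is.null(pos)) pos <- seq_len(length(counts)) * 1000
  haplotype_panel(A, pos, sprintf("s%02d", seq_len(n_hap / 2)))
}

test_that("site filtering removes multiallelic sites and singletons", {
  p <- panel_from_counts(c(1, 2, 5, 0), n_hap = 10)
  p$alleles[3, 1] <- 2L  # make site 3 triallelic (0/1/2 observed)
  kept <- filter_sites(p)
  # singleton (count 1), triallelic and monomorphic removed; count 2 retained
  expect_equal(kept$pos_bp, 2000)
  # idempotent
  expect_identical(filter_sites(kept), kept)
})

test_that("singleton boundary: minor allele count 2 is retained, 1 is not", {
  p <- panel_from_counts(c(1, 2, 7999), n_hap = 8000)
  kept <- filter_sites(p)
  expect_equal(kept$pos_bp, 2000)  # count 7999 of 8000 = minor count 1
})

test_that("array downsampling follows the two-pass highest-MAF rule", {
  # 10 cM chromosome, target 5 (I = 2 cM), w = 5:
  # sites at cM {0.1,1.9,2.5,3.1,6.2,9.9} with MAF {.30,.40,.10,.20,.25,.05}
  map <- uniform_map(1e7)
  counts <- round(c(.30, .40, .10, .20, .25, .05) * 20)
  p <- panel_from_counts(counts, n_hap = 20,
                         pos = c(0.1, 1.9, 2.5, 3.1, 6.2, 9.9) * 1e6)
  expect_equal(site_maf(p), c(.30, .40, .10, .20, .25, .05))
  ds <- downsample_to_array(p, map, target_sites = 5, window = 5)
  expect_equal(ds$pos_bp / 1e6, c(0.1, 1.9, 3.1, 6.2, 9.9))
})

test_that("downsampling edge cases: target >= sites, single interval", {
  map <- uniform_map(1e7)
  p <- panel_from_counts(c(3, 5, 7), n_hap = 20, pos = c(1e6, 2e6, 3e6))
  expect_warning(ds <- downsample_to_array(p, map, target_sites = 10),
                 "returning all sites")
  expect_equal(ds$pos_bp, p$pos_bp)

  # all sites in the first interval: pass 1 takes the best, pass 2 fills
  # other intervals of the same window from the leftovers
  p2 <- panel_from_counts(c(3, 5, 7), n_hap = 20, pos = c(1000, 2000, 3000))
  ds2 <- downsample_to_array(p2, map, target_sites = 2, window = 5)
  expect_equal(nrow(ds2$alleles), 2)  # best two MAFs selected
  expect_equal(ds2$pos_bp, c(2000, 3000))
})

test_that("downsampled output respects the target count", {
  for (s in 1:5) {
    p <- gen_panel(20, 2000, seed = s)
    map <- uniform_map(max(p$pos_bp) + 1)
    ds <- downsample_to_array(p, map, target_sites = 300, window = 5)
    expect_lte(nrow(ds$alleles), 300)
    expect_false(is.unsorted(ds$pos_bp))
  }
})

test_that("error injection: rate 0 is the identity, rate 1 flips everything", {
  p <- gen_panel(10, 100, seed = 1)
  r0 <- inject_genotyping_errors(p, 0, seed = 2)
  expect_identical(r0$panel$alleles, p$alleles)
  expect_equal(nrow(r0$errors), 0)
  r1 <- inject_genotyping_errors(p, 1, seed = 2)
  expect_identical(r1$panel$alleles, 1L - p$alleles)
  expect_equal(nrow(r1$errors), length(p$alleles))
  expect_error(inject_genotyping_errors(p, 1.5, seed = 1), "rate")
})

test_that("error injection is seed-deterministic and binomially distributed", {
  p <- gen_panel(100, 10000, seed = 3)  # 1e6 alleles
  a <- inject_genotyping_errors(p, 0.001, seed = 7)
  b <- inject_genotyping_errors(p, 0.001, seed = 7)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$errors, b$errors)
  # 99% binomial interval around 1000
  expect_gte(nrow(a$errors), 919)
  expect_lte(nrow(a$errors), 1081)
})

test_that("incremental error chains are nested and realize the marginal rate", {
  p <- gen_panel(100, 10000, seed = 4)
  r1 <- inject_genotyping_errors(p, 0.001, seed = 5)
  r2 <- inject_genotyping_errors(r1$panel, 0.002, seed = 6,
                                 base_errors = r1$errors, base_rate = 0.001)
  r3 <- inject_genotyping_errors(r2$panel, 0.004, seed = 7,
                                 base_errors = r2$errors, base_rate = 0.002)
  key <- function(e) paste(e$site, e$haplotype)
  expect_true(all(key(r1$errors) %in% key(r2$errors)))
  expect_true(all(key(r2$errors) %in% key(r3$errors)))
  # marginal totals within 99% binomial intervals of n * rate
  n <- length(p$alleles)
  for (r in list(r2, r3)) {
    mu <- n * r$rate
    sd3 <- 2.576 * sqrt(mu * (1 - r$rate))
    expect_gte(nrow(r$errors), mu - sd3)
    expect_lte(nrow(r$errors), mu + sd3)
  }
  # flipped cells really are flipped relative to the original panel
  flipped <- matrix(FALSE, nrow(p$alleles), ncol(p$alleles))
  flipped[cbind(r3$errors$site, r3$errors$haplotype)] <- TRUE
  expect_identical(r3$panel$alleles[flipped], 1L - p$alleles[flipped])
  expect_identical(r3$panel$alleles[!flipped], p$alleles[!flipped])
})

test_that("error injection shifts site allele frequencies by at most r plus noise", {
  p <- gen_panel(200, 2000, seed = 8)
  r <- 0.01
  inj <- inject_genotyping_errors(p, r, seed = 9)
  shift <- abs(rowMeans(inj$panel$alleles) - rowMeans(p$alleles))
  sigma <- sqrt(r * (1 - r) / 200)
  expect_lte(mean(shift), r + 3 * sigma)
  # per-site worst case over 2000 sites needs a wider tail allowance
  expect_true(all(shift <= r + 6 * sigma))
})

test_that("haplotype merging pairs consecutive haplotypes into genotypes", {
  A <- matrix(c(0L, 1L, 1L, 1L,
                1L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
  p <- haplotype_panel(A, c(100, 200), c("s1", "s2"))
  g <- merge_haplotypes_to_genotypes(p)
  expect_equal(g$gt[1, ], c(s1 = "0/1", s2 = "1/1"))
  expect_equal(g$gt[2, ], c(s1 = "0/1", s2 = "0/0"))
  expect_equal(g$dosage[, 1], c(1L, 1L))
  # genotype is unordered: (1,0) and (0,1) merge identically
  expect_equal(g$gt[1, "s1"], g$gt[2, "s1"])

  p8 <- gen_panel(8, 5, seed = 2)
  expect_length(merge_haplotypes_to_genotypes(p8)$sample_id, 4)

  p_odd <- p
  p_odd$alleles <- p_odd$alleles[, 1:3]
  expect_error(merge_haplotypes_to_genotypes(p_odd), "even")
})
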
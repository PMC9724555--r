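test_that("phased VCF round trip preserves the allele matrix", {
  p <- haplotype_panel(
    matrix(c(0L,1L,0L,1L, 1L,1L,0L,0L, 0L,0L,1L,1L), nrow = 3, byrow = TRUE),
    pos_bp = c(100, 200, 300), sample_ids = c("s1", "s2"), chrom = "20"
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p, f)
  p2 <- read_vcf(f)
  expect_equal(dim(p2), c(3, 4))
  expect_identical(unname(p2$alleles), unname(p$alleles))
  expect_equal(p2$pos_bp, p$pos_bp)
  expect_equal(p2$chrom, "20")
})

test_that("a large generated panel survives the VCF round trip", {
  p <- gen_panel(8000, 25, seed = 11)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p, f)
  p2 <- read_vcf(f)
  expect_identical(unname(p2$alleles), unname(p$alleles))
  expect_equal(p2$pos_bp, p$pos_bp)
})

test_that("unphased genotypes are a hard error when phasing is required", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1",
    "1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"
  ), f)
  expect_error(read_vcf(f), "unphased genotype at site 1:200")
  p <- read_vcf(f, phased_required = FALSE)
  expect_equal(dim(p), c(2, 2))
})

test_that("an empty panel writes and reads as a header-only VCF", {
  p0 <- haplotype_panel(matrix(integer(0), 0, 4), numeric(0), c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p0, f)
  p0b <- read_vcf(f)
  expect_equal(nrow(p0b$alleles), 0)
  expect_equal(ncol(p0b$alleles), 4)
})

test_that("PLINK and HapMap map dialects read to the same map", {
  fp <- withr::local_tempfile(fileext = ".map")
  writeLines(c("20 m1 0.0 100", "20 m2 1.0 1000000", "20 m3 1.5 3000000"), fp)
  m1 <- read_genetic_map(fp, "plink")
  expect_length(m1$pos_bp, 3)
  expect_equal(m1$pos_cm, c(0, 1, 1.5))
  expect_equal(m1$chrom, "20")

  fh <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr position rate_cM_Mb cM",
               "20 100 1.0 0.0", "20 1000000 0.5 1.0", "20 3000000 0 1.5"), fh)
  m2 <- read_genetic_map(fh, "hapmap")
  expect_equal(m2$pos_bp, m1$pos_bp)
  expect_equal(m2$pos_cm, m1$pos_cm)

  fbad <- withr::local_tempfile(fileext = ".map")
  writeLines(c("20 m1 0.0 100", "20 m2 1.0 1000000", "20 m3 0.9 3000000"), fbad)
  expect_error(read_genetic_map(fbad, "plink"), "decreases")
})

test_that("hap-IBD dialect rows convert coordinates and haplotype indices", {
  map <- uniform_map(1e7, chrom = "20")
  f <- withr::local_tempfile(fileext = ".ibd")
  writeLines("s1\t1\ts2\t2\t20\t1000001\t2000000\t1.0", f)
  segs <- read_ibd_calls(f, ibd_dialect("hapibd"), map)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$hap1, 0L)
  expect_equal(segs$hap2, 1L)
  expect_equal(segs$start_bp, 1e6)   # 1-based inclusive -> half-open 0-based
  expect_equal(segs$end_bp, 2e6)
  expect_equal(segs$length_cm, 1.0)  # recomputed from the map
})

test_that("generic dialect without a map preserves the stated cM length", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id_a\tid_b\tchr\tfrom\tto\tcm",
               "s1\ts2\t20\t1001\t5000\t3.21"), f)
  d <- ibd_dialect("generic",
                   column_map = list(sample1 = 1, sample2 = 2, chrom = 3,
                                     start_bp = 4, end_bp = 5, length_cm = 6),
                   has_header = TRUE)
  segs <- read_ibd_calls(f, d)
  expect_equal(segs$length_cm, 3.21)
  expect_true(is.na(segs$start_cm))
})

test_that("non-positive-length call records are skipped with a warning", {
  map <- uniform_map(1e7, chrom = "20")
  f <- withr::local_tempfile(fileext = ".ibd")
  rows <- sprintf("s1\t1\ts2\t1\t20\t%d\t%d\t0.5", (1:10) * 10000L + 1L,
                  (1:10) * 10000L + 5000L)
  rows[4] <- "s1\t1\ts2\t1\t20\t50001\t40000\t0.5"  # negative length
  writeLines(rows, f)
  expect_warning(segs <- read_ibd_calls(f, ibd_dialect("hapibd"), map),
                 "skipped 1 record")
  expect_equal(nrow(segs), 9)
})

test_that("truth TSV write/read is the identity on random segment sets", {
  withr::with_seed(3, {
    n <- 100
    s <- sort(runif(n, 0, 90))
    segs <- cm_seg(s, s + runif(n, 0.5, 9),
                   sample1 = sprintf("i%02d", sample(50, n, TRUE)),
                   sample2 = sprintf("j%02d", sample(50, n, TRUE)),
                   hap1 = sample(0:1, n, TRUE), hap2 = sample(0:1, n, TRUE))
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_ibd(segs, f)
  back <- read_truth_ibd(f)
  expect_equal(sort_segs(back), sort_segs(segs), tolerance = 1e-12)
})

test_that("empty and header-only truth files give empty segment sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_equal(nrow(read_truth_ibd(f)), 0)
  write_truth_ibd(ibd_segments(), f)  # header only
  expect_equal(nrow(read_truth_ibd(f)), 0)
})

test_that("silently truncated files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  segs <- cm_seg(c(1, 5), c(3, 9))
  write_truth_ibd(segs, f)
  txt <- readLines(f)
  txt[3] <- "A\t0\tB\t0\t1\t5000000"  # partial final record
  writeLines(txt, f)
  expect_error(read_truth_ibd(f), "truncated")
})

test_that("track files round trip through the text format", {
  tr <- gen_track(6, 2e5, 4e4, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, f)
  tr2 <- read_track(f)
  expect_equal(tr2$region_bp, tr$region_bp)
  expect_equal(sort_segs(tr2$runs[order(tr2$runs$sample1, tr2$runs$hap1,
                                        tr2$runs$sample2, tr2$runs$hap2,
                                        tr2$runs$start_bp), ])[
                 c("sample1", "start_bp", "end_bp", "label")],
               sort_segs(tr$runs[order(tr$runs$sample1, tr$runs$hap1,
                                       tr$runs$sample2, tr$runs$hap2,
                                       tr$runs$start_bp), ])[
                 c("sample1", "start_bp", "end_bp", "label")])
})

test_that("tskit tree sequences import as tracks with coherent truth", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # part of the supported toolchain
  ts_file <- withr::local_tempfile(fileext = ".trees")
  code <- sprintf(
    "import msprime; ts = msprime.sim_ancestry(samples=3, sequence_length=2e5, recombination_rate=1e-8, population_size=1000, random_seed=5); ts.dump('%s')",
    ts_file)
  status <- system2(py, c("-c", shQuote(code)), stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  tr <- read_tree_sequence(ts_file)
  expect_s3_class(tr, "local_tree_track")
  expect_equal(nrow(tr$haplotypes), 6)
  # MRCA labels are piecewise constant and defined everywhere
  pair <- tr$runs[1, c("sample1", "hap1", "sample2", "hap2")]
  labs <- mrca_labels(tr, pair, seq(0, tr$region_bp - 1, length.out = 50))
  expect_length(labs, 50)
  truth <- extract_truth_ibd(tr, uniform_map(tr$region_bp), min_length_cm = 0)
  expect_gt(nrow(truth), 0)
})
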
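#' Generate a synthetic local-tree track
#'
#' For every unordered cross-individual haplotype pair, MRCA-change
#' breakpoints are laid down as a Poisson process (exponential inter-break
#' distances with the given mean) and each run receives a fresh opaque label,
#' so adjacent runs always differ. A stand-in for coalescent tree sequences
#' with the same piecewise-constant structure; it makes no claim to realistic
#' IBD length distributions.
#'
#' @param n_haplotypes Even number of haplotypes (>= 4); haplotypes 2k-1, 2k
#'   form individual `ind<k>`.
#' @param region_bp Region length (track covers `[0, region_bp)`).
#' @param mean_segment_bp Mean distance between MRCA breakpoints.
#' @param seed Integer seed; same seed, same track.
#' @param chrom Chromosome label.
#' @param include_within Also enumerate the pair formed by one individual's
#'   own two haplotypes (default FALSE).
#' @return A `local_tree_track`.
#' @export
gen_track <- function(n_haplotypes, region_bp, mean_segment_bp, seed,
                      chrom = "1", include_within = FALSE) {
  if (n_haplotypes < 4 || n_haplotypes %% 2 != 0) {
    stop("n_haplotypes must be even and >= 4")
  }
  stopifnot(region_bp >= 2, mean_segment_bp > 0)
  n_ind <- n_haplotypes / 2L
  ids <- sprintf("ind%03d", seq_len(n_ind))
  hap_s <- rep(ids, each = 2L)
  hap_i <- rep(0:1, times = n_ind)
  pr <- utils::combn(n_haplotypes, 2L)
  if (!include_within) {
    pr <- pr[, hap_s[pr[1, ]] != hap_s[pr[2, ]], drop = FALSE]
  }
  runs <- withr::with_seed(seed, {
    lst <- vector("list", ncol(pr))
    batch <- max(8L, ceiling(region_bp / mean_segment_bp * 2) + 8L)
    for (p in seq_len(ncol(pr))) {
      bps <- cumsum(rexp(batch, rate = 1 / mean_segment_bp))
      while (bps[length(bps)] < region_bp) {
        bps <- c(bps, bps[length(bps)] +
                   cumsum(rexp(batch, rate = 1 / mean_segment_bp)))
      }
      bps <- floor(bps[bps < region_bp])
      bps <- unique(bps[bps > 0])
      starts <- c(0, bps)
      ends <- c(bps, region_bp)
      i <- pr[1, p]; j <- pr[2, p]
      lst[[p]] <- data.table(
        sample1 = hap_s[i], hap1 = hap_i[i],
        sample2 = hap_s[j], hap2 = hap_i[j],
        start_bp = starts, end_bp = ends,
        label = seq_along(starts)
      )
    }
    rbindlist(lst)
  })
  local_tree_track(as.data.frame(runs), region_bp = region_bp,
                   haplotypes = data.frame(sample_id = hap_s, hap_index = hap_i),
                   chrom = chrom)
}

#' Generate a synthetic phased haplotype panel
#'
#' Site minor-allele frequencies are drawn from `maf_sampler`; alleles are
#' independent Bernoulli draws per haplotype at each site (no linkage
#' structure — sufficient for exercising site filtering, downsampling and
#' error injection).
#'
#' @param n_haplotypes Even number of haplotypes.
#' @param n_sites Number of biallelic sites.
#' @param seed Integer seed.
#' @param maf_sampler Function n -> n target allele frequencies in (0, 1).
#' @param region_bp Positions are distinct uniform draws over `[1, region_bp]`.
#' @param chrom Chromosome label.
#' @return A `haplotype_panel`.
#' @export
gen_panel <- function(n_haplotypes, n_sites, seed,
                      maf_sampler = function(n) runif(n, 0.05, 0.5),
                      region_bp = max(10 * n_sites, 1e6), chrom = "1") {
  stopifnot(n_haplotypes >= 2, n_haplotypes %% 2 == 0, n_sites >= 1)
  withr::with_seed(seed, {
    pos <- sort(sample.int(region_bp, n_sites))
    maf <- maf_sampler(n_sites)
    A <- matrix(rbinom(n_sites * n_haplotypes, 1L, maf), nrow = n_sites)
    haplotype_panel(A, pos, sprintf("ind%03d", seq_len(n_haplotypes / 2L)),
                    chrom = chrom)
  })
}

#' Specify a truth/reported benchmark scenario
#'
#' @param n_pairs Number of haplotype pairs carrying truth segments.
#' @param segments_per_pair Candidate counts of truth segments per pair (one
#'   is sampled uniformly per pair).
#' @param min_length_cm,mean_length_cm Truth lengths are
#'   `min + Exponential(mean - min)` (cM).
#' @param boundary_jitter_cm SD of Gaussian noise added to each reported
#'   endpoint.
#' @param fragmentation_prob Probability a reported segment is split in two
#'   around its midpoint.
#' @param gap_cm Width of the gap removed at the split point.
#' @param false_positive_rate Expected number of spurious reported segments
#'   per truth segment (placed off-truth).
#' @param drop_rate Probability a truth segment goes entirely unreported.
#' @param seed Integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_pairs = 20, segments_per_pair = 1:3,
                          min_length_cm = 2, mean_length_cm = 5,
                          boundary_jitter_cm = 0, fragmentation_prob = 0,
                          gap_cm = 0, false_positive_rate = 0, drop_rate = 0,
                          seed = 1) {
  stopifnot(n_pairs >= 1, mean_length_cm > min_length_cm, min_length_cm > 0,
            boundary_jitter_cm >= 0, gap_cm >= 0,
            fragmentation_prob >= 0, fragmentation_prob <= 1,
            drop_rate >= 0, drop_rate <= 1, false_positive_rate >= 0)
  structure(as.list(environment()), class = "scenario_spec")
}

#' Generate a truth/reported scenario with known expected metrics
#'
#' Draws ground-truth segments per the spec, derives reported calls by
#' applying the pseudo-caller perturbations (drops, boundary jitter,
#' fragmentation, off-truth false positives), and computes the expected
#' [evaluate_binned()] report with the independent all-pairs oracle
#' ([oracle_metric_report()]) at generation time — the oracle never calls the
#' metrics engine, so engine-vs-oracle comparisons are non-circular.
#'
#' @param spec A [scenario_spec()].
#' @param map A `genetic_map` with strictly increasing cM.
#' @param cfg A [metric_config()] used for the expected report.
#' @return List `truth`, `reported` (both `ibd_segments`) and `expected` (a
#'   `metric_report`).
#' @export
gen_scenario <- function(spec, map = uniform_map(1e8, chrom = "1"),
                         cfg = metric_config()) {
  stopifnot(inherits(spec, "scenario_spec"))
  cm0 <- map$pos_cm[1]
  cm1 <- map$pos_cm[length(map$pos_cm)]
  withr::with_seed(spec$seed, {
    truth <- list()
    for (i in seq_len(spec$n_pairs)) {
      k <- if (length(spec$segments_per_pair) == 1) spec$segments_per_pair else
        sample(spec$segments_per_pair, 1)
      block <- (cm1 - cm0) / k
      for (b in seq_len(k)) {
        len <- spec$min_length_cm + rexp(1, 1 / (spec$mean_length_cm - spec$min_length_cm))
        len <- min(len, block * 0.9)
        s <- cm0 + (b - 1) * block + runif(1, 0, block - len)
        truth[[length(truth) + 1]] <- data.frame(
          sample1 = sprintf("A%04d", i), hap1 = 0L,
          sample2 = sprintf("B%04d", i), hap2 = 0L,
          start_cm = s, end_cm = s + len
        )
      }
    }
    truth <- do.call(rbind, truth)
    truth_segs <- .segments_from_cm(truth, map)
    reported_segs <- perturb_segments(
      truth_segs, map,
      boundary_jitter_cm = spec$boundary_jitter_cm,
      fragmentation_prob = spec$fragmentation_prob,
      gap_cm = spec$gap_cm,
      false_positive_rate = spec$false_positive_rate,
      drop_rate = spec$drop_rate,
      mean_length_cm = spec$mean_length_cm,
      min_length_cm = spec$min_length_cm
    )
    expected <- oracle_metric_report(truth_segs, reported_segs, cfg)
    list(truth = truth_segs, reported = reported_segs, expected = expected)
  })
}

# build an ibd_segments table from cM intervals by inverting the map;
# rounding keeps map round trips (bp -> cM -> bp) exact
.segments_from_cm <- function(df, map) {
  start_bp <- round(cm_to_bp(map, df$start_cm))
  end_bp <- round(cm_to_bp(map, df$end_cm))
  ibd_segments(df$sample1, df$hap1, df$sample2, df$hap2,
               chrom = map$chrom, start_bp = start_bp, end_bp = end_bp,
               start_cm = bp_to_cm(map, start_bp), end_cm = bp_to_cm(map, end_bp))
}

#' Pseudo-caller: perturb truth segments into reported calls
#'
#' Emulates the failure modes of real detectors: whole segments missed
#' (`drop_rate`), endpoints misplaced (`boundary_jitter_cm`), segments broken
#' into pieces with a gap (`fragmentation_prob`, `gap_cm`), and spurious
#' calls that overlap no truth segment of their pair
#' (`false_positive_rate`). Perturbation operates in genetic coordinates and
#' maps back to bp. Uses the ambient RNG state (seed it with
#' [withr::with_seed()] or an enclosing generator).
#'
#' @param truth An `ibd_segments` table.
#' @param map A `genetic_map` with strictly increasing cM.
#' @param boundary_jitter_cm,fragmentation_prob,gap_cm,false_positive_rate,drop_rate
#'   Perturbation intensities; see [scenario_spec()].
#' @param mean_length_cm,min_length_cm Length model for false positives.
#' @return An `ibd_segments` table of pseudo-calls.
#' @export
perturb_segments <- function(truth, map, boundary_jitter_cm = 0,
                             fragmentation_prob = 0, gap_cm = 0,
                             false_positive_rate = 0, drop_rate = 0,
                             mean_length_cm = 5, min_length_cm = 2) {
  cm0 <- map$pos_cm[1]
  cm1 <- map$pos_cm[length(map$pos_cm)]
  n <- nrow(truth)
  if (n == 0) return(ibd_segments())
  min_piece <- 0.05  # floor (cM) so jitter cannot invert an interval
  s <- truth$start_cm; e <- truth$end_cm
  keep <- if (drop_rate > 0) runif(n) >= drop_rate else rep(TRUE, n)
  frag <- if (fragmentation_prob > 0) {
    keep & runif(n) < fragmentation_prob & (e - s) > gap_cm + 2 * min_piece
  } else rep(FALSE, n)
  whole <- which(keep & !frag)
  fr <- which(frag)
  mid <- (s[fr] + e[fr]) / 2
  idx <- c(whole, fr, fr)
  ps <- c(s[whole], s[fr], mid + gap_cm / 2)
  pe <- c(e[whole], mid - gap_cm / 2, e[fr])
  a <- ps + rnorm(length(ps), 0, boundary_jitter_cm)
  b <- pe + rnorm(length(pe), 0, boundary_jitter_cm)
  a <- pmax(cm0, pmin(a, cm1 - min_piece))
  b <- pmax(a + min_piece, pmin(b, cm1))

  n_fp <- if (false_positive_rate > 0) {
    rbinom(1, n, min(1, false_positive_rate))
  } else 0L
  if (n_fp > 0) {
    keys <- .pair_keys(truth)
    tr_by_key <- split(seq_len(n), keys)
    fp_i <- sample.int(n, n_fp, replace = TRUE)
    fp_len <- min_length_cm + rexp(n_fp, 1 / (mean_length_cm - min_length_cm))
    fp_len <- pmin(fp_len, (cm1 - cm0) / 4)
    for (f in seq_len(n_fp)) {
      i <- fp_i[f]
      tr <- tr_by_key[[keys[i]]]
      for (try in 1:20) {
        fa <- runif(1, cm0, cm1 - fp_len[f])
        fb <- fa + fp_len[f]
        if (all(fb <= s[tr] | fa >= e[tr])) {
          idx <- c(idx, i); a <- c(a, fa); b <- c(b, fb)
          break
        }
      }
    }
  }
  if (length(idx) == 0) return(ibd_segments())
  .segments_from_cm(data.frame(
    sample1 = truth$sample1[idx], hap1 = truth$hap1[idx],
    sample2 = truth$sample2[idx], hap2 = truth$hap2[idx],
    start_cm = a, end_cm = b
  ), map)
}

# ---- independent metric oracle ---------------------------------------------

#' Naive all-pairs metric reference
#'
#' An independent re-implementation of the six metrics using explicit loops
#' over every (subject, candidate) segment pair — no indexing, no shared code
#' with [evaluate_binned()]. Used to validate the metrics engine and to
#' stamp expected values onto generated scenarios. Quadratic; small inputs
#' only.
#'
#' @inheritParams evaluate_binned
#' @return A `metric_report` data frame with the same layout as
#'   [evaluate_binned()].
#' @export
oracle_metric_report <- function(truth_full, reported_full,
                                 cfg = metric_config(),
                                 reference = c("full", "bin")) {
  reference <- match.arg(reference)
  truth_full <- as.data.frame(truth_full)
  reported_full <- as.data.frame(reported_full)

  seg_key <- function(df) paste(df$chrom, .pair_keys(df, cfg$pair_mode), sep = "\036")

  # one subject (scalars) against candidate vectors: best single overlap
  best_of <- function(k, s, e, len, ck, cs, ce, clen) {
    best_ov <- 0; best_len <- NA_real_; best_tie <- Inf; best_start <- Inf
    for (j in seq_along(ck)) {
      if (ck[j] != k) next
      o <- min(e, ce[j]) - max(s, cs[j])
      if (o <= 0) next
      tie <- abs(clen[j] - len)
      if (o > best_ov ||
          (o == best_ov && (tie < best_tie ||
                            (tie == best_tie && cs[j] < best_start)))) {
        best_ov <- o; best_len <- clen[j]
        best_tie <- tie; best_start <- cs[j]
      }
    }
    list(ov = best_ov, len = best_len)
  }

  union_cover <- function(k, s, e, ck, cs, ce) {
    lo <- c(); hi <- c()
    for (j in seq_along(ck)) {
      if (ck[j] != k) next
      a <- max(s, cs[j]); b <- min(e, ce[j])
      if (b > a) { lo <- c(lo, a); hi <- c(hi, b) }
    }
    if (length(lo) == 0) return(0)
    o <- order(lo); lo <- lo[o]; hi <- hi[o]
    tot <- 0; cl <- lo[1]; ch <- hi[1]
    if (length(lo) > 1) for (t in 2:length(lo)) {
      if (lo[t] <= ch) ch <- max(ch, hi[t])
      else { tot <- tot + (ch - cl); cl <- lo[t]; ch <- hi[t] }
    }
    tot + (ch - cl)
  }

  rep_side <- function(rep_set, truth_ref) {
    n <- nrow(rep_set)
    if (n == 0) return(list(accuracy = NA_real_, length_accuracy = NA_real_,
                            length_discrepancy_cm = NA_real_, n_reported = 0L))
    sk <- seg_key(rep_set); ck <- seg_key(truth_ref)
    cs <- truth_ref$start_cm; ce <- truth_ref$end_cm; clen <- truth_ref$length_cm
    cov <- logical(n); frac <- numeric(n); dd <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      li <- rep_set$length_cm[i]
      b <- best_of(sk[i], rep_set$start_cm[i], rep_set$end_cm[i], li,
                   ck, cs, ce, clen)
      cov[i] <- b$ov >= cfg$coverage_threshold * li
      frac[i] <- if (li > 0) b$ov / li else 1
      if (b$ov > 0) dd[i] <- abs(li - b$len)
      else if (cfg$penalize_unmatched_discrepancy) dd[i] <- li
    }
    la <- if (cfg$length_accuracy_matched_only) {
      if (any(frac > 0)) mean(frac[frac > 0]) else NA_real_
    } else mean(frac)
    disc <- if (all(is.na(dd))) NA_real_ else sqrt(mean(dd[!is.na(dd)]^2))
    list(accuracy = mean(cov), length_accuracy = la,
         length_discrepancy_cm = disc, n_reported = n)
  }

  truth_side <- function(truth_set, rep_ref) {
    n <- nrow(truth_set)
    if (n == 0) return(list(recall = NA_real_, power = NA_real_,
                            accumulative_power = NA_real_, n_truth = 0L))
    sk <- seg_key(truth_set); ck <- seg_key(rep_ref)
    cs <- rep_ref$start_cm; ce <- rep_ref$end_cm; clen <- rep_ref$length_cm
    cov <- logical(n); frac <- numeric(n); ufrac <- numeric(n)
    for (i in seq_len(n)) {
      li <- truth_set$length_cm[i]
      s <- truth_set$start_cm[i]; e <- truth_set$end_cm[i]
      b <- best_of(sk[i], s, e, li, ck, cs, ce, clen)
      cov[i] <- b$ov >= cfg$coverage_threshold * li
      frac[i] <- if (li > 0) b$ov / li else 1
      ufrac[i] <- if (li > 0) union_cover(sk[i], s, e, ck, cs, ce) / li else 1
    }
    list(recall = mean(cov), power = mean(frac),
         accumulative_power = mean(ufrac), n_truth = n)
  }

  in_bin <- function(df, b) df[df$length_cm >= b[1] & df$length_cm < b[2], , drop = FALSE]

  mk_row <- function(lbl, rs, ts) {
    data.frame(bin = lbl, n_reported = rs$n_reported, n_truth = ts$n_truth,
               accuracy = rs$accuracy, length_accuracy = rs$length_accuracy,
               length_discrepancy_cm = rs$length_discrepancy_cm,
               recall = ts$recall, power = ts$power,
               accumulative_power = ts$accumulative_power,
               stringsAsFactors = FALSE)
  }

  rows <- list(mk_row("all", rep_side(reported_full, truth_full),
                      truth_side(truth_full, reported_full)))
  for (b in cfg$bins) {
    rb <- in_bin(reported_full, b)
    tb <- in_bin(truth_full, b)
    if (reference == "full") {
      rows[[length(rows) + 1]] <- mk_row(.bin_label(b),
                                         rep_side(rb, truth_full),
                                         truth_side(tb, reported_full))
    } else {
      rows[[length(rows) + 1]] <- mk_row(.bin_label(b),
                                         rep_side(rb, tb), truth_side(tb, rb))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}
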
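#' Construct a local-tree track
#'
#' A piecewise-constant representation of pairwise genealogy along one
#' chromosome: for every unordered haplotype pair, a run-length encoding of
#' the label of the pair's most recent common ancestor (MRCA) over half-open
#' bp intervals that partition `[0, region_bp)`. MRCA labels are opaque
#' integers compared only for equality within one track.
#'
#' @param runs Data frame with columns `sample1, hap1, sample2, hap2,
#'   start_bp, end_bp, label`; for each pair the intervals must partition the
#'   region.
#' @param region_bp Region length L; the track covers `[0, L)`.
#' @param haplotypes Data frame `(sample_id, hap_index)` listing the sample
#'   haplotypes (derived from `runs` when omitted).
#' @param chrom Chromosome label.
#' @return An object of class `local_tree_track`.
#' @export
local_tree_track <- function(runs, region_bp, haplotypes = NULL, chrom = "1") {
  runs <- as.data.frame(runs)
  need <- c("sample1", "hap1", "sample2", "hap2", "start_bp", "end_bp", "label")
  if (!all(need %in% names(runs))) {
    stop("runs must have columns ", paste(need, collapse = ", "))
  }
  runs <- canonicalize_pairs(runs)
  dt <- as.data.table(runs)
  setorder(dt, sample1, hap1, sample2, hap2, start_bp)
  chk <- dt[, {
    ok <- start_bp[1] == 0 && end_bp[.N] == region_bp &&
      (.N == 1 || all(abs(start_bp[-1] - end_bp[-.N]) < 1e-9))
    .(ok = ok)
  }, by = .(sample1, hap1, sample2, hap2)]
  if (!all(chk$ok)) {
    stop("per-pair intervals must partition [0, region_bp)")
  }
  if (is.null(haplotypes)) {
    h <- unique(rbind(
      data.frame(sample_id = dt$sample1, hap_index = dt$hap1),
      data.frame(sample_id = dt$sample2, hap_index = dt$hap2)
    ))
    haplotypes <- h[order(h$sample_id, h$hap_index), , drop = FALSE]
    rownames(haplotypes) <- NULL
  }
  structure(
    list(chrom = as.character(chrom), region_bp = as.numeric(region_bp),
         runs = as.data.frame(dt), haplotypes = haplotypes),
    class = "local_tree_track"
  )
}

#' @export
print.local_tree_track <- function(x, ...) {
  cat(sprintf("<local_tree_track> chrom %s: [0, %.0f) bp, %d haplotypes, %d pairs, %d runs\n",
              x$chrom, x$region_bp, nrow(x$haplotypes),
              length(unique(.pair_keys(x$runs))), nrow(x$runs)))
  invisible(x)
}

#' MRCA labels for one pair at given positions
#'
#' @param track A `local_tree_track`.
#' @param pair List or data frame row with `sample1, hap1, sample2, hap2`.
#' @param positions Sorted bp positions within `[0, region_bp)`.
#' @return Integer vector of MRCA labels, one per position.
#' @export
mrca_labels <- function(track, pair, positions) {
  if (any(positions < 0 | positions >= track$region_bp)) {
    stop("positions must lie within [0, region_bp)")
  }
  p <- canonicalize_pairs(as.data.frame(pair))
  key <- .pair_keys(p)
  runs <- track$runs
  sel <- .pair_keys(runs) == key
  if (!any(sel)) stop("pair not present in track")
  r <- runs[sel, , drop = FALSE]
  r <- r[order(r$start_bp), , drop = FALSE]
  r$label[findInterval(positions, r$start_bp)]
}

#' Extract ground-truth IBD segments from a local-tree track
#'
#' For every unordered haplotype pair, MRCA labels are read at sampled
#' positions `0, step, 2*step, ...` along the region; maximal runs of an
#' identical label become candidate segments. A segment starts at the first
#' sampled position of its run and ends at the first sampled position after
#' the run (the region end for the terminal run, so the final segment is not
#' truncated by up to one step). Candidates shorter than `min_length_cm` on
#' the supplied map are dropped.
#'
#' With `exact_breakpoints = TRUE` the tree breakpoints themselves are used
#' instead of the sampling grid; the default discretized mode reflects how
#' coalescent truth tracks are typically sampled.
#'
#' @param track A `local_tree_track`.
#' @param map A `genetic_map` covering the region.
#' @param sample_step_bp Sampling step in bp (default 5000).
#' @param min_length_cm Minimum genetic length to keep (default 1 cM).
#' @param exact_breakpoints Use exact run boundaries instead of the grid.
#' @return An `ibd_segments` table sorted by pair then start.
#' @export
extract_truth_ibd <- function(track, map, sample_step_bp = 5000,
                              min_length_cm = 1.0, exact_breakpoints = FALSE) {
  stopifnot(sample_step_bp >= 1, min_length_cm >= 0)
  runs <- as.data.table(track$runs)
  if (nrow(runs) == 0) return(ibd_segments())
  L <- track$region_bp
  setorder(runs, sample1, hap1, sample2, hap2, start_bp)
  if (exact_breakpoints) {
    segs <- runs[, .(sample1, hap1, sample2, hap2, start_bp, end_bp)]
  } else {
    grid <- seq(0, L - 0.5, by = sample_step_bp)
    segs <- runs[, {
      labs <- label[findInterval(grid, start_bp)]
      r <- rle(labs)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      .(start_bp = grid[starts_i],
        end_bp = c(grid[ends_i[-length(ends_i)] + 1L], L))
    }, by = .(sample1, hap1, sample2, hap2)]
  }
  segs[, `:=`(start_cm = bp_to_cm(map, start_bp),
              end_cm = bp_to_cm(map, end_bp))]
  segs <- segs[end_cm - start_cm >= min_length_cm]
  segs[, chrom := track$chrom]
  setorder(segs, sample1, hap1, sample2, hap2, start_bp)
  out <- as.data.frame(segs[, .(sample1, hap1, sample2, hap2, chrom,
                                start_bp, end_bp, start_cm, end_cm)])
  .as_ibd_segments(out)
}

#' Brute-force reference for truth extraction
#'
#' Independent implementation of [extract_truth_ibd()]: for each pair it
#' scans every sampled position one at a time, looks the MRCA label up by a
#' linear search over the pair's intervals, and accumulates runs with an
#' explicit loop. Intended for validation on small tracks only.
#'
#' @inheritParams extract_truth_ibd
#' @return An `ibd_segments` table.
#' @export
extract_truth_ibd_oracle <- function(track, map, sample_step_bp = 5000,
                                     min_length_cm = 1.0) {
  runs <- canonicalize_pairs(as.data.frame(track$runs))
  if (nrow(runs) == 0) return(ibd_segments())
  L <- track$region_bp
  keys <- .pair_keys(runs)
  out <- list()
  for (k in unique(keys)) {
    r <- runs[keys == k, , drop = FALSE]
    r <- r[order(r$start_bp), , drop = FALSE]
    pos <- 0
    labs <- c()
    grid <- c()
    while (pos < L) {
      hit <- which(pos >= r$start_bp & pos < r$end_bp)
      labs <- c(labs, r$label[hit[1]])
      grid <- c(grid, pos)
      pos <- pos + sample_step_bp
    }
    run_start <- 1
    i <- 2
    repeat {
      if (i > length(labs) || labs[i] != labs[run_start]) {
        s_bp <- grid[run_start]
        e_bp <- if (i > length(labs)) L else grid[i]
        s_cm <- bp_to_cm(map, s_bp)
        e_cm <- bp_to_cm(map, e_bp)
        if (e_cm - s_cm >= min_length_cm) {
          out[[length(out) + 1]] <- data.frame(
            sample1 = r$sample1[1], hap1 = r$hap1[1],
            sample2 = r$sample2[1], hap2 = r$hap2[1],
            chrom = track$chrom, start_bp = s_bp, end_bp = e_bp,
            start_cm = s_cm, end_cm = e_cm
          )
        }
        if (i > length(labs)) break
        run_start <- i
      }
      i <- i + 1
    }
  }
  if (length(out) == 0) return(ibd_segments())
  df <- do.call(rbind, out)
  df <- df[order(df$sample1, df$hap1, df$sample2, df$hap2, df$start_bp), ]
  rownames(df) <- NULL
  .as_ibd_segments(df)
}
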
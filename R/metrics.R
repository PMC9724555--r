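#' Best-matching segment for one subject
#'
#' Among candidates sharing the subject's pair (under the configured pair
#' mode), the best match is the one with the longest genetic overlap. Ties on
#' overlap break toward the candidate with the smaller absolute length
#' difference, then the earlier start; ties affect only length discrepancy,
#' never accuracy or power. The subject is covered when the best single
#' overlap reaches `coverage_threshold` times the subject's own length.
#'
#' @param subject A single-row `ibd_segments` table.
#' @param candidates An `ibd_segments` table of potential matches.
#' @param cfg A [metric_config()].
#' @return List with `best` (single-row table or NULL), `best_overlap_cm` and
#'   `covered`.
#' @export
best_match <- function(subject, candidates, cfg = metric_config()) {
  subject <- as.data.frame(subject)
  stopifnot(nrow(subject) == 1)
  m <- .match_table(subject, candidates, cfg)
  best <- if (is.na(m$best_row[1])) NULL else
    .as_ibd_segments(as.data.frame(candidates)[m$best_row[1], , drop = FALSE])
  list(best = best, best_overlap_cm = m$best_overlap[1], covered = m$covered[1])
}

# Vectorised best-match: for each subject row, the same-key candidate with
# maximal overlap (ties: smaller |length difference|, then earlier start).
# Returns data.frame(best_overlap, best_len, best_row, covered, union_overlap)
# aligned with subjects. union_overlap is the length of the union of ALL
# positively-overlapping same-key candidates intersected with the subject.
.match_table <- function(subjects, candidates, cfg, want_union = FALSE) {
  ns <- nrow(subjects)
  res <- data.frame(best_overlap = numeric(ns), best_len = rep(NA_real_, ns),
                    best_row = rep(NA_integer_, ns), covered = logical(ns),
                    union_overlap = numeric(ns))
  if (ns == 0 || nrow(candidates) == 0) {
    res$covered <- res$best_overlap >= cfg$coverage_threshold * subjects$length_cm
    return(res)
  }
  sub <- data.table(
    key_ = paste(subjects$chrom, .pair_keys(subjects, cfg$pair_mode), sep = "\036"),
    s_idx = seq_len(ns),
    s_start = subjects$start_cm, s_end = subjects$end_cm,
    s_len = subjects$length_cm
  )
  cand <- data.table(
    key_ = paste(candidates$chrom, .pair_keys(candidates, cfg$pair_mode), sep = "\036"),
    c_row = seq_len(nrow(candidates)),
    c_start = candidates$start_cm, c_end = candidates$end_cm,
    c_len = candidates$length_cm
  )
  j <- cand[sub, on = "key_", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(j) > 0) {
    j[, ov := pmax(0, pmin(s_end, c_end) - pmax(s_start, c_start))]
    j <- j[ov > 0]
  }
  if (nrow(j) > 0) {
    j[, tie := abs(c_len - s_len)]
    setorder(j, s_idx, -ov, tie, c_start)
    best <- j[, .SD[1L], by = s_idx]
    res$best_overlap[best$s_idx] <- best$ov
    res$best_len[best$s_idx] <- best$c_len
    res$best_row[best$s_idx] <- best$c_row
    if (want_union) {
      u <- j[, {
        lo <- pmax(c_start, s_start[1])
        hi <- pmin(c_end, s_end[1])
        o <- order(lo)
        lo <- lo[o]; hi <- hi[o]
        tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
        if (length(lo) > 1) for (t in 2:length(lo)) {
          if (lo[t] <= cur_hi) cur_hi <- max(cur_hi, hi[t])
          else { tot <- tot + (cur_hi - cur_lo); cur_lo <- lo[t]; cur_hi <- hi[t] }
        }
        .(uo = tot + (cur_hi - cur_lo))
      }, by = s_idx]
      res$union_overlap[u$s_idx] <- u$uo
    }
  }
  res$covered <- res$best_overlap >= cfg$coverage_threshold * subjects$length_cm
  res
}

#' Score reported segments against the full truth set
#'
#' Three reported-side metrics:
#' * **accuracy** — fraction of reported segments whose single best-matching
#'   truth segment covers at least `coverage_threshold` of their length
#'   (so `1 - accuracy` is the false-positive fraction);
#' * **length accuracy** — mean over reported segments of the fraction of
#'   each segment covered by its best-matching truth segment (unmatched
#'   segments contribute 0 unless `length_accuracy_matched_only`);
#' * **length discrepancy** — root-mean-square of the absolute length
#'   difference between each matched reported segment and its best-matching
#'   truth segment, in cM.
#'
#' @param reported An `ibd_segments` table of reported calls.
#' @param truth_full The FULL ground-truth set (not a length bin).
#' @param cfg A [metric_config()].
#' @return List: `accuracy`, `length_accuracy`, `length_discrepancy_cm`
#'   (NA when the corresponding denominator is empty), `n_reported`.
#' @export
evaluate_reported <- function(reported, truth_full, cfg = metric_config()) {
  n <- nrow(reported)
  if (n == 0) {
    return(list(accuracy = NA_real_, length_accuracy = NA_real_,
                length_discrepancy_cm = NA_real_, n_reported = 0L))
  }
  m <- .match_table(reported, truth_full, cfg)
  .reported_metrics(reported, m, cfg)
}

# aggregate reported-side metrics from a precomputed match table
.reported_metrics <- function(reported, m, cfg) {
  n <- nrow(reported)
  if (n == 0) {
    return(list(accuracy = NA_real_, length_accuracy = NA_real_,
                length_discrepancy_cm = NA_real_, n_reported = 0L))
  }
  frac <- ifelse(reported$length_cm > 0, m$best_overlap / reported$length_cm, 1)
  matched <- m$best_overlap > 0
  la <- if (cfg$length_accuracy_matched_only) {
    if (any(matched)) mean(frac[matched]) else NA_real_
  } else mean(frac)
  d <- abs(reported$length_cm - m$best_len)
  if (cfg$penalize_unmatched_discrepancy) {
    d[!matched] <- reported$length_cm[!matched]
    disc <- sqrt(mean(d^2))
  } else {
    disc <- if (any(matched)) sqrt(mean(d[matched]^2)) else NA_real_
  }
  list(accuracy = mean(m$covered), length_accuracy = la,
       length_discrepancy_cm = disc, n_reported = n)
}

#' Score truth segments against the full reported set
#'
#' Three truth-side metrics:
#' * **recall** — fraction of truth segments covered at least
#'   `coverage_threshold` of their length by a single best-matching reported
#'   segment;
#' * **power** — mean over truth segments of the fraction covered by the best
#'   single reported segment;
#' * **accumulative power** — as power, but crediting the union of all
#'   overlapping reported segments (overlaps merged so shared coverage is not
#'   double-counted).
#'
#' @param truth An `ibd_segments` table of ground-truth segments.
#' @param reported_full The FULL reported set (not a length bin).
#' @param cfg A [metric_config()].
#' @return List: `recall`, `power`, `accumulative_power` (NA when `truth` is
#'   empty), `n_truth`.
#' @export
evaluate_truth <- function(truth, reported_full, cfg = metric_config()) {
  n <- nrow(truth)
  if (n == 0) {
    return(list(recall = NA_real_, power = NA_real_,
                accumulative_power = NA_real_, n_truth = 0L))
  }
  m <- .match_table(truth, reported_full, cfg, want_union = TRUE)
  .truth_metrics(truth, m, cfg)
}

# aggregate truth-side metrics from a precomputed match table (with unions)
.truth_metrics <- function(truth, m, cfg) {
  n <- nrow(truth)
  if (n == 0) {
    return(list(recall = NA_real_, power = NA_real_,
                accumulative_power = NA_real_, n_truth = 0L))
  }
  frac <- ifelse(truth$length_cm > 0, m$best_overlap / truth$length_cm, 1)
  ufrac <- ifelse(truth$length_cm > 0, m$union_overlap / truth$length_cm, 1)
  list(recall = mean(m$covered), power = mean(frac),
       accumulative_power = mean(ufrac), n_truth = n)
}

#' Assign segments to genetic-length bins
#'
#' A segment of length l (cM) goes to the half-open bin `[e_i, e_{i+1})`
#' containing l; the final bin is open-ended; segments shorter than the first
#' edge are excluded.
#'
#' @param segments An `ibd_segments` table.
#' @param edges Strictly increasing bin edges in cM.
#' @return Named list of `ibd_segments` tables, one per bin.
#' @export
bin_segments <- function(segments, edges = c(2, 3, 4, 5, 6, 7)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  lo <- edges
  hi <- c(edges[-1], Inf)
  bins <- Map(c, lo, hi)
  out <- lapply(bins, function(b) {
    .as_ibd_segments(segments[segments$length_cm >= b[1] &
                                segments$length_cm < b[2], , drop = FALSE])
  })
  names(out) <- vapply(bins, .bin_label, character(1))
  out
}

#' Length-stratified metric report
#'
#' Computes the six metrics per length bin and overall. Each bin of reported
#' segments is scored against the FULL truth set, and each bin of truth
#' segments against the FULL reported set (`reference = "full"`), so a call
#' whose length falls just across a bin edge from its true counterpart is
#' still credited. `reference = "bin"` forces the rejected per-bin-reference
#' scheme (each bin scored only against the same bin of the other set), kept
#' for comparison.
#'
#' @param truth_full An `ibd_segments` table of ground truth.
#' @param reported_full An `ibd_segments` table of reported calls.
#' @param cfg A [metric_config()].
#' @param reference `"full"` (default) or `"bin"`.
#' @return A data frame of class `metric_report`: one row per bin plus an
#'   `"all"` row, with columns `bin, n_reported, n_truth, accuracy,
#'   length_accuracy, length_discrepancy_cm, recall, power,
#'   accumulative_power`.
#' @export
evaluate_binned <- function(truth_full, reported_full, cfg = metric_config(),
                            reference = c("full", "bin")) {
  reference <- match.arg(reference)
  pick <- function(segs, b) {
    .as_ibd_segments(segs[segs$length_cm >= b[1] & segs$length_cm < b[2], ,
                          drop = FALSE])
  }
  mk_row <- function(lbl, er, et) {
    data.frame(bin = lbl, n_reported = er$n_reported, n_truth = et$n_truth,
               accuracy = er$accuracy, length_accuracy = er$length_accuracy,
               length_discrepancy_cm = er$length_discrepancy_cm,
               recall = et$recall, power = et$power,
               accumulative_power = et$accumulative_power,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (reference == "full") {
    # each bin is scored against the FULL reference, so the per-segment
    # best-match tables need computing only once
    mr <- .match_table(reported_full, truth_full, cfg)
    mt <- .match_table(truth_full, reported_full, cfg, want_union = TRUE)
    rows[[1]] <- mk_row("all",
                        .reported_metrics(reported_full, mr, cfg),
                        .truth_metrics(truth_full, mt, cfg))
    for (b in cfg$bins) {
      ri <- reported_full$length_cm >= b[1] & reported_full$length_cm < b[2]
      ti <- truth_full$length_cm >= b[1] & truth_full$length_cm < b[2]
      rows[[length(rows) + 1]] <- mk_row(
        .bin_label(b),
        .reported_metrics(reported_full[ri, , drop = FALSE],
                          mr[ri, , drop = FALSE], cfg),
        .truth_metrics(truth_full[ti, , drop = FALSE],
                       mt[ti, , drop = FALSE], cfg))
    }
  } else {
    rows[[1]] <- mk_row("all",
                        evaluate_reported(reported_full, truth_full, cfg),
                        evaluate_truth(truth_full, reported_full, cfg))
    for (b in cfg$bins) {
      rb <- pick(reported_full, b)
      tb <- pick(truth_full, b)
      rows[[length(rows) + 1]] <- mk_row(.bin_label(b),
                                         evaluate_reported(rb, tb, cfg),
                                         evaluate_truth(tb, rb, cfg))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write a metric report to TSV or JSON
#'
#' @param report A `metric_report`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"` (guessed from the extension by default).
#' @return The path, invisibly.
#' @export
write_metric_report <- function(report, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         na = "null", digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.table(as.data.frame(report), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
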
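#' Read a phased haplotype panel from VCF
#'
#' Reads a (plain or gzipped) VCF 4.x file into a [haplotype_panel()]. One
#' column per haplotype in file order; alleles coded 0/1 for biallelic sites
#' and higher integers for multiallelic records (filter those downstream with
#' [filter_sites()]).
#'
#' @param path VCF file.
#' @param phased_required Error on any unphased ("/"-separated) genotype
#'   (default TRUE); the detectors being benchmarked consume phased panels.
#' @return A `haplotype_panel`.
#' @export
read_vcf <- function(path, phased_required = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_sites <- nrow(v@gt)
  samples <- colnames(v@gt)[-1]
  if (n_sites == 0) {
    return(haplotype_panel(matrix(integer(0), 0, 2 * length(samples)),
                           numeric(0), samples, chrom = "1"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_sites)
  unph <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (phased_required && any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at site %s:%s, sample %s",
                 fix[w[1], "CHROM"], fix[w[1], "POS"], samples[w[2]]))
  }
  parts <- strsplit(as.vector(gt), "[|/]")
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed GT '%s' at record %d", as.vector(gt)[i],
                 (i - 1L) %% n_sites + 1L))
  }
  al <- suppressWarnings(as.integer(unlist(parts)))
  if (anyNA(al)) stop("non-numeric allele in GT field")
  # unlist order: site-major within sample; interleave into hap columns
  a1 <- matrix(al[seq(1, length(al), by = 2)], nrow = n_sites)
  a2 <- matrix(al[seq(2, length(al), by = 2)], nrow = n_sites)
  allele <- matrix(0L, n_sites, 2 * length(samples))
  allele[, seq(1, ncol(allele), by = 2)] <- a1
  allele[, seq(2, ncol(allele), by = 2)] <- a2
  haplotype_panel(allele, as.numeric(fix[, "POS"]), samples,
                  chrom = fix[1, "CHROM"], ref = fix[, "REF"],
                  alt = fix[, "ALT"])
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits plain-text VCF 4.2 with phased (`|`-separated) GT fields, positions
#' sorted, one record per site.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(panel, path) {
  if (anyDuplicated(panel$pos_bp)) stop("duplicate site positions")
  samples <- unique(panel$haplotypes$sample_id)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  n <- nrow(panel$alleles)
  lines <- hdr
  if (n > 0) {
    A <- panel$alleles
    gt_cols <- vapply(seq_along(samples), function(k) {
      paste(A[, 2 * k - 1], A[, 2 * k], sep = "|")
    }, character(n))
    if (n == 1) gt_cols <- matrix(gt_cols, nrow = 1)
    body <- paste(
      panel$chrom, format(panel$pos_bp, scientific = FALSE, trim = TRUE),
      ".", panel$ref, panel$alt, ".", "PASS", ".", "GT",
      apply(gt_cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genetic map file
#'
#' Two dialects: `plink` (four whitespace-separated columns `chrom, id, cM,
#' bp`, no header) and `hapmap` (header line then `chrom, pos, rate, cM`
#' columns).
#'
#' @param path Map file.
#' @param dialect `"plink"` or `"hapmap"`.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, dialect = c("plink", "hapmap")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "plink") {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("PLINK map needs 4 columns (chrom, id, cM, bp)")
    chrom <- df[[1]][1]; cm <- as.numeric(df[[3]]); bp <- as.numeric(df[[4]])
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("HapMap map needs 4 columns (chrom, pos, rate, cM)")
    chrom <- df[[1]][1]; bp <- as.numeric(df[[2]]); cm <- as.numeric(df[[4]])
  }
  o <- order(bp)
  bp <- bp[o]; cm <- cm[o]
  if (any(diff(cm) < 0)) {
    bad <- which(diff(cm) < 0)[1] + 1L
    stop(sprintf("cM decreases at line %d of %s", bad, path))
  }
  genetic_map(bp, cm, chrom = sub("^chr", "", as.character(chrom)))
}

#' Describe an IBD call-file dialect
#'
#' `hapibd` is the hap-IBD output layout (8 tab-separated columns: sample1,
#' hap1 in 1/2, sample2, hap2, chromosome, 1-based inclusive start and end
#' bp, cM length; no header). `generic` takes an explicit `column_map` from
#' logical fields to column indices for any other detector.
#'
#' @param name `"hapibd"` or `"generic"`.
#' @param column_map Named list mapping `sample1, hap1, sample2, hap2, chrom,
#'   start_bp, end_bp, length_cm` (hap and length entries optional) to column
#'   indices. Required for `generic`.
#' @param has_header Does the file start with a header line?
#' @param sep Field separator.
#' @param hap_base Value of the first haplotype index in the file (1 for
#'   hap-IBD's 1/2 coding, 0 for 0/1 coding).
#' @param coords One-based inclusive (`"1-inclusive"`, the common
#'   VCF-derived convention, default) or already half-open zero-based
#'   (`"0-half-open"`).
#' @return An object of class `ibd_dialect`.
#' @export
ibd_dialect <- function(name = c("hapibd", "generic"), column_map = NULL,
                        has_header = FALSE, sep = "\t", hap_base = NULL,
                        coords = c("1-inclusive", "0-half-open")) {
  name <- match.arg(name)
  coords <- match.arg(coords)
  if (name == "hapibd") {
    if (is.null(column_map)) {
      column_map <- list(sample1 = 1, hap1 = 2, sample2 = 3, hap2 = 4,
                         chrom = 5, start_bp = 6, end_bp = 7, length_cm = 8)
    }
    if (is.null(hap_base)) hap_base <- 1L
  } else {
    if (is.null(column_map)) stop("generic dialect requires a column_map")
    if (is.null(hap_base)) hap_base <- 0L
  }
  need <- c("sample1", "sample2", "chrom", "start_bp", "end_bp")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name at least ", paste(need, collapse = ", "))
  }
  structure(list(name = name, column_map = column_map,
                 has_header = has_header, sep = sep,
                 hap_base = as.integer(hap_base), coords = coords),
            class = "ibd_dialect")
}

#' Read detector-reported IBD calls
#'
#' Parses a detector output file under a dialect into an `ibd_segments`
#' table. Physical coordinates are converted to the internal half-open
#' 0-based convention. When a `map` is given, genetic coordinates are
#' recomputed from it — every tool in a benchmark must be scored against one
#' map — and, if the file carries its own cM length, rows differing from the
#' recomputed length by more than 0.01 cM are counted and reported in a
#' message. Without a map the file's `length_cm` column is preserved exactly
#' and start/end cM are left NA. Rows with non-positive bp length are skipped
#' with a warning giving the count.
#'
#' Files lacking haplotype columns can only be used with
#' `pair_mode = "individual"` metrics; such rows get hap indices 0/0.
#'
#' @param path Call file.
#' @param dialect An [ibd_dialect()].
#' @param map Optional `genetic_map`.
#' @return An `ibd_segments` table.
#' @export
read_ibd_calls <- function(path, dialect = ibd_dialect("hapibd"), map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .read_tsv_checked(path, header = dialect$has_header, sep = dialect$sep)
  cm_map <- dialect$column_map
  if (nrow(df) == 0) return(ibd_segments())
  if (ncol(df) < max(unlist(cm_map))) {
    stop(sprintf("file has %d columns but dialect needs %d",
                 ncol(df), max(unlist(cm_map))))
  }
  col <- function(f) if (!is.null(cm_map[[f]])) df[[cm_map[[f]]]] else NULL
  hap1 <- col("hap1"); hap2 <- col("hap2")
  if (is.null(hap1)) hap1 <- rep(dialect$hap_base, nrow(df))
  if (is.null(hap2)) hap2 <- rep(dialect$hap_base, nrow(df))
  start_bp <- as.numeric(col("start_bp"))
  end_bp <- as.numeric(col("end_bp"))
  if (dialect$coords == "1-inclusive") start_bp <- start_bp - 1
  len_file <- if (!is.null(cm_map$length_cm)) as.numeric(col("length_cm")) else NULL
  keep <- end_bp > start_bp
  if (any(!keep)) {
    warning(sprintf("skipped %d record(s) with non-positive length", sum(!keep)))
  }
  segs <- ibd_segments(
    sample1 = as.character(col("sample1"))[keep],
    hap1 = as.integer(hap1)[keep] - dialect$hap_base,
    sample2 = as.character(col("sample2"))[keep],
    hap2 = as.integer(hap2)[keep] - dialect$hap_base,
    chrom = as.character(col("chrom"))[keep],
    start_bp = start_bp[keep], end_bp = end_bp[keep],
    length_cm = if (is.null(len_file)) NULL else len_file[keep]
  )
  if (!is.null(map)) {
    old_len <- segs$length_cm
    segs <- add_genetic_coords(segs, map)
    if (!is.null(len_file)) {
      ndiff <- sum(abs(segs$length_cm - old_len) > 0.01, na.rm = TRUE)
      if (ndiff > 0) {
        message(sprintf(
          "%d call(s) differ from the map-derived length by > 0.01 cM; map lengths used",
          ndiff))
      }
    }
  }
  segs
}

# fread-like reader that rejects silently truncated files: every row must
# carry the full column count (a trailing partial line leaves NAs behind).
.read_tsv_checked <- function(path, header, sep) {
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep,
                      stringsAsFactors = FALSE, fill = TRUE,
                      blank.lines.skip = TRUE, comment.char = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      stop("parse error in ", path, ": ", conditionMessage(e))
    })
  if (nrow(df) > 0 && anyNA(df[nrow(df), ])) {
    stop("truncated file (incomplete final record): ", path)
  }
  df
}

.TRUTH_COLS <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                 "start_bp", "end_bp", "start_cm", "end_cm")

#' Read / write ground-truth IBD segment files
#'
#' The framework's own truth format: a header line then tab-separated columns
#' `sample1 hap1 sample2 hap2 chrom start_bp end_bp start_cm end_cm`, with
#' hap indices 0/1 and half-open 0-based bp intervals. `write_truth_ibd` and
#' `read_truth_ibd` are mutual inverses.
#'
#' @param path File path.
#' @param segments An `ibd_segments` table.
#' @return `read_truth_ibd`: an `ibd_segments` table; `write_truth_ibd`: the
#'   path, invisibly.
#' @export
read_truth_ibd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(ibd_segments())
  df <- .read_tsv_checked(path, header = TRUE, sep = "\t")
  if (nrow(df) == 0) return(ibd_segments())
  if (!all(.TRUTH_COLS %in% names(df))) {
    stop("truth file must have columns ", paste(.TRUTH_COLS, collapse = ", "))
  }
  ibd_segments(df$sample1, df$hap1, df$sample2, df$hap2, df$chrom,
               df$start_bp, df$end_bp, df$start_cm, df$end_cm)
}

#' @rdname read_truth_ibd
#' @export
write_truth_ibd <- function(segments, path) {
  df <- as.data.frame(segments)[, .TRUTH_COLS, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write local-tree tracks
#'
#' The framework's text track format: a `#chrom=<c> region_bp=<L>` comment
#' line, a header, then tab-separated `sample1 hap1 sample2 hap2 start_bp
#' end_bp label` rows giving each pair's MRCA-label runs.
#'
#' @param path File path.
#' @param track A `local_tree_track`.
#' @return `read_track`: a `local_tree_track`; `write_track`: the path,
#'   invisibly.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#chrom=(\\S+)\\s+region_bp=(\\S+)", first))[[1]]
  if (length(m) != 3) stop("track file must start with '#chrom=<c> region_bp=<L>'")
  df <- data.table::fread(path, skip = 1, header = TRUE, sep = "\t",
                          data.table = FALSE)
  local_tree_track(df, region_bp = as.numeric(m[3]), chrom = m[2])
}

#' @rdname read_track
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom=%s region_bp=%s", track$chrom,
                     format(track$region_bp, scientific = FALSE)), con)
  utils::write.table(track$runs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import a tskit tree sequence as a local-tree track
#'
#' Converts a binary `.trees` file (msprime/tskit/stdpopsim output) into the
#' framework's track format by computing, for every local tree and every
#' unordered sample-haplotype pair, the pair's MRCA node id. The conversion
#' runs the bundled Python helper (requires `python` with the `tskit` module
#' on the PATH); consecutive trees with an unchanged pairwise MRCA are merged
#' into one run. Sample nodes 2k, 2k+1 become individual `ind<k>`.
#'
#' @param path A `.trees` file.
#' @param python Python interpreter to use.
#' @return A `local_tree_track`.
#' @export
read_tree_sequence <- function(path, python = "python") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (Sys.which(python) == "") stop("python interpreter not found: ", python)
  helper <- system.file("python", "trees_to_track.py", package = "ibdbench")
  out <- tempfile(fileext = ".track.tsv")
  status <- system2(python, c(helper, shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(out)) {
    stop("tree-sequence conversion failed (is the 'tskit' Python module installed?)")
  }
  on.exit(unlink(out))
  read_track(out)
}
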
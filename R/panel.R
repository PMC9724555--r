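#' Construct a phased haplotype panel
#'
#' A biallelic (or, transiently, multiallelic) phased haplotype matrix: one
#' row per site, one column per haplotype, alleles coded as small non-negative
#' integers (0 = REF). Two consecutive haplotypes belong to one diploid
#' sample.
#'
#' @param alleles Integer matrix, sites x haplotypes.
#' @param pos_bp Strictly increasing physical positions, one per site.
#' @param sample_ids Sample identifiers, one per diploid individual
#'   (`2 * length(sample_ids) == ncol(alleles)`).
#' @param chrom Chromosome label.
#' @param ref,alt Optional REF / ALT allele strings per site (ALT may be a
#'   comma-joined list for multiallelic sites).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, pos_bp, sample_ids, chrom = "1",
                            ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- nrow(alleles)
  n_hap <- ncol(alleles)
  if (length(pos_bp) != n_sites) stop("pos_bp length must equal site count")
  if (n_sites > 1 && any(diff(pos_bp) <= 0)) {
    stop("site positions must be strictly increasing")
  }
  if (2L * length(sample_ids) != n_hap) {
    stop("need exactly 2 haplotypes per sample")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  haps <- data.frame(
    sample_id = rep(as.character(sample_ids), each = 2L),
    hap_index = rep(0:1, times = length(sample_ids)),
    stringsAsFactors = FALSE
  )
  colnames(alleles) <- paste(haps$sample_id, haps$hap_index, sep = "_")
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  structure(
    list(chrom = as.character(chrom), pos_bp = as.numeric(pos_bp),
         ref = as.character(ref), alt = as.character(alt),
         alleles = alleles, haplotypes = haps),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> chrom %s: %d sites x %d haplotypes (%d samples)\n",
              x$chrom, nrow(x$alleles), ncol(x$alleles), nrow(x$haplotypes) / 2L))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

# subset a panel to a set of site rows (logical or integer index)
.panel_subset_sites <- function(panel, idx) {
  panel$alleles <- panel$alleles[idx, , drop = FALSE]
  panel$pos_bp <- panel$pos_bp[idx]
  panel$ref <- panel$ref[idx]
  panel$alt <- panel$alt[idx]
  panel
}

#' Per-site minor allele frequency
#'
#' For biallelic sites the frequency of the rarer of the two alleles; NA for
#' sites carrying more than two distinct allele values.
#'
#' @param panel A `haplotype_panel`.
#' @return Numeric vector, one MAF per site.
#' @export
site_maf <- function(panel) {
  A <- panel$alleles
  p1 <- rowMeans(A == 1L)
  multi <- .multiallelic_sites(panel)
  maf <- pmin(p1, 1 - p1)
  maf[multi] <- NA_real_
  maf
}

.multiallelic_sites <- function(panel) {
  A <- panel$alleles
  mx <- max(A, 0L)
  if (mx <= 1L) return(rep(FALSE, nrow(A)))
  n_vals <- Reduce(`+`, lapply(0:mx, function(v) (rowSums(A == v) > 0L) + 0L))
  n_vals > 2L
}

#' Remove multiallelic sites and singletons
#'
#' Drops sites with more than two observed allele values and sites whose minor
#' allele count is 0 or 1 (monomorphic sites and singletons). The haplotype
#' set is unchanged; the operation is idempotent.
#'
#' @param panel A `haplotype_panel`.
#' @return The filtered panel.
#' @export
filter_sites <- function(panel) {
  A <- panel$alleles
  multi <- .multiallelic_sites(panel)
  n1 <- rowSums(A == 1L)
  n0 <- rowSums(A == 0L)
  minor <- pmin(n0, n1)
  keep <- !multi & minor >= 2L
  .panel_subset_sites(panel, keep)
}

#' Downsample a panel to array marker density
#'
#' Emulates genotyping-array marker selection from a sequencing-density panel.
#' The chromosome's mapped genetic length is divided by `target_sites` to give
#' an ideal inter-marker interval `I` (cM); consecutive intervals are grouped
#' into windows of `window` intervals. Pass 1 takes the highest-MAF site from
#' each interval that has one; pass 2 fills each still-empty interval with the
#' highest-MAF unused site from its window, until window leftovers are
#' exhausted. MAF ties break toward the lower bp position.
#'
#' @param panel A `haplotype_panel` (biallelic).
#' @param map A `genetic_map` covering the panel.
#' @param target_sites Desired number of markers.
#' @param window Window size `w` in intervals (default 5).
#' @return Panel restricted to the selected sites (positions in order). If
#'   `target_sites >=` available sites the panel is returned unchanged with a
#'   warning.
#' @export
downsample_to_array <- function(panel, map, target_sites, window = 5L) {
  stopifnot(target_sites >= 1, window >= 1)
  n <- nrow(panel$alleles)
  if (target_sites >= n) {
    warning(sprintf("target_sites (%d) >= available sites (%d); returning all sites",
                    target_sites, n))
    return(panel)
  }
  cm <- bp_to_cm(map, panel$pos_bp)
  cm0 <- map$pos_cm[1]
  I <- map_total_cm(map) / target_sites
  iv <- pmin(floor((cm - cm0) / I), target_sites - 1)
  win <- iv %/% window
  maf <- site_maf(panel)
  if (anyNA(maf)) stop("downsampling requires a biallelic panel; run filter_sites first")

  dt <- data.table(idx = seq_len(n), iv = iv, win = win, maf = maf,
                   pos = panel$pos_bp)
  setorder(dt, iv, -maf, pos)
  pass1 <- dt[, .SD[1L], by = iv]
  selected <- pass1$idx

  empty_iv <- setdiff(0:(target_sites - 1), pass1$iv)
  if (length(empty_iv) > 0) {
    leftover <- dt[!idx %in% selected]
    setorder(leftover, win, -maf, pos)
    taken <- rep(FALSE, nrow(leftover))
    for (j in sort(empty_iv)) {
      w <- j %/% window
      cand <- which(leftover$win == w & !taken)
      if (length(cand) > 0) {
        pick <- cand[1L]  # leftover already ordered by (-maf, pos) within window
        taken[pick] <- TRUE
        selected <- c(selected, leftover$idx[pick])
      }
    }
  }
  .panel_subset_sites(panel, sort(selected))
}

#' Implant genotyping errors into a panel
#'
#' Flips alleles 0<->1 at uniformly random (site, haplotype) cells so that the
#' marginal per-allele error rate equals `rate`. Errors can be layered
#' incrementally: passing the error set of a previous, lower-rate injection
#' (applied to the same panel lineage) flips only additional cells with
#' probability `(rate - base_rate) / (1 - base_rate)`, so the realized
#' marginal rate is exactly `rate` and error sets are nested across rates.
#'
#' @param panel A biallelic `haplotype_panel` (for incremental use: the panel
#'   already carrying the base errors).
#' @param rate Target marginal error rate per allele, in `[0, 1]`.
#' @param seed Integer seed; same seed, same output.
#' @param base_errors Optional data frame `(site, haplotype)` of cells already
#'   flipped, as returned in `$errors` of a previous call.
#' @param base_rate Rate realized by `base_errors` (0 when none).
#' @return List with `panel` (perturbed), `errors` (data frame of all flipped
#'   cells, a superset of `base_errors`) and `rate`.
#' @export
inject_genotyping_errors <- function(panel, rate, seed, base_errors = NULL,
                                     base_rate = 0) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (base_rate < 0 || base_rate > rate) {
    stop("base_rate must be in [0, rate]")
  }
  A <- panel$alleles
  if (max(A, 0L) > 1L) stop("error injection requires a biallelic panel")
  n_cells <- length(A)
  base_idx <- integer(0)
  if (!is.null(base_errors) && nrow(base_errors) > 0) {
    base_idx <- (base_errors$haplotype - 1L) * nrow(A) + base_errors$site
  }
  p_add <- if (base_rate < 1) (rate - base_rate) / (1 - base_rate) else 0
  new_idx <- withr::with_seed(seed, {
    u <- runif(n_cells)
    cand <- which(u < p_add)
    setdiff(cand, base_idx)
  })
  if (length(new_idx) > 0) A[new_idx] <- 1L - A[new_idx]
  panel$alleles <- A
  all_idx <- sort(c(base_idx, new_idx))
  errors <- data.frame(
    site = ((all_idx - 1L) %% nrow(A)) + 1L,
    haplotype = ((all_idx - 1L) %/% nrow(A)) + 1L
  )
  list(panel = panel, errors = errors, rate = rate)
}

#' Merge consecutive haplotypes into unphased genotypes
#'
#' Haplotypes (2k-1, 2k) become individual k; each genotype is the unordered
#' multiset of the two alleles (reported as sorted `"a/b"` strings plus, for
#' biallelic panels, an ALT-dosage matrix).
#'
#' @param panel A `haplotype_panel` with an even haplotype count.
#' @return An object of class `genotype_panel`: `sample_id`, `chrom`,
#'   `pos_bp`, `gt` (character matrix sites x individuals), `dosage`.
#' @export
merge_haplotypes_to_genotypes <- function(panel) {
  A <- panel$alleles
  if (ncol(A) %% 2L != 0L) stop("haplotype count must be even")
  a1 <- A[, seq(1L, ncol(A), by = 2L), drop = FALSE]
  a2 <- A[, seq(2L, ncol(A), by = 2L), drop = FALSE]
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  gt <- matrix(paste(lo, hi, sep = "/"), nrow = nrow(A))
  ids <- unique(panel$haplotypes$sample_id)
  colnames(gt) <- ids
  structure(
    list(sample_id = ids, chrom = panel$chrom, pos_bp = panel$pos_bp,
         gt = gt, dosage = a1 + a2),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> chrom %s: %d sites x %d individuals\n",
              x$chrom, length(x$pos_bp), length(x$sample_id)))
  invisible(x)
}
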
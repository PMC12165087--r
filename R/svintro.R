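# Population-specific SV detection by permutation F_ST and introgression
# assignment by flanking-segment intersection.
#
# An SV is population-specific when all four criteria hold:
#   (1) F_ST above the top-5% quantile of the tested set,
#   (2) permutation empirical P < 0.05,
#   (3) missingness < 0.1, and (4) MAF > 0.01
# (MAF and missingness over the union of the two compared groups). A
# specific SV is classified introgressed when its interval overlaps (or
# lies within `max_gap` of) an inferred introgressed segment.

#' Weir-Cockerham F_ST for one SV between two sample groups
#'
#' Treats the SV as a single biallelic locus and reuses the shared WC84
#' estimator ([wc_fst()]).
#'
#' @param genotypes Named dosage vector (0/1/2/NA per sample).
#' @param group_a,group_b Sample id vectors.
#' @return Per-site F_ST, `NA` when the SV is monomorphic over both groups
#'   or a group has no called genotypes.
#' @export
sv_fst <- function(genotypes, group_a, group_b) {
  ga <- genotypes[group_a]; gb <- genotypes[group_b]
  summ <- function(g) {
    n <- sum(!is.na(g))
    list(n = n, p = if (n) sum(g, na.rm = TRUE) / (2 * n) else NA_real_,
         h = if (n) mean(g == 1L, na.rm = TRUE) else NA_real_)
  }
  sa <- summ(ga); sb <- summ(gb)
  wc_fst(c(sa$n, sb$n), c(sa$p, sb$p), c(sa$h, sb$h))
}

#' Permutation empirical P-value for an SV's F_ST
#'
#' Group labels are permuted across samples (the permutation unit is the
#' diploid genotype, preserving within-individual dependence) and the
#' add-one estimator `(1 + #{perm F_ST >= observed}) / (1 + n_perm)` is
#' returned.
#'
#' @param genotypes Named dosage vector.
#' @param group_a,group_b Sample id vectors.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List with `fst` (observed) and `p` (empirical P; `NA` when the
#'   observed F_ST is missing).
#' @export
permutation_empirical_p <- function(genotypes, group_a, group_b,
                                    n_perm = 1000, seed = 1) {
  if (n_perm < 100)
    stop("permutation_empirical_p: n_perm must be >= 100")
  obs <- sv_fst(genotypes, group_a, group_b)
  if (is.na(obs)) return(list(fst = NA_real_, p = NA_real_))
  set.seed(seed)
  pool <- c(group_a, group_b)
  na <- length(group_a)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    perm <- sample(pool)
    f <- sv_fst(genotypes, perm[seq_len(na)], perm[-seq_len(na)])
    if (!is.na(f) && f >= obs) exceed <- exceed + 1L
  }
  list(fst = obs, p = (1 + exceed) / (1 + n_perm))
}

#' Run the permutation F_ST test over every SV in an `SVSet`
#'
#' @param svs An `SVSet`.
#' @param popmap A `PopulationMap`.
#' @param pop_a,pop_b The two compared population labels.
#' @param n_perm Permutations per SV.
#' @param seed Base seed; SV i uses `seed + i` so the engine is
#'   reproducible and order-independent.
#' @return `data.frame` with `sv_id`, `svtype`, `chrom`, `pos`, `end`,
#'   `fst`, `empirical_p`, `maf`, `missingness` (MAF/missingness over the
#'   union of the two groups).
#' @export
sv_permutation_scan <- function(svs, popmap, pop_a, pop_b, n_perm = 1000,
                                seed = 1) {
  ga <- intersect(pop_samples(popmap, pop_a), svs$sample_ids)
  gb <- intersect(pop_samples(popmap, pop_b), svs$sample_ids)
  if (!length(ga) || !length(gb))
    stop("sv_permutation_scan: both groups must have genotyped samples")
  res <- lapply(seq_len(nrow(svs$info)), function(i) {
    g <- stats::setNames(as.numeric(svs$genotypes[i, ]), svs$sample_ids)
    permutation_empirical_p(g, ga, gb, n_perm = n_perm, seed = seed + i)
  })
  sub <- svs$genotypes[, c(ga, gb), drop = FALSE]
  called <- rowSums(!is.na(sub))
  p_alt <- rowSums(sub, na.rm = TRUE) / (2 * pmax(called, 1L))
  data.frame(sv_id = svs$info$sv_id, svtype = svs$info$svtype,
             chrom = svs$info$chrom, pos = svs$info$pos,
             end = svs$info$end,
             fst = vapply(res, `[[`, 0, "fst"),
             empirical_p = vapply(res, `[[`, 0, "p"),
             maf = ifelse(called > 0, pmin(p_alt, 1 - p_alt), NA_real_),
             missingness = 1 - called / ncol(sub))
}

#' Flag population-specific SVs by the four-criterion conjunction
#'
#' @param scan `data.frame` from [sv_permutation_scan()].
#' @param fst_quantile F_ST quantile over the tested set (default 0.95,
#'   the top 5 percent).
#' @param p_max Empirical-P ceiling (default 0.05).
#' @param miss_max Missingness ceiling (default 0.1).
#' @param maf_min MAF floor (default 0.01).
#' @return The scan with a logical `specific` column; the attribute
#'   `criteria_failures` counts SVs failing each criterion.
#' @export
filter_specific <- function(scan, fst_quantile = 0.95, p_max = 0.05,
                            miss_max = 0.1, maf_min = 0.01) {
  tested <- !is.na(scan$fst)
  thr <- stats::quantile(scan$fst[tested], fst_quantile, names = FALSE,
                         type = 1)
  pass_fst <- tested & scan$fst > thr
  pass_p <- !is.na(scan$empirical_p) & scan$empirical_p < p_max
  pass_miss <- scan$missingness < miss_max
  pass_maf <- !is.na(scan$maf) & scan$maf > maf_min
  scan$specific <- pass_fst & pass_p & pass_miss & pass_maf
  attr(scan, "fst_threshold") <- thr
  attr(scan, "criteria_failures") <- c(fst = sum(!pass_fst),
                                       p = sum(!pass_p),
                                       missingness = sum(!pass_miss),
                                       maf = sum(!pass_maf))
  scan
}

#' Classify population-specific SVs by flanking introgressed segments
#'
#' A specific SV is classified introgressed iff its interval
#' `[pos - 1, end)` overlaps a segment or lies within `max_gap` bp of one.
#'
#' @param scan `data.frame` from [filter_specific()] (needs `specific`).
#' @param segments Segment `data.frame` (`chrom`, `start`, `end`; 0-based
#'   half-open) from [call_segments()].
#' @param max_gap Maximum distance to a segment in bp (default 0 = strict
#'   overlap).
#' @return The scan with `segment_id` (index into `segments` or `NA`) and
#'   `classification` (`"introgressed"` or `"none"`).
#' @export
assign_flanking <- function(scan, segments, max_gap = 0) {
  scan$segment_id <- NA_integer_
  scan$classification <- "none"
  if (!nrow(segments) || !any(scan$specific)) return(scan)
  sv_gr <- GenomicRanges::GRanges(scan$chrom,
                                  IRanges::IRanges(scan$pos, scan$end))
  seg_gr <- intervals_to_gr(segments)
  ov <- GenomicRanges::distanceToNearest(sv_gr, seg_gr)
  qh <- S4Vectors::queryHits(ov)
  near <- qh[S4Vectors::mcols(ov)$distance <= max_gap]
  hit_seg <- S4Vectors::subjectHits(ov)[S4Vectors::mcols(ov)$distance <=
                                          max_gap]
  sel <- scan$specific[near]
  scan$segment_id[near[sel]] <- hit_seg[sel]
  scan$classification[near[sel]] <- "introgressed"
  scan
}
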
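# High-level drivers wiring the modules into the bidirectional scan:
#   rIBD (both directions) -> windowed D/f_d (both arrangements) ->
#   direction inference -> segment calling -> bidirectional intersection
#   -> SV classification -> summary.
#
# Population roles follow the four-taxon design: two domestic populations
# (dom_a, dom_b), each with a conspecific wild background (wild_a, wild_b),
# and one distant outgroup used solely to polarize alleles.
#   direction "a_to_b" (donor dom_a -> recipient dom_b):
#     rIBD roles recipient = dom_b, donor = dom_a, background = wild_b;
#     arrangement 1: D(wild_b, dom_b; dom_a, outgroup).
#   direction "b_to_a" is the mirror image (arrangement 2).

default_role_set <- function() {
  list(dom_a = "P_A", dom_b = "P_B", wild_a = "W_A", wild_b = "W_B",
       outgroup = "OUT")
}

#' Bidirectional introgression scan
#'
#' Runs the windowed rIBD scan and the two-arrangement D/f_d scan in both
#' directions, infers per-window direction, calls segments per direction
#' and intersects them.
#'
#' @param panel A phased `HaplotypePanel` holding all five populations.
#' @param popmap A `PopulationMap`.
#' @param chrom_length Chromosome length in bp.
#' @param roles Named list mapping `dom_a`, `dom_b`, `wild_a`, `wild_b`,
#'   `outgroup` to population labels (defaults match the simulator).
#' @param window,step Window grid in bp (defaults 50 kb / 25 kb).
#' @param q Top-quantile mass for rIBD seeds (default 0.01).
#' @param fd_min f_d confirmation threshold (default 0).
#' @param min_sites Minimum informative sites per D/f_d window.
#' @param delta Direction-inference margin (default 0).
#' @param extend Extend seeds over positive-rIBD runs (default TRUE).
#' @param ibd_args List of arguments passed to [detect_ibd()].
#' @return List with the window grid, per-direction rIBD and f_d scans,
#'   the per-window `direction` call (`dir1` = a_to_b), per-direction
#'   segments, their intersection, and genome fractions.
#' @export
scan_bidirectional <- function(panel, popmap, chrom_length,
                               roles = default_role_set(),
                               window = 50000, step = 25000, q = 0.01,
                               fd_min = 0, min_sites = 10, delta = 0,
                               extend = TRUE, ibd_args = list()) {
  need <- c("dom_a", "dom_b", "wild_a", "wild_b", "outgroup")
  if (!all(need %in% names(roles)))
    stop("scan_bidirectional: roles must name ",
         paste(need, collapse = ", "))
  windows <- make_windows(chrom_length, window, step, chrom = panel$chrom)

  pm_ab <- popmap; pm_ab$roles <- list(recipient = roles$dom_b,
                                       donor = roles$dom_a,
                                       background = roles$wild_b)
  pm_ba <- popmap; pm_ba$roles <- list(recipient = roles$dom_a,
                                       donor = roles$dom_b,
                                       background = roles$wild_a)
  ribd_ab <- do.call(ribd_scan, c(list(panel, pm_ab, windows), ibd_args))
  ribd_ba <- do.call(ribd_scan, c(list(panel, pm_ba, windows), ibd_args))

  fq1 <- quartet_freqs(panel, popmap, roles$wild_b, roles$dom_b,
                       roles$dom_a, roles$outgroup)
  fq2 <- quartet_freqs(panel, popmap, roles$wild_a, roles$dom_a,
                       roles$dom_b, roles$outgroup)
  fd1 <- dstat_scan(fq1, windows, min_sites)
  fd2 <- dstat_scan(fq2, windows, min_sites)
  direction <- infer_direction(fd1$fd, fd2$fd, delta)

  # Direction is decided per segment, not per window: the length-weighted
  # mean f_d of each arrangement over the segment's windows is compared.
  # Single 50 kb windows carry too few informative sites for a reliable
  # per-window call; averaging over a called region restores the margin.
  seg_ab <- call_segments(ribd_ab, fd1, q = q, fd_min = fd_min,
                          direction_label = "a_to_b", extend = extend)
  seg_ba <- call_segments(ribd_ba, fd2, q = q, fd_min = fd_min,
                          direction_label = "b_to_a", extend = extend)
  seg_ab <- filter_segment_direction(seg_ab, windows, fd1$fd, fd2$fd, delta)
  seg_ba <- filter_segment_direction(seg_ba, windows, fd2$fd, fd1$fd, delta)
  both <- intersect_bidirectional(seg_ab, seg_ba)
  list(windows = windows, ribd_ab = ribd_ab, ribd_ba = ribd_ba,
       fd_arr1 = fd1, fd_arr2 = fd2, direction = direction,
       segments_ab = seg_ab, segments_ba = seg_ba,
       bidirectional = both,
       fraction_ab = genome_fraction(seg_ab, chrom_length),
       fraction_ba = genome_fraction(seg_ba, chrom_length))
}

#' Keep only segments whose own-arrangement f_d beats the other arrangement
#'
#' Length-weighted mean f_d over each segment's windows is compared between
#' the segment's own arrangement (`fd_own`) and the mirror arrangement
#' (`fd_other`); segments whose margin does not exceed `delta` are dropped.
#'
#' @param segments Segment `data.frame` from [call_segments()].
#' @param windows The window grid the segments were called on.
#' @param fd_own,fd_other Per-window f_d vectors for the two arrangements.
#' @param delta Decision margin (default 0).
#' @return The filtered segment `data.frame` with a `fd_margin` column.
#' @export
filter_segment_direction <- function(segments, windows, fd_own, fd_other,
                                     delta = 0) {
  if (!nrow(segments)) {
    segments$fd_margin <- numeric(0)
    return(segments)
  }
  margin <- vapply(seq_len(nrow(segments)), function(i) {
    m <- windows$start < segments$end[i] & windows$end > segments$start[i]
    w <- windows$end[m] - windows$start[m]
    own <- sum(w * ifelse(is.na(fd_own[m]), 0, fd_own[m])) / sum(w)
    oth <- sum(w * ifelse(is.na(fd_other[m]), 0, fd_other[m])) / sum(w)
    own - oth
  }, 0)
  segments$fd_margin <- margin
  segments[margin > delta, , drop = FALSE]
}

#' End-to-end simulate -> scan -> call -> SV -> report driver
#'
#' @param config A [sim_config()].
#' @param n_svs Number of simulated SVs (0 disables the SV stage).
#' @param stratified_fraction Fraction of SVs constructed as stratified.
#' @param co_place Place stratified SVs inside truth tracts.
#' @param n_perm Permutations per SV.
#' @param ... Passed to [scan_bidirectional()].
#' @return List with `sim`, `svs`, `scan`, `sv_calls` and a `summary` list
#'   (segment counts, genome fractions, base-level recovery against truth
#'   per direction, SV counts).
#' @export
run_pipeline <- function(config, n_svs = 0, stratified_fraction = 0,
                         co_place = FALSE, n_perm = 200, ...) {
  sim <- simulate_history(config)
  panel <- bind_panels(sim$panels)
  scan <- scan_bidirectional(panel, sim$popmap,
                             config$chromosome_length, ...)
  truth_ab <- sim$tracts[sim$tracts$donor_pop == "P_A", , drop = FALSE]
  truth_ba <- sim$tracts[sim$tracts$donor_pop == "P_B", , drop = FALSE]
  rec_ab <- evaluate_recovery(scan$segments_ab, truth_ab)
  rec_ba <- evaluate_recovery(scan$segments_ba, truth_ba)

  svs <- NULL; sv_calls <- NULL
  if (n_svs > 0) {
    svs <- simulate_sv_table(config, n_svs, stratified_fraction,
                             tracts = sim$tracts, co_place = co_place)
    sv_scan <- sv_permutation_scan(svs, sim$popmap, "P_A", "P_B",
                                   n_perm = n_perm,
                                   seed = config$seed + 1000L)
    sv_scan <- filter_specific(sv_scan)
    all_segs <- rbind(scan$segments_ab, scan$segments_ba)
    sv_calls <- assign_flanking(sv_scan, all_segs)
  }
  summary <- list(
    seed = config$seed,
    n_windows = nrow(scan$windows),
    n_segments_a_to_b = nrow(scan$segments_ab),
    n_segments_b_to_a = nrow(scan$segments_ba),
    n_bidirectional = nrow(scan$bidirectional),
    fraction_a_to_b = scan$fraction_ab,
    fraction_b_to_a = scan$fraction_ba,
    recovery_a_to_b = rec_ab,
    recovery_b_to_a = rec_ba,
    n_svs = if (is.null(svs)) 0L else nrow(svs$info),
    n_specific_svs = if (is.null(sv_calls)) 0L else sum(sv_calls$specific),
    n_introgressed_svs = if (is.null(sv_calls)) 0L else
      sum(sv_calls$classification == "introgressed"))
  list(sim = sim, svs = svs, scan = scan, sv_calls = sv_calls,
       summary = summary)
}
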
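# From window statistics to introgressed segments: top-quantile rIBD
# candidates, f_d confirmation, direction inference from the two population
# arrangements, seed extension over positive-rIBD runs, merging,
# bidirectional intersection, and genome-fraction / recovery reporting.
#
# Candidate gate: a window is a seed iff its rIBD exceeds the empirical
# top-quantile threshold, rIBD > 0, and the arrangement-matched f_d confirms
# it (f_d > fd_min after the D < 0 zeroing rule). Seeds are then extended
# into the maximal surrounding run of windows with rIBD > 0: the
# top-quantile rule with f_d confirmation localises the strongest,
# corroborated signals while the extension recovers the full extent of the
# introgressed region around each seed (introgressed regions are regions
# of positive rIBD).

#' Empirical top-quantile threshold for rIBD candidates
#'
#' Nearest-rank `(1 - q)` quantile. Windows qualify as candidates only when
#' strictly above the threshold and strictly positive.
#'
#' @param ribd Numeric rIBD values (NAs allowed).
#' @param q Upper tail mass (default 0.01, the top 1 percent).
#' @return The threshold value.
#' @export
top_quantile_threshold <- function(ribd, q = 0.01) {
  x <- ribd[!is.na(ribd)]
  n <- length(x)
  if (n < 1 / q)
    stop("top_quantile_threshold: need at least ", ceiling(1 / q),
         " non-missing windows for q = ", q, ", got ", n)
  sort(x)[ceiling((1 - q) * n)]
}

#' Candidate windows by the top-quantile + positivity gate
#' @param ribd Numeric rIBD values.
#' @param q Upper tail mass.
#' @return Logical vector: `ribd > threshold & ribd > 0`.
#' @export
candidate_windows <- function(ribd, q = 0.01) {
  thr <- top_quantile_threshold(ribd, q)
  !is.na(ribd) & ribd > thr & ribd > 0
}

#' Confirm candidate windows with f_d
#'
#' A candidate is confirmed iff its f_d exceeds `fd_min` after the zeroing
#' rule (f_d = 0 wherever D < 0), i.e. D > 0 and f_d > fd_min. Candidates
#' with missing f_d (too few informative sites) are rejected.
#'
#' @param candidates Logical candidate vector over the window grid.
#' @param fd_scan `data.frame` from [dstat_scan()] on the same grid.
#' @param windows The window grid the candidates refer to.
#' @param fd_min Confirmation threshold (default 0).
#' @return Logical vector of confirmed windows.
#' @export
confirm_with_fd <- function(candidates, fd_scan, windows, fd_min = 0) {
  if (nrow(fd_scan) != nrow(windows) ||
      any(fd_scan$start != windows$start) ||
      any(fd_scan$end != windows$end))
    stop("confirm_with_fd: f_d scan is not on the candidate window grid")
  candidates & !is.na(fd_scan$fd) & fd_scan$fd > fd_min
}

#' Per-window direction inference from the two arrangements
#'
#' The arrangement matching the true direction of gene flow yields the
#' larger f_d; the mismatched arrangement underestimates it. A window is
#' assigned `dir1` iff `fd_arr1 - fd_arr2 > delta`, `dir2` iff
#' `fd_arr2 - fd_arr1 > delta`, else `ambiguous`. A missing value on one
#' side counts as 0; windows missing both are ambiguous.
#'
#' @param fd_arr1,fd_arr2 Per-window f_d under arrangements 1 and 2 (same
#'   grid).
#' @param delta Decision margin (default 0, strict inequality).
#' @return Character vector in `c("dir1", "dir2", "ambiguous")`.
#' @export
infer_direction <- function(fd_arr1, fd_arr2, delta = 0) {
  if (length(fd_arr1) != length(fd_arr2))
    stop("infer_direction: arrangements must share the window grid")
  both_na <- is.na(fd_arr1) & is.na(fd_arr2)
  a1 <- ifelse(is.na(fd_arr1), 0, fd_arr1)
  a2 <- ifelse(is.na(fd_arr2), 0, fd_arr2)
  out <- rep("ambiguous", length(a1))
  out[a1 - a2 > delta] <- "dir1"
  out[a2 - a1 > delta] <- "dir2"
  out[both_na] <- "ambiguous"
  out
}

#' Merge selected windows into introgressed segments
#'
#' Overlapping or near-adjacent (up to `gap` bp apart) selected windows of
#' the same direction merge into one segment; segment statistics are
#' window-length-weighted means.
#'
#' @param windows Window grid `data.frame` (`chrom`, `start`, `end`).
#' @param selected Logical vector over the grid.
#' @param ribd,fd Per-window statistics carried into segment means.
#' @param direction Direction label attached to the segments.
#' @param gap Maximum bp between merged windows (default 0 = book-ended).
#' @return `data.frame` with `chrom`, `start`, `end`, `direction`,
#'   `mean_ribd`, `mean_fd`, `n_windows`.
#' @export
merge_segments <- function(windows, selected, ribd = NULL, fd = NULL,
                           direction = "dir1", gap = 0) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      mean_ribd = numeric(), mean_fd = numeric(),
                      n_windows = integer())
  idx <- which(selected)
  if (!length(idx)) return(empty)
  idx <- idx[order(windows$chrom[idx], windows$start[idx])]
  segs <- list()
  cur <- idx[1]
  cur_members <- c(cur)
  cur_end <- windows$end[cur]
  flush <- function(members, end) {
    w <- windows$end[members] - windows$start[members]
    data.frame(chrom = windows$chrom[members[1]],
               start = windows$start[members[1]], end = end,
               direction = direction,
               mean_ribd = if (is.null(ribd)) NA_real_ else
                 sum(w * ribd[members]) / sum(w),
               mean_fd = if (is.null(fd)) NA_real_ else
                 sum(w * fd[members], na.rm = TRUE) / sum(w),
               n_windows = length(members))
  }
  for (i in idx[-1]) {
    same_chrom <- windows$chrom[i] == windows$chrom[cur_members[1]]
    if (same_chrom && windows$start[i] <= cur_end + gap) {
      cur_members <- c(cur_members, i)
      cur_end <- max(cur_end, windows$end[i])
    } else {
      segs[[length(segs) + 1]] <- flush(cur_members, cur_end)
      cur_members <- c(i)
      cur_end <- windows$end[i]
    }
  }
  segs[[length(segs) + 1]] <- flush(cur_members, cur_end)
  do.call(rbind, segs)
}

#' Call introgressed segments for one direction
#'
#' Seeds are windows passing the top-quantile rIBD gate confirmed by f_d
#' (and, when a direction vector is supplied, assigned to `direction`).
#' With `extend = TRUE` each seed grows into the maximal contiguous run of
#' windows with rIBD > 0 before merging.
#'
#' @param ribd_scan `data.frame` from [ribd_scan()].
#' @param fd_scan `data.frame` from [dstat_scan()] for the matching
#'   arrangement, same grid.
#' @param q Top-quantile mass for the seed gate.
#' @param fd_min f_d confirmation threshold.
#' @param direction_call Optional per-window direction vector from
#'   [infer_direction()]; seeds must then match `direction_label`.
#' @param direction_label Label recorded on the segments.
#' @param extend Grow seeds over their surrounding positive-rIBD runs.
#' @param gap Merge gap in bp.
#' @return Segment `data.frame` as from [merge_segments()].
#' @export
call_segments <- function(ribd_scan, fd_scan, q = 0.01, fd_min = 0,
                          direction_call = NULL,
                          direction_label = "dir1", extend = TRUE,
                          gap = 0) {
  grid <- ribd_scan[c("chrom", "start", "end")]
  cand <- candidate_windows(ribd_scan$ribd, q)
  seeds <- confirm_with_fd(cand, fd_scan, grid, fd_min)
  if (!is.null(direction_call))
    seeds <- seeds & direction_call == direction_label
  selected <- seeds
  if (extend && any(seeds)) {
    # seeds carry the f_d confirmation; extension follows the full extent
    # of the surrounding positive-rIBD region
    extendable <- !is.na(ribd_scan$ribd) & ribd_scan$ribd > 0
    runs <- rle(extendable)
    run_id <- rep(seq_along(runs$lengths), runs$lengths)
    seed_runs <- unique(run_id[seeds & extendable])
    selected <- seeds | (extendable & run_id %in% seed_runs)
  }
  merge_segments(grid, selected, ribd = ribd_scan$ribd, fd = fd_scan$fd,
                 direction = direction_label, gap = gap)
}

#' Intersect segment sets called in the two directions
#'
#' Maximal intervals covered by at least one segment from each direction
#' set (standard half-open interval intersection).
#'
#' @param segments_a,segments_b Segment `data.frame`s (`chrom`, `start`,
#'   `end`).
#' @return `data.frame` with `chrom`, `start`, `end` (0-based half-open).
#' @export
intersect_bidirectional <- function(segments_a, segments_b) {
  ga <- GenomicRanges::reduce(intervals_to_gr(segments_a))
  gb <- GenomicRanges::reduce(intervals_to_gr(segments_b))
  gr_to_intervals(GenomicRanges::intersect(ga, gb))
}

#' Fraction of the genome covered by a segment set (union semantics)
#'
#' @param segments Segment `data.frame` (`chrom`, `start`, `end`).
#' @param genome_length Total genome (chromosome) length in bp.
#' @return Proportion in `[0, 1]`.
#' @export
genome_fraction <- function(segments, genome_length) {
  if (!nrow(segments)) return(0)
  if (any(segments$start < 0) || any(segments$end > genome_length))
    stop("genome_fraction: segment outside [0, genome_length)")
  red <- GenomicRanges::reduce(intervals_to_gr(segments))
  sum(GenomicRanges::width(red)) / genome_length
}

#' Base-pair precision/recall of segment calls against truth tracts
#'
#' Both sets are collapsed to their base-level union before comparison:
#' recall is the fraction of truth bases covered by segments, precision the
#' fraction of segment bases overlapping truth, F1 their harmonic mean.
#'
#' @param segments Segment `data.frame` (`chrom`, `start`, `end`).
#' @param truth Truth tract `data.frame` (`chrom`, `start`, `end`), e.g.
#'   from [simulate_history()].
#' @return List with `precision`, `recall`, `f1` (NA where undefined).
#' @export
evaluate_recovery <- function(segments, truth) {
  gs <- GenomicRanges::reduce(intervals_to_gr(segments))
  gt <- GenomicRanges::reduce(intervals_to_gr(truth))
  seg_bases <- sum(GenomicRanges::width(gs))
  truth_bases <- sum(GenomicRanges::width(gt))
  ov_bases <- sum(GenomicRanges::width(GenomicRanges::intersect(gs, gt)))
  precision <- if (seg_bases == 0) NA_real_ else ov_bases / seg_bases
  recall <- if (truth_bases == 0) NA_real_ else ov_bases / truth_bases
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  if (truth_bases > 0 && seg_bases == 0) recall <- 0
  list(precision = precision, recall = recall, f1 = f1)
}
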
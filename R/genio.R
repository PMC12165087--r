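# Data model and I/O: haplotype panels, population maps, SV tables,
# VCF/BED/TSV readers and writers, and the shared windowing engine.
#
# Coordinate contract used throughout the package:
#   * VCF positions are 1-based (as stored in the file);
#   * windows, BED intervals, IBD tracts and introgressed segments are
#     0-based half-open [start, end).
# A 1-based site at position p falls in window [s, e) iff p > s and p <= e.

#' Construct a phased haplotype panel
#'
#' A `HaplotypePanel` holds the phased biallelic genotypes of one chromosome
#' as a haplotype-by-site 0/1 matrix. Rows come in pairs: haplotypes
#' `2*i - 1` and `2*i` belong to `sample_ids[i]`.
#'
#' @param chrom Chromosome identifier.
#' @param positions Integer vector of 1-based site positions, strictly
#'   increasing.
#' @param alleles Integer matrix (`2 * length(sample_ids)` rows,
#'   `length(positions)` columns) with values 0, 1 or `NA`.
#' @param sample_ids Character vector of sample identifiers.
#' @param phased Logical; must be `TRUE` for IBD and haplotype operations.
#' @param chrom_length Chromosome length in bp (`NA` if unknown).
#' @return An object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(chrom, positions, alleles, sample_ids,
                            phased = TRUE, chrom_length = NA_integer_) {
  positions <- as.numeric(positions)
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("HaplotypePanel: positions must be strictly increasing")
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("HaplotypePanel: allele matrix must have 2 rows per sample (",
         nrow(alleles), " rows for ", length(sample_ids), " samples)")
  if (ncol(alleles) != length(positions))
    stop("HaplotypePanel: one allele column per position required")
  storage.mode(alleles) <- "integer"
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("HaplotypePanel: alleles must be 0, 1 or NA")
  rownames(alleles) <- hap_names(sample_ids)
  structure(list(chrom = as.character(chrom),
                 positions = positions,
                 alleles = alleles,
                 sample_ids = as.character(sample_ids),
                 phased = isTRUE(phased),
                 chrom_length = as.numeric(chrom_length)),
            class = "HaplotypePanel")
}

hap_names <- function(sample_ids) {
  as.vector(rbind(paste0(sample_ids, "_1"), paste0(sample_ids, "_2")))
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat("HaplotypePanel:", x$chrom, "-", length(x$sample_ids), "samples,",
      ncol(x$alleles), "sites,", if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' Subset a panel to a set of samples (keeping site order)
#' @param panel A `HaplotypePanel`.
#' @param samples Character vector of sample ids to keep, in the given order.
#' @return A `HaplotypePanel` restricted to `samples`.
#' @export
subset_panel <- function(panel, samples) {
  miss <- setdiff(samples, panel$sample_ids)
  if (length(miss))
    stop("samples not in panel: ", paste(miss, collapse = ", "))
  idx <- match(samples, panel$sample_ids)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_panel(panel$chrom, panel$positions,
                  panel$alleles[rows, , drop = FALSE], samples,
                  phased = panel$phased, chrom_length = panel$chrom_length)
}

#' Combine panels over the same sites
#' @param ... `HaplotypePanel` objects sharing chrom and positions.
#' @return A single `HaplotypePanel` with samples concatenated.
#' @export
bind_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "HaplotypePanel"))
    panels <- panels[[1]]
  ref <- panels[[1]]
  for (p in panels[-1]) {
    if (!identical(p$chrom, ref$chrom) ||
        !isTRUE(all.equal(p$positions, ref$positions)))
      stop("bind_panels: panels must share chrom and positions")
  }
  haplotype_panel(ref$chrom, ref$positions,
                  do.call(rbind, lapply(panels, `[[`, "alleles")),
                  unlist(lapply(panels, `[[`, "sample_ids")),
                  phased = all(vapply(panels, `[[`, TRUE, "phased")),
                  chrom_length = ref$chrom_length)
}

#' Construct a population map
#'
#' Assigns each sample to exactly one population and optionally attaches
#' analysis roles (recipient, donor, background, outgroup) to populations.
#'
#' @param assignments Named character vector: `names` are sample ids, values
#'   are population labels.
#' @param roles Named list/character vector mapping roles (`recipient`,
#'   `donor`, `background`, `outgroup`) to population labels.
#' @return An object of class `PopulationMap`.
#' @export
pop_map <- function(assignments, roles = list()) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("PopulationMap: assignments must be a named vector (sample -> pop)")
  if (anyDuplicated(names(assignments)))
    stop("PopulationMap: a sample may belong to only one population")
  roles <- as.list(roles)
  known <- c("recipient", "donor", "background", "outgroup")
  extra <- setdiff(names(roles), known)
  if (length(extra))
    stop("PopulationMap: unknown role(s): ", paste(extra, collapse = ", "))
  structure(list(assignments = assignments, roles = roles),
            class = "PopulationMap")
}

#' Samples belonging to a population (or to the population in a role)
#' @param popmap A `PopulationMap`.
#' @param pop A population label, or a role name if `role = TRUE`.
#' @param role Interpret `pop` as a role name.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(popmap, pop, role = FALSE) {
  if (role) {
    if (is.null(popmap$roles[[pop]]))
      stop("PopulationMap: role '", pop, "' is not set")
    pop <- popmap$roles[[pop]]
  }
  names(popmap$assignments)[popmap$assignments %in% pop]
}

require_roles <- function(popmap, roles) {
  miss <- roles[!roles %in% names(popmap$roles)]
  if (length(miss))
    stop("PopulationMap: required role(s) not set: ",
         paste(miss, collapse = ", "))
  invisible(popmap)
}

#' Read a two-column sample-to-population map (TSV, no header)
#' @param path Path to the TSV file.
#' @return A `PopulationMap` with empty roles.
#' @export
read_pop_map <- function(path) {
  if (!file.exists(path)) stop("pop map not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  pop_map(stats::setNames(df$population, df$sample))
}

#' Write a sample-to-population map as two-column TSV
#' @param popmap A `PopulationMap`.
#' @param path Output path.
#' @export
write_pop_map <- function(popmap, path) {
  df <- data.frame(sample = names(popmap$assignments),
                   population = unname(popmap$assignments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Windows

#' Sliding windows over a chromosome
#'
#' Produces the window grid `[k*step, k*step + window)` for
#' `k = 0, 1, ...` while `k*step < chrom_length`; the final windows are
#' truncated at `chrom_length` and flagged.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 50 kb).
#' @param step Step size in bp (default 25 kb); must satisfy
#'   `0 < step <= window`.
#' @param chrom Chromosome label attached to each window.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `truncated`.
#' @export
make_windows <- function(chrom_length, window = 50000, step = 25000,
                         chrom = "chr1") {
  if (step <= 0 || window <= 0) stop("window and step must be positive")
  if (step > window) stop("step (", step, ") must not exceed window (",
                          window, ")")
  if (chrom_length <= 0) stop("chrom_length must be positive")
  starts <- seq(0, chrom_length - 1, by = step)
  ends <- pmin(starts + window, chrom_length)
  data.frame(chrom = chrom, start = starts, end = ends,
             truncated = (starts + window) > chrom_length)
}

#' Index sites into windows
#' @param positions 1-based site positions.
#' @param windows Window `data.frame` from [make_windows()].
#' @return List of integer site-index vectors, one per window.
#' @export
window_site_index <- function(positions, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    which(positions > windows$start[i] & positions <= windows$end[i])
  })
}

# ---------------------------------------------------------------------------
# VCF: phased SNP panels

#' Read a phased biallelic SNP VCF into a `HaplotypePanel`
#'
#' Only biallelic SNP records are consumed; multiallelic and non-SNP
#' records are skipped (count reported in the `skipped` attribute). All
#' records must come from a single chromosome.
#'
#' @param path Path to a VCF file.
#' @param region Optional `"chrom:start-end"` (1-based inclusive) filter.
#' @param require_phased Reject unphased genotypes (default `TRUE`).
#' @return A `HaplotypePanel`; attribute `skipped` carries the number of
#'   non-biallelic-SNP records dropped.
#' @export
read_phased_vcf <- function(path, region = NULL, require_phased = TRUE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  is_snp <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) &
    nchar(alt1) == 1L & ref %in% c("A", "C", "G", "T") &
    alt1 %in% c("A", "C", "G", "T")
  skipped <- sum(!is_snp)

  chroms <- unique(as.character(GenomicRanges::seqnames(rr)[is_snp]))
  if (length(chroms) > 1L)
    stop("read_phased_vcf: panel must span a single chromosome, got: ",
         paste(chroms, collapse = ", "))
  if (length(chroms) == 0L) chroms <- as.character(
    GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(vcf)))[1]

  pos <- GenomicRanges::start(rr)[is_snp]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("read_phased_vcf: VCF has no GT field")
  gt <- gt[is_snp, , drop = FALSE]

  keep <- seq_along(pos)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("bad region string: ", region)
    if (m[2] != chroms) keep <- integer(0)
    else keep <- which(pos >= as.numeric(m[3]) & pos <= as.numeric(m[4]))
  }
  pos <- pos[keep]; gt <- gt[keep, , drop = FALSE]

  samples <- colnames(gt)
  sep <- substr(gt, 2, 2)
  if (require_phased) {
    called <- !(gt %in% c(".", "./.", ".|."))
    bad <- called & sep != "|"
    if (any(bad)) {
      i <- which(bad, arr.ind = TRUE)[1, ]
      stop("read_phased_vcf: unphased genotype '", gt[bad][1],
           "' at ", chroms, ":", pos[i[1]], " sample ", samples[i[2]])
    }
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out
  }
  # interleave haplotypes: rows S1_1, S1_2, S2_1, ...
  n_s <- length(samples); n_v <- length(pos)
  alleles <- matrix(NA_integer_, nrow = 2L * n_s, ncol = n_v)
  if (n_v > 0L) {
    alleles[seq(1L, 2L * n_s, by = 2L), ] <- t(matrix(to_int(a1), nrow = n_v))
    alleles[seq(2L, 2L * n_s, by = 2L), ] <- t(matrix(to_int(a2), nrow = n_v))
  }
  sl <- GenomeInfoDb::seqlengths(vcf)
  clen <- if (chroms %in% names(sl)) unname(sl[chroms]) else NA_integer_
  panel <- haplotype_panel(chroms, pos, alleles, samples,
                           phased = TRUE, chrom_length = clen)
  attr(panel, "skipped") <- skipped
  panel
}

#' Write a `HaplotypePanel` as a phased VCF
#'
#' Alleles are written as REF="A", ALT="T" carriers of the 0/1 coding; the
#' header declares the contig with `panel$chrom_length` when known.
#'
#' @param panel A phased `HaplotypePanel`.
#' @param path Output path.
#' @export
write_phased_vcf <- function(panel, path) {
  if (!panel$phased) stop("write_phased_vcf: panel must be phased")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               if (!is.na(panel$chrom_length))
                 sprintf("##contig=<ID=%s,length=%d>", panel$chrom,
                         as.integer(panel$chrom_length))
               else sprintf("##contig=<ID=%s>", panel$chrom),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids),
                     collapse = "\t")), con)
  n_s <- length(panel$sample_ids)
  a1 <- panel$alleles[seq(1L, 2L * n_s, by = 2L), , drop = FALSE]
  a2 <- panel$alleles[seq(2L, 2L * n_s, by = 2L), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  for (j in seq_along(panel$positions)) {
    gts <- paste0(fmt(a1[, j]), "|", fmt(a2[, j]))
    writeLines(paste(c(panel$chrom, panel$positions[j],
                       paste0("snp", j), "A", "T", ".", "PASS", ".", "GT",
                       gts), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# SV tables

SV_CLASSES <- c("DEL", "INS", "DUP", "INV")

#' Construct an SV genotype table
#'
#' @param info `data.frame` with columns `sv_id`, `svtype`, `chrom`, `pos`
#'   (1-based), `end` (1-based inclusive; `end == pos` for insertions).
#' @param genotypes Integer matrix of alt-allele dosages (rows = SVs,
#'   columns = samples; values 0/1/2/NA).
#' @param sample_ids Column sample ids.
#' @return An object of class `SVSet` with per-SV `maf` and `missingness`
#'   computed over called alleles.
#' @export
sv_set <- function(info, genotypes, sample_ids) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(info) == nrow(genotypes),
            ncol(genotypes) == length(sample_ids))
  if (any(!info$svtype %in% SV_CLASSES))
    stop("sv_set: svtype must be one of ", paste(SV_CLASSES, collapse = "/"))
  if (any(info$end < info$pos)) stop("sv_set: end must be >= pos")
  colnames(genotypes) <- sample_ids
  rownames(genotypes) <- info$sv_id
  called <- rowSums(!is.na(genotypes))
  p <- rowSums(genotypes, na.rm = TRUE) / (2 * pmax(called, 1L))
  info$maf <- ifelse(called > 0, pmin(p, 1 - p), NA_real_)
  info$missingness <- 1 - called / ncol(genotypes)
  structure(list(info = info, genotypes = genotypes,
                 sample_ids = as.character(sample_ids)),
            class = "SVSet")
}

#' @export
print.SVSet <- function(x, ...) {
  cat("SVSet:", nrow(x$info), "SVs x", length(x$sample_ids), "samples (",
      paste(names(table(x$info$svtype)), table(x$info$svtype),
            sep = ":", collapse = " "), ")\n")
  invisible(x)
}

#' Read an SV VCF into an `SVSet`
#'
#' Requires an `SVTYPE` INFO key; `END` is required for DEL/DUP/INV.
#' Records whose class is outside DEL/INS/DUP/INV (e.g. translocations/BND)
#' and SVs longer than `max_size` are dropped; counts are reported in the
#' `dropped` attribute.
#'
#' @param path Path to an SV VCF.
#' @param max_size Maximum SV size in bp (default 5 Mb).
#' @return An `SVSet`.
#' @export
read_sv_vcf <- function(path, max_size = 5e6) {
  if (!file.exists(path)) stop("SV VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  inf <- VariantAnnotation::info(vcf)
  if (!"SVTYPE" %in% colnames(inf))
    stop("read_sv_vcf: VCF lacks the SVTYPE INFO key")
  svtype <- as.character(inf$SVTYPE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  endv <- if ("END" %in% colnames(inf)) {
    e <- inf$END
    if (inherits(e, "List") || is.list(e))
      e <- vapply(as.list(e), function(x)
        if (length(x)) as.numeric(x[[1]]) else NA_real_, 0)
    as.numeric(e)
  } else rep(NA_real_, length(pos))
  # readVcf may fold END into the range end; use the wider of the two
  endv <- pmax(endv, GenomicRanges::end(rr), na.rm = TRUE)
  endv[svtype == "INS"] <- pos[svtype == "INS"]
  if (any(svtype %in% c("DEL", "DUP", "INV") & is.na(endv)))
    stop("read_sv_vcf: END required for DEL/DUP/INV records")

  bad_class <- !svtype %in% SV_CLASSES
  too_long <- !bad_class & (endv - pos) > max_size
  keep <- !bad_class & !too_long
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("sv", which(keep))
  out <- sv_set(data.frame(sv_id = ids,
                           svtype = svtype[keep],
                           chrom = as.character(
                             GenomicRanges::seqnames(rr))[keep],
                           pos = pos[keep], end = endv[keep]),
                dos, colnames(gt))
  attr(out, "dropped") <- c(non_class = sum(bad_class),
                            too_long = sum(too_long))
  out
}

gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  d <- suppressWarnings(as.integer(a1) + as.integer(a2))
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write an `SVSet` as a VCF with SVTYPE/END INFO keys
#' @param svs An `SVSet`.
#' @param path Output path.
#' @param chrom_length Optional contig length for the header.
#' @export
write_sv_vcf <- function(svs, path, chrom_length = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  chrom <- unique(svs$info$chrom)
  writeLines(c("##fileformat=VCFv4.2",
               vapply(chrom, function(ch)
                 if (!is.na(chrom_length))
                   sprintf("##contig=<ID=%s,length=%d>", ch,
                           as.integer(chrom_length))
                 else sprintf("##contig=<ID=%s>", ch), ""),
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
               "##ALT=<ID=DEL,Description=\"Deletion\">",
               "##ALT=<ID=INS,Description=\"Insertion\">",
               "##ALT=<ID=DUP,Description=\"Duplication\">",
               "##ALT=<ID=INV,Description=\"Inversion\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", svs$sample_ids),
                     collapse = "\t")), con)
  gt_str <- matrix("./.", nrow = nrow(svs$genotypes),
                   ncol = ncol(svs$genotypes))
  gt_str[svs$genotypes == 0L] <- "0/0"
  gt_str[svs$genotypes == 1L] <- "0/1"
  gt_str[svs$genotypes == 2L] <- "1/1"
  for (i in seq_len(nrow(svs$info))) {
    writeLines(paste(c(svs$info$chrom[i], svs$info$pos[i], svs$info$sv_id[i],
                       "N", paste0("<", svs$info$svtype[i], ">"), ".", "PASS",
                       sprintf("SVTYPE=%s;END=%d", svs$info$svtype[i],
                               as.integer(svs$info$end[i])),
                       "GT", gt_str[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# BED

#' Write intervals as BED3+ (0-based half-open), sorted by (chrom, start)
#' @param intervals `data.frame` with at least `chrom`, `start`, `end`;
#'   extra columns are written verbatim after the first three.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals)) {
    o <- order(intervals$chrom, intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
    first <- c("chrom", "start", "end")
    intervals <- intervals[c(first, setdiff(names(intervals), first))]
  }
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file
#' @param path Path to a BED file.
#' @param extra_cols Names for columns beyond chrom/start/end (optional).
#' @return `data.frame` with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  if (!file.exists(path)) stop("BED not found: ", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  extra <- if (ncol(df) > 3L) {
    if (!is.null(extra_cols) && length(extra_cols) == ncol(df) - 3L)
      extra_cols else paste0("V", seq_len(ncol(df) - 3L))
  } else character(0)
  names(df) <- c(base, extra)
  df
}

# GRanges helpers shared by segment operations -------------------------------

intervals_to_gr <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}
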
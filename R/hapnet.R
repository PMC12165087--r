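# Locus-level haplotype analysis: haplotype extraction over a region,
# per-population frequency tables, and a minimum-spanning haplotype network
# over Hamming distances (with alternative equal-weight links). Haplogroups
# are the two components obtained by cutting the largest-weight MST edge --
# a documented heuristic for the Asian/European-style bipartition.

#' Extract haplotype classes over a region
#'
#' Restricts the panel to the region's SNPs, drops sites with
#' `MAF <= maf_min` (computed over the included haplotypes), excludes
#' haplotypes with missing alleles over the remaining sites, and collapses
#' identical allele strings into classes. Classes are labelled with roman
#' numerals by descending count, ties broken lexicographically by allele
#' string.
#'
#' @param panel A phased `HaplotypePanel`.
#' @param region `"chrom:start-end"` (1-based inclusive) or numeric
#'   `c(start, end)`.
#' @param maf_min Site MAF floor (default 0.05, strict inequality).
#' @param samples Optional sample subset.
#' @return List with `classes` (`data.frame`: `label`, `allele_string`,
#'   `count`), `assignment` (named haplotype -> label vector), `sites`
#'   (positions kept) and `n_excluded` (haplotypes dropped for
#'   missingness).
#' @export
extract_haplotypes <- function(panel, region, maf_min = 0.05,
                               samples = NULL) {
  if (!panel$phased) stop("extract_haplotypes: panel must be phased")
  if (!is.null(samples)) panel <- subset_panel(panel, samples)
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$",
                                    region))[[1]]
    if (length(m) != 4L) stop("bad region string: ", region)
    if (m[2] != panel$chrom)
      stop("region chromosome ", m[2], " does not match panel ",
           panel$chrom)
    region <- as.numeric(m[3:4])
  }
  in_reg <- which(panel$positions >= region[1] & panel$positions <= region[2])
  if (!length(in_reg)) {
    warning("extract_haplotypes: no sites in region")
    return(list(classes = data.frame(label = character(),
                                     allele_string = character(),
                                     count = integer()),
                assignment = character(0), sites = numeric(0),
                n_excluded = 0L))
  }
  sub <- panel$alleles[, in_reg, drop = FALSE]
  maf <- pmin(colMeans(sub, na.rm = TRUE), 1 - colMeans(sub, na.rm = TRUE))
  keep <- !is.na(maf) & maf > maf_min
  if (!any(keep)) {
    warning("extract_haplotypes: no sites pass the MAF filter")
    return(list(classes = data.frame(label = character(),
                                     allele_string = character(),
                                     count = integer()),
                assignment = character(0), sites = numeric(0),
                n_excluded = 0L))
  }
  sub <- sub[, keep, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  strings <- apply(sub[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- table(strings)
  ord <- order(-as.integer(tab), names(tab))
  classes <- data.frame(label = as.character(utils::as.roman(
                          seq_along(ord))),
                        allele_string = names(tab)[ord],
                        count = as.integer(tab)[ord])
  assignment <- classes$label[match(strings, classes$allele_string)]
  names(assignment) <- rownames(sub)[complete]
  list(classes = classes, assignment = assignment,
       sites = panel$positions[in_reg][keep],
       n_excluded = sum(!complete))
}

#' Haplotype frequency table by population
#'
#' @param haps Result of [extract_haplotypes()].
#' @param popmap A `PopulationMap` covering every sample in the panel.
#' @return List of matrices `counts` and `proportions`
#'   (class x population); proportions divide by each population's number
#'   of included haplotypes.
#' @export
hap_frequency_table <- function(haps, popmap) {
  hap_samples <- sub("_[12]$", "", names(haps$assignment))
  unknown <- setdiff(hap_samples, names(popmap$assignments))
  if (length(unknown))
    stop("hap_frequency_table: samples missing from population map: ",
         paste(unique(unknown), collapse = ", "))
  pops <- popmap$assignments[hap_samples]
  counts <- table(factor(haps$assignment, levels = haps$classes$label),
                  pops)
  counts <- unclass(counts)
  props <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  list(counts = counts, proportions = props)
}

hamming_dist <- function(s1, s2) {
  sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
}

#' Minimum-spanning haplotype network
#'
#' Kruskal MST over pairwise Hamming distances between class allele
#' strings, with deterministic tie-breaks (edge weight, then lexicographic
#' node-pair order), plus every non-tree edge whose weight equals the
#' largest weight on the tree path between its endpoints (the alternative
#' links of a minimum-spanning network).
#'
#' @param classes Class `data.frame` from [extract_haplotypes()].
#' @return List with `nodes` (`label`, `count`) and `edges` (`node_a`,
#'   `node_b`, `hamming`, `is_alternative`); a single class yields a
#'   single-node network with no edges.
#' @export
build_network <- function(classes) {
  n <- nrow(classes)
  if (n < 1) stop("build_network: no haplotype classes")
  nodes <- classes[c("label", "count")]
  empty_edges <- data.frame(node_a = character(), node_b = character(),
                            hamming = integer(),
                            is_alternative = logical())
  if (n == 1) return(list(nodes = nodes, edges = empty_edges))
  pairs <- utils::combn(n, 2)
  w <- apply(pairs, 2, function(ij)
    hamming_dist(classes$allele_string[ij[1]], classes$allele_string[ij[2]]))
  ord <- order(w, classes$label[pairs[1, ]], classes$label[pairs[2, ]])
  comp <- seq_len(n)
  in_mst <- rep(FALSE, ncol(pairs))
  for (e in ord) {
    a <- pairs[1, e]; b <- pairs[2, e]
    if (comp[a] != comp[b]) {
      in_mst[e] <- TRUE
      comp[comp == comp[b]] <- comp[a]
    }
  }
  # adjacency over MST edges for path-max queries
  mst_edges <- which(in_mst)
  adj <- vector("list", n)
  for (e in mst_edges) {
    a <- pairs[1, e]; b <- pairs[2, e]
    adj[[a]] <- rbind(adj[[a]], c(b, w[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[e]))
  }
  path_max <- function(from, to) {
    # DFS on the tree tracking the max edge weight en route
    stack <- list(c(from, -1L, 0L))  # node, parent, max weight so far
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (top[1] == to) return(top[3])
      nb <- adj[[top[1]]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        if (nb[k, 1] != top[2])
          stack[[length(stack) + 1L]] <- c(nb[k, 1], top[1],
                                           max(top[3], nb[k, 2]))
      }
    }
    stop("build_network: MST not connected")  # cannot happen
  }
  is_alt <- rep(FALSE, ncol(pairs))
  for (e in which(!in_mst)) {
    if (w[e] == path_max(pairs[1, e], pairs[2, e])) is_alt[e] <- TRUE
  }
  keep <- in_mst | is_alt
  list(nodes = nodes,
       edges = data.frame(node_a = classes$label[pairs[1, keep]],
                          node_b = classes$label[pairs[2, keep]],
                          hamming = as.integer(w[keep]),
                          is_alternative = is_alt[keep]))
}

#' Two-haplogroup bipartition of a haplotype network
#'
#' Removes the largest-weight MST edge (ties broken by weight, then
#' lexicographic node pair) and labels the two resulting components "A"
#' (the component holding the most haplotypes) and "B".
#'
#' @param network Result of [build_network()].
#' @return Named character vector: class label -> haplogroup.
#' @export
hap_groups <- function(network) {
  edges <- network$edges[!network$edges$is_alternative, , drop = FALSE]
  labels <- network$nodes$label
  if (!nrow(edges))
    return(stats::setNames(rep("A", length(labels)), labels))
  ord <- order(-edges$hamming, edges$node_a, edges$node_b)
  cut <- ord[1]
  keep <- edges[-cut, , drop = FALSE]
  comp <- stats::setNames(seq_along(labels), labels)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(keep))) {
      a <- keep$node_a[k]; b <- keep$node_b[k]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- tapply(network$nodes$count, comp[labels], sum)
  big <- names(sizes)[which.max(sizes)]
  stats::setNames(ifelse(comp[labels] == as.integer(big), "A", "B"), labels)
}
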
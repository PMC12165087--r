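# Forward-in-time Wright-Fisher simulator of two diverged domestic
# populations (P_A, P_B), their conspecific wild relatives (W_A, W_B) and a
# distant outgroup (OUT), with dated admixture pulses whose donor-derived
# material is tracked exactly as segment paintings.
#
# Population tree (generations before present, forward in time):
#   root ──out_split──> OUT + ingroup
#   ingroup ──split_generations──> ancA + ancB
#   ancA/ancB ──wild_split──> (P_A, W_A) / (P_B, W_B)
# Pulses replace a fraction f of the recipient gene pool with donor gametes
# at their stated generation; every donor-derived segment carries the pulse
# label forward through recombination, so truth tracts are exact.
#
# Haplotypes are stored as paintings (breakpoints + founder id + ancestry
# label per segment) plus a set of mutation tokens; sequences are only
# materialised at export. This keeps per-generation cost proportional to the
# handful of recombination events, not to the number of sites.

#' Admixture pulse specification
#'
#' @param generation Generations before present at which the pulse occurs
#'   (the recipient generation born at that time draws each gamete from the
#'   donor pool with probability `proportion`).
#' @param donor,recipient Population labels among
#'   `P_A`, `P_B`, `W_A`, `W_B`, `OUT`.
#' @param proportion Pulse fraction `f` in `[0, 1]`.
#' @return A `pulse_spec` list.
#' @export
pulse_spec <- function(generation, donor, recipient, proportion) {
  structure(list(generation = as.integer(generation), donor = donor,
                 recipient = recipient, proportion = proportion),
            class = "pulse_spec")
}

SIM_POPS <- c("P_A", "P_B", "W_A", "W_B", "OUT")

#' Simulation configuration
#'
#' Defaults describe a desk-scale world: a 5 Mb chromosome with a few
#' thousand segregating sites and 30-60 haplotypes per population, small
#' enough that the full pipeline runs in minutes. Split times (wild 600 /
#' domestic 3000 / outgroup 4500 generations) and effective sizes
#' (census x time_scale, about 6000) are chosen so that pulse-derived IBD
#' paths (tens of meioses) fall well inside the detectable tract-length
#' horizon `1 / (r * min_length)` (500 meioses at the 1e-8 per-bp
#' crossover rate and the 200 kb tract floor) while background coalescent
#' paths (>= 1200 meioses) fall outside it; no claim is made that the
#' demography matches any real species.
#'
#' @param chromosome_length Chromosome length in bp.
#' @param n_sites Target number of segregating sites at export.
#' @param pop_sizes Named vector of haplotype counts for
#'   `P_A`, `P_B`, `W_A`, `W_B`, `OUT` (each even, >= 2).
#' @param split_generations Generations since the A/B-lineage split.
#' @param pulse_specs List of [pulse_spec()] objects; every pulse generation
#'   must be younger than `wild_split_generations`.
#' @param mutation_rate Per-site per-generation mutation probability.
#' @param recombination_rate Per-bp per-generation crossover probability.
#' @param seed Integer RNG seed; identical configs reproduce bit-for-bit.
#' @param wild_split_generations Generations since each domestic population
#'   split from its wild relative (default `ceiling(split / 6)`). Must be
#'   much older than any pulse (background IBD sharing has to decay below
#'   the detectable tract-length scale) yet much younger than the A/B
#'   split: the drift accumulated between the two is what separates the
#'   f_d values of the two arrangements and powers direction inference.
#' @param outgroup_split_generations Generations since the outgroup split
#'   (default `ceiling(1.5 * split)`).
#' @param census_sizes Breeding-pool haplotype counts used during the
#'   forward simulation (`terminal` for the two domestic populations,
#'   `wild` for the two wild backgrounds, `ancestral` for root/ancestral
#'   pools, `OUT` for the outgroup); `pop_sizes` haplotypes are sampled
#'   from these pools at export. Census sizes well above the sample sizes
#'   keep post-split drift realistic (the donor fraction of an f = 0.2
#'   pulse stays near 0.2 instead of wandering, as it would at census
#'   40-60). Domestic pools are kept smaller than wild pools on purpose:
#'   donor-side coalescence is what makes introgressed tracts match
#'   present-day donor haplotypes, while diverse wild pools keep background
#'   IBD sharing low and stable.
#' @param time_scale Coalescent-style rescaling factor `c`: the engine
#'   runs `T / c` internal generations at rates `c * mutation_rate` and
#'   `c * recombination_rate`, so the effective population size is
#'   `census * c` while drift, recombination and mutation per nominal
#'   generation are preserved in distribution. All user-facing times stay
#'   nominal.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(chromosome_length = 5e6,
                       n_sites = 24000,
                       pop_sizes = c(P_A = 60, P_B = 60, W_A = 60, W_B = 60,
                                     OUT = 30),
                       split_generations = 3000,
                       pulse_specs = list(),
                       mutation_rate = 2e-8,
                       recombination_rate = 1e-8,
                       seed = 1,
                       wild_split_generations = NULL,
                       outgroup_split_generations = NULL,
                       census_sizes = c(terminal = 200, wild = 200,
                                        ancestral = 300, OUT = 100),
                       time_scale = 15) {
  cfg <- list(chromosome_length = chromosome_length, n_sites = n_sites,
              pop_sizes = pop_sizes, split_generations = split_generations,
              pulse_specs = pulse_specs, mutation_rate = mutation_rate,
              recombination_rate = recombination_rate, seed = as.integer(seed),
              wild_split_generations = if (is.null(wild_split_generations))
                ceiling(split_generations / 6) else wild_split_generations,
              outgroup_split_generations =
                if (is.null(outgroup_split_generations))
                  ceiling(1.5 * split_generations)
                else outgroup_split_generations,
              census_sizes = census_sizes, time_scale = time_scale)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$chromosome_length <= 0)
    stop("sim_config: chromosome_length must be positive")
  if (cfg$n_sites < 1) stop("sim_config: n_sites must be >= 1")
  if (!all(SIM_POPS %in% names(cfg$pop_sizes)))
    stop("sim_config: pop_sizes must name all of ",
         paste(SIM_POPS, collapse = ", "))
  if (any(cfg$pop_sizes < 2)) stop("sim_config: pop_sizes must all be >= 2")
  if (any(cfg$pop_sizes %% 2 != 0))
    stop("sim_config: pop_sizes must be even (haplotypes pair into diploids)")
  if (is.null(cfg$time_scale) || cfg$time_scale < 1)
    stop("sim_config: time_scale must be >= 1")
  if (!all(c("terminal", "ancestral", "OUT") %in% names(cfg$census_sizes)))
    stop("sim_config: census_sizes must name terminal, ancestral, OUT")
  if (!"wild" %in% names(cfg$census_sizes))
    cfg$census_sizes[["wild"]] <- cfg$census_sizes[["terminal"]]
  if (cfg$census_sizes[["terminal"]] < max(cfg$pop_sizes[c("P_A", "P_B")]) ||
      cfg$census_sizes[["wild"]] < max(cfg$pop_sizes[c("W_A", "W_B")]) ||
      cfg$census_sizes[["OUT"]] < cfg$pop_sizes[["OUT"]])
    stop("sim_config: census_sizes must be >= the sampled pop_sizes")
  if (cfg$mutation_rate < 0) stop("sim_config: mutation_rate must be >= 0")
  if (cfg$recombination_rate < 0)
    stop("sim_config: recombination_rate must be >= 0")
  if (cfg$wild_split_generations >= cfg$split_generations)
    stop("sim_config: wild_split_generations must be < split_generations")
  if (cfg$outgroup_split_generations <= cfg$split_generations)
    stop("sim_config: outgroup_split_generations must be > split_generations")
  for (p in cfg$pulse_specs) {
    if (p$proportion < 0 || p$proportion > 1)
      stop("sim_config: pulse proportion must be in [0, 1], got ",
           p$proportion)
    if (p$generation >= cfg$split_generations)
      stop("sim_config: pulse generation (", p$generation,
           ") must be < split_generations (", cfg$split_generations, ")")
    if (p$generation >= cfg$wild_split_generations)
      stop("sim_config: pulse generation (", p$generation,
           ") must be < wild_split_generations (",
           cfg$wild_split_generations, ")")
    if (p$generation < 0) stop("sim_config: pulse generation must be >= 0")
    if (!p$donor %in% SIM_POPS || !p$recipient %in% SIM_POPS)
      stop("sim_config: pulse donor/recipient must be one of ",
           paste(SIM_POPS, collapse = ", "))
    if (p$donor == p$recipient)
      stop("sim_config: pulse donor and recipient must differ")
  }
  cfg
}

# A haplotype painting: bp = segment start breakpoints (first is 0),
# fid = founder id per segment, anc = ancestry label per segment
# (0 = native, k = index into pulse_specs), tok = mutation token ids.
new_hap <- function(fid, L, anc = 0L) {
  list(bp = 0, fid = as.integer(fid), anc = as.integer(anc),
       tok = integer(0))
}

# Recombine two paintings at sorted crossover positions xpos (length >= 1).
recombine_haps <- function(h1, h2, xpos, L, tok_pos) {
  if (length(xpos) == 1L) return(recombine_1x(h1, h2, xpos, L, tok_pos))
  bounds <- c(0, xpos, L)
  n_iv <- length(bounds) - 1L
  bp_out <- numeric(0); fid_out <- integer(0); anc_out <- integer(0)
  for (j in seq_len(n_iv)) {
    src <- if (j %% 2L == 1L) h1 else h2
    lo <- bounds[j]; hi <- bounds[j + 1L]
    if (lo >= hi) next
    i0 <- findInterval(lo, src$bp)
    i1 <- findInterval(hi, src$bp, left.open = TRUE)
    idx <- i0:i1
    seg_bp <- src$bp[idx]; seg_bp[1L] <- lo
    bp_out <- c(bp_out, seg_bp)
    fid_out <- c(fid_out, src$fid[idx])
    anc_out <- c(anc_out, src$anc[idx])
  }
  # merge adjacent segments with identical (fid, anc)
  if (length(bp_out) > 1L) {
    same <- c(FALSE, fid_out[-1L] == fid_out[-length(fid_out)] &
                anc_out[-1L] == anc_out[-length(anc_out)])
    keep <- !same
    bp_out <- bp_out[keep]; fid_out <- fid_out[keep]; anc_out <- anc_out[keep]
  }
  tok <- integer(0)
  if (length(h1$tok)) {
    iv <- findInterval(tok_pos[h1$tok], bounds, left.open = TRUE)
    tok <- h1$tok[iv %% 2L == 1L & iv >= 1L & iv <= n_iv]
  }
  if (length(h2$tok)) {
    iv <- findInterval(tok_pos[h2$tok], bounds, left.open = TRUE)
    tok <- c(tok, h2$tok[iv %% 2L == 0L & iv >= 1L & iv <= n_iv])
  }
  list(bp = bp_out, fid = fid_out, anc = anc_out, tok = tok)
}

# Single-crossover fast path (the common case at desk-scale rates).
recombine_1x <- function(h1, h2, x, L, tok_pos) {
  i1 <- findInterval(x, h1$bp)
  i2 <- findInterval(x, h2$bp, left.open = TRUE)
  n2 <- length(h2$bp)
  bp <- c(h1$bp[seq_len(i1)], if (i2 <= n2) h2$bp[i2:n2])
  fid <- c(h1$fid[seq_len(i1)], if (i2 <= n2) h2$fid[i2:n2])
  anc <- c(h1$anc[seq_len(i1)], if (i2 <= n2) h2$anc[i2:n2])
  bp[i1 + 1L] <- x
  if (length(bp) > i1 && fid[i1 + 1L] == fid[i1] && anc[i1 + 1L] == anc[i1]) {
    bp <- bp[-(i1 + 1L)]; fid <- fid[-(i1 + 1L)]; anc <- anc[-(i1 + 1L)]
  }
  tok <- c(h1$tok[tok_pos[h1$tok] <= x], h2$tok[tok_pos[h2$tok] > x])
  list(bp = bp, fid = fid, anc = anc, tok = tok)
}

# One generation of random mating within a haplotype pool. Returns the
# offspring pool; `from_donor` marks gametes drawn from a donor pool, whose
# segments are relabelled with `pulse_id`.
next_generation <- function(pop, size, r_per_meiosis, state,
                            donor_pop = NULL, f = 0, pulse_id = 0L) {
  H <- length(pop)
  p1 <- sample.int(H, size, replace = TRUE)
  p2 <- sample.int(H, size, replace = TRUE)
  clash <- p2 == p1
  while (any(clash)) {
    p2[clash] <- sample.int(H, sum(clash), replace = TRUE)
    clash <- p2 == p1
  }
  nx <- stats::rpois(size, r_per_meiosis)
  from_donor <- if (!is.null(donor_pop) && f > 0)
    stats::runif(size) < f else rep(FALSE, size)
  Hd <- length(donor_pop)
  d1 <- d2 <- integer(size)
  if (any(from_donor)) {
    nd <- sum(from_donor)
    d1[from_donor] <- sample.int(Hd, nd, replace = TRUE)
    d2[from_donor] <- sample.int(Hd, nd, replace = TRUE)
    cl <- from_donor & d2 == d1
    while (any(cl)) {
      d2[cl] <- sample.int(Hd, sum(cl), replace = TRUE)
      cl <- from_donor & d2 == d1
    }
  }
  out <- vector("list", size)
  L <- state$L
  for (i in seq_len(size)) {
    if (from_donor[i]) {
      h1 <- donor_pop[[d1[i]]]; h2 <- donor_pop[[d2[i]]]
    } else {
      h1 <- pop[[p1[i]]]; h2 <- pop[[p2[i]]]
    }
    h <- if (nx[i] == 0L) h1
         else {
           xs <- stats::runif(nx[i], 0, L)
           if (nx[i] > 1L) xs <- sort.int(xs)
           recombine_haps(h1, h2, xs, L, state$tok_pos)
         }
    if (from_donor[i]) h$anc <- rep(pulse_id, length(h$fid))
    out[[i]] <- h
  }
  out
}

# Sprinkle this generation's new mutations over a pool (in place).
add_mutations <- function(pop, mu_L, state) {
  n_new <- stats::rpois(1, mu_L * length(pop))
  if (n_new == 0L) return(list(pop = pop, state = state))
  pos <- stats::runif(n_new, 0, state$L)
  ids <- state$next_tok + seq_len(n_new) - 1L
  state$tok_pos[ids] <- pos
  state$next_tok <- state$next_tok + n_new
  who <- sample.int(length(pop), n_new, replace = TRUE)
  for (k in seq_len(n_new)) {
    h <- who[k]
    pop[[h]]$tok <- c(pop[[h]]$tok, ids[k])
  }
  list(pop = pop, state = state)
}

#' Simulate the five-population history with exact donor-tract tracking
#'
#' Runs the forward Wright-Fisher model described in the package vignette
#' and returns present-day phased panels for all five populations together
#' with the exact donor-derived tracts created by the configured pulses.
#'
#' @param config A [sim_config()].
#' @return A list with elements `panels` (named list of
#'   [haplotype_panel()]s), `tracts` (`data.frame` with columns `sample`,
#'   `hap`, `chrom`, `start`, `end`, `donor_pop`, `pulse_generation`;
#'   0-based half-open), `popmap` (a [pop_map()]) and `config`.
#' @export
simulate_history <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  L <- config$chromosome_length
  census <- config$census_sizes
  sc <- config$time_scale
  g_out <- ceiling(config$outgroup_split_generations / sc)
  g_ab <- ceiling(config$split_generations / sc)
  g_wd <- ceiling(config$wild_split_generations / sc)
  r_m <- config$recombination_rate * sc * L
  mu_L <- config$mutation_rate * sc * L

  H_root <- unname(census[["ancestral"]])
  state <- list(L = L, tok_pos = numeric(0), next_tok = 1L)
  pools <- list(root = lapply(seq_len(H_root), function(i) new_hap(i, L)))
  pool_census <- function(pn) {
    switch(pn,
           root = , ingroup = , ancA = , ancB = census[["ancestral"]],
           OUT = census[["OUT"]],
           W_A = , W_B = census[["wild"]],
           census[["terminal"]])
  }
  pulse_gen_internal <- vapply(config$pulse_specs, function(p)
    max(0L, as.integer(round(p$generation / sc))), 0L)
  if (any(pulse_gen_internal >= g_wd))
    stop("sim_config: pulse generation too close to wild_split_generations",
         " at time_scale ", sc)
  pulses_by_gen <- split(seq_along(config$pulse_specs), pulse_gen_internal)
  # daughter pools are founded by random mating within the mother pool at
  # the split generation; pool sizes may therefore change across a split
  splits <- list()
  splits[[as.character(g_out)]] <- list(root = c("OUT", "ingroup"))
  splits[[as.character(g_ab)]] <-
    c(splits[[as.character(g_ab)]], list(ingroup = c("ancA", "ancB")))
  splits[[as.character(g_wd)]] <-
    c(splits[[as.character(g_wd)]],
      list(ancA = c("P_A", "W_A"), ancB = c("P_B", "W_B")))

  for (g in seq(g_out, 1L)) {
    ev <- splits[[as.character(g)]]
    if (!is.null(ev)) {
      for (mother in names(ev)) {
        for (d in ev[[mother]]) {
          pools[[d]] <- next_generation(pools[[mother]], pool_census(d),
                                        r_m, state)
        }
        pools[[mother]] <- NULL
      }
    }
    born <- g - 1L
    gen_pulses <- pulses_by_gen[[as.character(born)]]
    nxt <- list()
    for (pn in names(pools)) {
      donor <- NULL; f <- 0; pid <- 0L
      if (!is.null(gen_pulses)) {
        for (k in gen_pulses) {
          ps <- config$pulse_specs[[k]]
          if (ps$recipient == pn) {
            donor <- pools[[ps$donor]]; f <- ps$proportion; pid <- k
          }
        }
      }
      nxt[[pn]] <- next_generation(pools[[pn]], pool_census(pn), r_m,
                                   state, donor_pop = donor, f = f,
                                   pulse_id = pid)
      if (mu_L > 0) {
        am <- add_mutations(nxt[[pn]], mu_L, state)
        nxt[[pn]] <- am$pop; state <- am$state
      }
    }
    pools <- nxt
  }

  # sample the requested panel sizes from the final census pools
  sampled <- lapply(SIM_POPS, function(pn)
    pools[[pn]][sample.int(length(pools[[pn]]), config$pop_sizes[[pn]])])
  names(sampled) <- SIM_POPS
  export_simulation(sampled, state, config, n_founders = H_root)
}

# Materialise sequences and truth tracts from present-day paintings.
export_simulation <- function(pools, state, config, n_founders) {
  L <- config$chromosome_length
  H_root <- n_founders

  # root standing variation: positions uniform, derived counts ~ 1/k SFS;
  # over-generated, then downsampled to the n_sites target at export
  n_root <- round(config$n_sites * 1.5)
  root_pos <- sort(stats::runif(n_root, 0, L))
  k_counts <- sample(seq_len(H_root - 1L), n_root, replace = TRUE,
                     prob = 1 / seq_len(H_root - 1L))
  root_mat <- matrix(0L, nrow = H_root, ncol = n_root)
  for (j in seq_len(n_root))
    root_mat[sample.int(H_root, k_counts[j]), j] <- 1L

  all_haps <- unlist(pools, recursive = FALSE, use.names = FALSE)
  n_hap <- length(all_haps)
  surv_tok <- sort(unique(unlist(lapply(all_haps, `[[`, "tok"))))
  tok_pos <- state$tok_pos[surv_tok]

  pos_all <- c(root_pos, tok_pos)
  ord <- order(pos_all)
  pos_all <- pos_all[ord]
  src_root <- c(seq_len(n_root), rep(NA_integer_, length(surv_tok)))[ord]
  src_tok <- c(rep(NA_integer_, n_root), surv_tok)[ord]

  geno <- matrix(0L, nrow = n_hap, ncol = length(pos_all))
  root_cols <- which(!is.na(src_root))
  tok_col_of <- stats::setNames(which(!is.na(src_tok)), src_tok[!is.na(src_tok)])
  for (i in seq_len(n_hap)) {
    h <- all_haps[[i]]
    if (length(root_cols)) {
      seg <- findInterval(pos_all[root_cols], h$bp)
      geno[i, root_cols] <- root_mat[cbind(h$fid[seg], src_root[root_cols])]
    }
    if (length(h$tok))
      geno[i, tok_col_of[as.character(h$tok)]] <- 1L
  }

  # integer 1-based positions; drop rounding collisions and fixed sites
  ipos <- floor(pos_all) + 1
  keep <- !duplicated(ipos)
  cs <- colSums(geno)
  keep <- keep & cs > 0L & cs < n_hap
  ipos <- ipos[keep]
  geno <- geno[, keep, drop = FALSE]
  if (length(ipos) > config$n_sites) {
    sub <- sort(sample.int(length(ipos), config$n_sites))
    ipos <- ipos[sub]
    geno <- geno[, sub, drop = FALSE]
  }

  chrom <- "chr1"
  panels <- list()
  offset <- 0L
  popmap_assign <- character(0)
  for (pn in names(pools)) {
    H <- length(pools[[pn]])
    samples <- sprintf("%s_%02d", pn, seq_len(H / 2L))
    panels[[pn]] <- haplotype_panel(chrom, ipos,
                                    geno[offset + seq_len(H), , drop = FALSE],
                                    samples, phased = TRUE, chrom_length = L)
    popmap_assign <- c(popmap_assign, stats::setNames(rep(pn, H / 2L), samples))
    offset <- offset + H
  }

  tracts <- extract_truth_tracts(pools, config, chrom)
  list(panels = panels, tracts = tracts,
       popmap = pop_map(popmap_assign), config = config)
}

extract_truth_tracts <- function(pools, config, chrom) {
  rows <- list()
  for (pn in names(pools)) {
    H <- length(pools[[pn]])
    samples <- sprintf("%s_%02d", pn, seq_len(H / 2L))
    for (i in seq_len(H)) {
      h <- pools[[pn]][[i]]
      if (!any(h$anc != 0L)) next
      bp <- c(h$bp, config$chromosome_length)
      runs <- rle(h$anc)
      ends_idx <- cumsum(runs$lengths)
      starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
      for (r in seq_along(runs$values)) {
        if (runs$values[r] == 0L) next
        ps <- config$pulse_specs[[runs$values[r]]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[ceiling(i / 2)],
          hap = (i - 1L) %% 2L,
          chrom = chrom,
          start = floor(bp[starts_idx[r]]),
          end = floor(bp[ends_idx[r] + 1L]),
          donor_pop = ps$donor,
          pulse_generation = ps$generation)
      }
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), hap = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), donor_pop = character(),
                      pulse_generation = integer()))
  out <- do.call(rbind, rows)
  out[out$end > out$start, , drop = FALSE]
}

#' Simulate a structural-variant genotype table over the five populations
#'
#' A `stratified_fraction` of SVs is constructed with an allele-frequency
#' difference of at least 0.5 between the two domestic populations `P_A`
#' and `P_B`; the remainder follow a neutral null (one shared frequency for
#' all populations). SV classes are drawn with weights matching the
#' relative abundance of deletions, insertions, duplications and inversions
#' in large short-read surveys.
#'
#' @param config A [sim_config()]; supplies chromosome length, population
#'   sizes and the RNG stream (seeded with `config$seed + 1` so SNP and SV
#'   channels are independent but jointly reproducible).
#' @param n_svs Number of SVs (>= 1).
#' @param stratified_fraction Fraction of SVs forced to be stratified.
#' @param tracts Optional truth-tract `data.frame` (from
#'   [simulate_history()]); when `co_place = TRUE`, stratified SVs are
#'   placed inside these tracts.
#' @param co_place Place stratified SVs inside truth tracts.
#' @return An `SVSet`; `info$stratified` flags the constructed stratified
#'   SVs.
#' @export
simulate_sv_table <- function(config, n_svs, stratified_fraction = 0,
                              tracts = NULL, co_place = FALSE) {
  config <- validate_sim_config(config)
  if (n_svs < 1) stop("simulate_sv_table: n_svs must be >= 1")
  if (stratified_fraction < 0 || stratified_fraction > 1)
    stop("simulate_sv_table: stratified_fraction must be in [0, 1]")
  if (co_place && (is.null(tracts) || nrow(tracts) == 0))
    stop("simulate_sv_table: co_place requires a non-empty tract table")
  set.seed(config$seed + 1L)
  L <- config$chromosome_length
  n_strat <- round(n_svs * stratified_fraction)
  stratified <- rep(FALSE, n_svs)
  if (n_strat > 0) stratified[sample.int(n_svs, n_strat)] <- TRUE

  pos <- floor(stats::runif(n_svs, 0, L - 1)) + 1
  if (co_place && any(stratified)) {
    idx <- sample.int(nrow(tracts), sum(stratified), replace = TRUE)
    pos[stratified] <- floor(tracts$start[idx] +
      stats::runif(sum(stratified)) * (tracts$end[idx] - tracts$start[idx])) + 1
  }
  svtype <- sample(SV_CLASSES, n_svs, replace = TRUE,
                   prob = c(79358, 34126, 13637, 2106) / 129227)
  size <- pmin(round(stats::rlnorm(n_svs, log(500), 1.2)), 5e6)
  endv <- pmin(pos + size, L)
  endv[svtype == "INS"] <- pos[svtype == "INS"]

  n_samples <- sum(config$pop_sizes) / 2
  pops <- rep(SIM_POPS, times = config$pop_sizes / 2)
  samples <- unlist(lapply(SIM_POPS, function(pn)
    sprintf("%s_%02d", pn, seq_len(config$pop_sizes[[pn]] / 2L))))

  geno <- matrix(0L, nrow = n_svs, ncol = n_samples)
  for (i in seq_len(n_svs)) {
    if (stratified[i]) {
      lo <- stats::runif(1, 0.0, 0.25)
      hi <- lo + stats::runif(1, 0.5, min(0.75, 1 - lo))
      if (stats::runif(1) < 0.5) { tmp <- lo; lo <- hi; hi <- tmp }
      p <- stats::setNames(rep((lo + hi) / 2, 5), SIM_POPS)
      p["P_A"] <- lo; p["P_B"] <- hi
    } else {
      p <- stats::setNames(rep(stats::runif(1, 0.05, 0.95), 5), SIM_POPS)
    }
    geno[i, ] <- stats::rbinom(n_samples, 2, p[pops])
  }
  info <- data.frame(sv_id = sprintf("sv%04d", seq_len(n_svs)),
                     svtype = svtype, chrom = "chr1", pos = pos, end = endv)
  out <- sv_set(info, geno, samples)
  out$info$stratified <- stratified
  out
}

#' Write a simulated dataset to disk
#'
#' Emits `<prefix>.snps.vcf` (combined phased panel), `<prefix>.svs.vcf`,
#' `<prefix>.truth.bed` (0-based half-open tracts with name column
#' `sample|hap|donor_pop|pulse_generation`) and `<prefix>.popmap.tsv`.
#'
#' @param sim Result of [simulate_history()].
#' @param svs Optional `SVSet` from [simulate_sv_table()].
#' @param out_prefix Output path prefix.
#' @return Named character vector of the files written.
#' @export
write_simulation <- function(sim, svs = NULL, out_prefix = "sim") {
  if (!length(sim$panels)) stop("write_simulation: no panels to write")
  combined <- bind_panels(sim$panels)
  files <- c(snps = paste0(out_prefix, ".snps.vcf"),
             truth = paste0(out_prefix, ".truth.bed"),
             popmap = paste0(out_prefix, ".popmap.tsv"))
  write_phased_vcf(combined, files[["snps"]])
  tr <- sim$tracts
  bed <- data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                    name = if (nrow(tr))
                      paste(tr$sample, tr$hap, tr$donor_pop,
                            tr$pulse_generation, sep = "|") else character(0))
  write_bed(bed, files[["truth"]])
  write_pop_map(sim$popmap, files[["popmap"]])
  if (!is.null(svs)) {
    files[["svs"]] <- paste0(out_prefix, ".svs.vcf")
    write_sv_vcf(svs, files[["svs"]],
                 chrom_length = sim$config$chromosome_length)
  }
  files
}

#' Read a truth-tract BED written by [write_simulation()]
#' @param path Path to the truth BED.
#' @return Tract `data.frame` in the [simulate_history()] layout.
#' @export
read_truth_bed <- function(path) {
  df <- read_bed(path, extra_cols = "name")
  if (!nrow(df))
    return(data.frame(sample = character(), hap = integer(),
                      chrom = character(), start = numeric(),
                      end = numeric(), donor_pop = character(),
                      pulse_generation = integer()))
  parts <- strsplit(df$name, "|", fixed = TRUE)
  data.frame(sample = vapply(parts, `[`, "", 1),
             hap = as.integer(vapply(parts, `[`, "", 2)),
             chrom = df$chrom, start = df$start, end = df$end,
             donor_pop = vapply(parts, `[`, "", 3),
             pulse_generation = as.integer(vapply(parts, `[`, "", 4)))
}
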
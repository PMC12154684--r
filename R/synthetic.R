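# Synthetic subterminal caps with planted truth.
#
# The generator emulates the organisation reported for African great ape
# subterminal heterochromatic caps: tandem arrays of a 32-bp satellite
# monomer (mean uninterrupted array length in the several-hundred-kbp
# range) interdigitated with ~32 kbp segmental-duplication spacer copies,
# satellite CpG methylation much higher than spacer methylation, and
# optional planted interchromosomal exchanges anchored at spacers.

#' Configuration for the synthetic cap simulator
#'
#' Defaults emulate the organisation of real caps: the 32-bp pCht
#' consensus, arrays whose mean length falls in the reported 341-398 kbp
#' range, ~32 kbp spacers, and per-copy unit mutation consistent with
#' satellites that are generally more than 80 percent identical.
#'
#' @param consensus satellite monomer consensus (default [pcht_consensus()]).
#' @param n_arrays arrays per cap; a cap is `n_arrays` arrays alternating
#'   with `n_arrays - 1` spacer copies.
#' @param array_len_mean,array_len_sd mean and sd (bp) of the log-normal
#'   array length distribution (real arrays range from under 10 kbp to
#'   hundreds of kbp, so a right-skewed law is used).
#' @param unit_mutation_rate expected mutation events per base per unit
#'   copy, in `[0, 0.5]`.
#' @param indel_fraction fraction of unit mutation events that are 1-bp
#'   indels rather than substitutions (variant classes are small
#'   insertions, deletions or substitutions).
#' @param spacer_template spacer sequence; `NULL` generates a random
#'   template of `spacer_len` bp from the seed.
#' @param spacer_len template length when generated (~32 kbp for a
#'   Pan-like set; use 34000 for a gorilla-like set).
#' @param spacer_divergence expected substitutions per site per spacer
#'   copy, in `[0, 0.5]`.
#' @param cap_count number of caps to simulate.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `cap_config`.
#' @export
cap_config <- function(consensus = pcht_consensus(), n_arrays = 8,
                       array_len_mean = 370000, array_len_sd = 250000,
                       unit_mutation_rate = 0.02, indel_fraction = 0.1,
                       spacer_template = NULL, spacer_len = 32000,
                       spacer_divergence = 0.01, cap_count = 2, seed = 1) {
  check_dna(consensus, "consensus")
  stopifnot(n_arrays >= 1, array_len_mean > 0, array_len_sd >= 0,
            unit_mutation_rate >= 0, unit_mutation_rate <= 0.5,
            indel_fraction >= 0, indel_fraction <= 1,
            spacer_divergence >= 0, spacer_divergence <= 0.5,
            cap_count >= 1, spacer_len > 0)
  if (!is.null(spacer_template)) check_dna(spacer_template, "spacer_template")
  structure(list(consensus = toupper(consensus), n_arrays = n_arrays,
                 array_len_mean = array_len_mean,
                 array_len_sd = array_len_sd,
                 unit_mutation_rate = unit_mutation_rate,
                 indel_fraction = indel_fraction,
                 spacer_template = spacer_template,
                 spacer_len = spacer_len,
                 spacer_divergence = spacer_divergence,
                 cap_count = cap_count, seed = seed),
            class = "cap_config")
}

# mutate one unit (character vector of bases); events: substitution or
# 1-bp indel (insertion/deletion equally likely)
mutate_unit_chars <- function(chars, n_events, indel_fraction) {
  for (k in seq_len(n_events)) {
    pos <- sample.int(length(chars), 1)
    if (runif(1) < indel_fraction) {
      if (runif(1) < 0.5 && length(chars) > 1) {
        chars <- chars[-pos]
      } else {
        chars <- append(chars, sample(DNA_BASES, 1), after = pos)
      }
    } else {
      chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1)
    }
  }
  chars
}

# substitution-only mutation of a long sequence at per-site probability p
mutate_substitutions <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- seq_chars(seq)
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(DNA_BASES, b), 1), "")
  }
  paste(chars, collapse = "")
}

# draw array lengths (bp) from a log-normal with given mean and sd
draw_array_lengths <- function(n, mean, sd, unit_len) {
  if (sd == 0) return(rep(max(unit_len, round(mean)), n))
  s2 <- log(1 + (sd / mean)^2)
  len <- stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  pmax(unit_len, round(len))
}

#' Simulate a set of subterminal caps with planted truth
#'
#' Each cap is an alternation of satellite arrays (tandem, independently
#' mutated copies of the consensus monomer) and spacer copies
#' (substitution-mutated copies of one template). The returned truth table
#' records every planted unit, array and spacer; the three levels tile
#' each cap exactly. Deterministic given `config$seed`.
#'
#' @param config a [cap_config()].
#' @return list with `caps` (named character vector of sequences), `meta`
#'   (data.frame: cap_id, species, haplotype, chrom, arm), `truth` (list
#'   of interval data.frames `units`, `arrays`, `spacers`, empty
#'   `exchanges`, plus the `consensus` and `spacer_template` used).
#' @export
simulate_cap_set <- function(config) {
  stopifnot(inherits(config, "cap_config"))
  with_seed(config$seed, {
    template <- config$spacer_template
    if (is.null(template)) template <- random_dna(config$spacer_len)
    cons_chars <- seq_chars(config$consensus)
    ulen <- length(cons_chars)
    caps <- character(config$cap_count)
    names(caps) <- sprintf("cap%02d", seq_len(config$cap_count))
    units_l <- list(); arrays_l <- list(); spacers_l <- list()
    for (ci in seq_len(config$cap_count)) {
      cap_id <- names(caps)[ci]
      alens <- draw_array_lengths(config$n_arrays, config$array_len_mean,
                                  config$array_len_sd, ulen)
      n_units <- pmax(1L, as.integer(round(alens / ulen)))
      pieces <- character(0)
      pos <- 0
      u_start <- numeric(0); u_end <- numeric(0)
      a_start <- numeric(0); a_end <- numeric(0)
      s_start <- numeric(0); s_end <- numeric(0)
      for (ai in seq_len(config$n_arrays)) {
        astart <- pos
        nu <- n_units[ai]
        nev <- rbinom(nu, ulen, config$unit_mutation_rate)
        useqs <- character(nu)
        plain <- paste(cons_chars, collapse = "")
        for (ui in seq_len(nu)) {
          if (nev[ui] == 0) {
            useqs[ui] <- plain
          } else {
            useqs[ui] <- paste(mutate_unit_chars(cons_chars, nev[ui],
                                                 config$indel_fraction),
                               collapse = "")
          }
        }
        w <- nchar(useqs)
        ue <- pos + cumsum(w)
        us <- ue - w
        u_start <- c(u_start, us); u_end <- c(u_end, ue)
        pos <- ue[nu]
        a_start <- c(a_start, astart); a_end <- c(a_end, pos)
        pieces <- c(pieces, paste(useqs, collapse = ""))
        if (ai < config$n_arrays) {
          sp <- mutate_substitutions(template, config$spacer_divergence)
          s_start <- c(s_start, pos); s_end <- c(s_end, pos + nchar(sp))
          pos <- pos + nchar(sp)
          pieces <- c(pieces, sp)
        }
      }
      caps[ci] <- paste(pieces, collapse = "")
      units_l[[ci]] <- intervals(cap_id, u_start, u_end,
                                 name = sprintf("unit%d", seq_along(u_start)),
                                 strand = "+")
      arrays_l[[ci]] <- intervals(cap_id, a_start, a_end,
                                  name = sprintf("array%d", seq_along(a_start)),
                                  strand = ".")
      spacers_l[[ci]] <- if (length(s_start)) {
        intervals(cap_id, s_start, s_end,
                  name = sprintf("spacer%d", seq_along(s_start)),
                  strand = ".")
      } else intervals(character(), numeric(), numeric())[0, ]
    }
    hap <- rep(c("h1", "h2"), length.out = config$cap_count)
    chrom <- sprintf("chr%d", (seq_len(config$cap_count) + 1) %/% 2)
    meta <- data.frame(cap_id = names(caps), species = "sim",
                       haplotype = hap, chrom = chrom, arm = "p")
    truth <- list(units = do.call(rbind, units_l),
                  arrays = do.call(rbind, arrays_l),
                  spacers = do.call(rbind, spacers_l),
                  exchanges = data.frame(),
                  consensus = config$consensus,
                  spacer_template = template)
    list(caps = caps, meta = meta, truth = truth)
  })
}

#' Simulate clock-like spacer evolution along a time tree
#'
#' Sequences evolve along `tree` (an ultrametric `phylo` with edge lengths
#' in million years, MY) under a Jukes-Cantor process at `rate`
#' substitutions per site per MY: on a branch of length `t` each site is
#' redrawn uniformly from the four bases with probability
#' `1 - exp(-4 * rate * t / 3)`, so two tips with TMRCA `T` have expected
#' p-distance `3/4 * (1 - exp(-8 * rate * T / 3))`. Substitution-only, so
#' the tip sequences are an alignment as-is.
#'
#' @param tree ultrametric `phylo`, edge lengths in MY.
#' @param rate substitutions per site per MY.
#' @param length sequence length, bp.
#' @param seed integer seed.
#' @return list with `seqs` (named character vector, one per tip) and
#'   `tree` (the input truth genealogy).
#' @export
simulate_spacer_evolution <- function(tree, rate, length, seed = 1) {
  stopifnot(inherits(tree, "phylo"), rate >= 0, length > 0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    nodes <- vector("list", ntip + tree$Nnode)
    nodes[[root]] <- sample(DNA_BASES, length, replace = TRUE)
    # preorder edge traversal so parents are filled before children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (i in seq_len(nrow(edges))) {
      parent <- nodes[[edges[i, 1]]]
      t <- elen[i]
      q <- 1 - exp(-4 * rate * t / 3)
      child <- parent
      hit <- which(runif(length) < q)
      if (length(hit)) {
        child[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
      }
      nodes[[edges[i, 2]]] <- child
    }
    seqs <- vapply(seq_len(ntip), function(i) paste(nodes[[i]], collapse = ""),
                   "")
    names(seqs) <- tree$tip.label
    list(seqs = seqs, tree = tree)
  })
}

#' Random clock (ultrametric) tree
#'
#' Coalescent topology rescaled to a fixed root age; convenience generator
#' for clock simulations.
#'
#' @param n_tips number of tips.
#' @param depth root age (MY).
#' @param seed integer seed.
#' @return an ultrametric `phylo` with tip labels `t1..tn`.
#' @export
random_clock_tree <- function(n_tips, depth, seed = 1) {
  with_seed(seed, {
    tr <- ape::rcoal(n_tips)
    tr$edge.length <- tr$edge.length * depth /
      max(ape::node.depth.edgelength(tr))
    tr
  })
}

#' Plant an ectopic exchange between two simulated caps
#'
#' Replaces an acceptor cap segment by a copy of a donor cap segment. Both
#' segment endpoints are anchored at spacer midpoints (the `spacer_from`-th
#' and `spacer_to`-th spacers of each cap), emulating exchanges whose
#' breakpoints fall within SD spacers; `offset` shifts both endpoints by a
#' fixed amount (e.g. into the arrays) for negative controls. The acceptor
#' truth table is re-sliced so truth intervals still tile the modified cap,
#' and the exchange (with its two acceptor breakpoints) is recorded.
#'
#' @param capset output of [simulate_cap_set()].
#' @param donor_id,acceptor_id cap ids.
#' @param spacer_from,spacer_to 1-based spacer indices (from < to).
#' @param divergence additional substitutions/site applied to the copied
#'   segment (0 keeps it identical to the donor).
#' @param offset bp added to both cut points.
#' @param seed integer seed (used when `divergence > 0`).
#' @return the modified capset; `truth$exchanges` gains one row.
#' @export
plant_exchange <- function(capset, donor_id, acceptor_id, spacer_from,
                           spacer_to, divergence = 0, offset = 0, seed = 1) {
  stopifnot(spacer_from < spacer_to, divergence >= 0)
  sp_d <- capset$truth$spacers
  sp_d <- sp_d[sp_d$seq_id == donor_id, , drop = FALSE]
  sp_a <- capset$truth$spacers
  sp_a <- sp_a[sp_a$seq_id == acceptor_id, , drop = FALSE]
  if (max(spacer_from, spacer_to) > min(nrow(sp_d), nrow(sp_a))) {
    stop("spacer index out of range", call. = FALSE)
  }
  mid <- function(df, i) floor((df$start[i] + df$end[i]) / 2)
  cut_d1 <- mid(sp_d, spacer_from) + offset
  cut_d2 <- mid(sp_d, spacer_to) + offset
  cut_a1 <- mid(sp_a, spacer_from) + offset
  cut_a2 <- mid(sp_a, spacer_to) + offset
  donor_seq <- capset$caps[[donor_id]]
  acc_seq <- capset$caps[[acceptor_id]]
  stopifnot(cut_d2 <= nchar(donor_seq), cut_a2 <= nchar(acc_seq))
  segment <- substr(donor_seq, cut_d1 + 1, cut_d2)
  if (divergence > 0) {
    segment <- with_seed(seed, mutate_substitutions(segment, divergence))
  }
  new_seq <- paste0(substr(acc_seq, 1, cut_a1), segment,
                    substr(acc_seq, cut_a2 + 1, nchar(acc_seq)))
  capset$caps[[acceptor_id]] <- new_seq
  seg_len <- nchar(segment)
  shift <- (cut_a1 + seg_len) - cut_a2
  reslice <- function(df) {
    left <- df[df$seq_id != acceptor_id, , drop = FALSE]
    a <- df[df$seq_id == acceptor_id, , drop = FALSE]
    keep_l <- a[a$start < cut_a1, , drop = FALSE]
    keep_l$end <- pmin(keep_l$end, cut_a1)
    keep_r <- a[a$end > cut_a2, , drop = FALSE]
    keep_r$start <- pmax(keep_r$start, cut_a2)
    keep_r$start <- keep_r$start + shift
    keep_r$end <- keep_r$end + shift
    d <- df[df$seq_id == donor_id, , drop = FALSE]
    mid_part <- d[d$end > cut_d1 & d$start < cut_d2, , drop = FALSE]
    if (nrow(mid_part)) {
      mid_part$start <- pmax(mid_part$start, cut_d1) + (cut_a1 - cut_d1)
      mid_part$end <- pmin(mid_part$end, cut_d2) + (cut_a1 - cut_d1)
      mid_part$seq_id <- acceptor_id
    }
    out <- rbind(left, keep_l, mid_part, keep_r)
    out[order(out$seq_id, out$start), , drop = FALSE]
  }
  capset$truth$units <- reslice(capset$truth$units)
  capset$truth$arrays <- reslice(capset$truth$arrays)
  capset$truth$spacers <- reslice(capset$truth$spacers)
  ex <- data.frame(donor = donor_id, acceptor = acceptor_id,
                   acc_start = cut_a1, acc_end = cut_a1 + seg_len,
                   donor_start = cut_d1, donor_end = cut_d2,
                   spacer_from = spacer_from, spacer_to = spacer_to,
                   divergence = divergence)
  capset$truth$exchanges <- rbind(capset$truth$exchanges, ex)
  capset
}

#' Simulate a CpG methylation track over a cap set
#'
#' CpG sites are placed every `cpg_spacing` bp; the methylated fraction at
#' each site is drawn from a normal centred on the region-level mean
#' (satellite arrays vs spacers), truncated to `[0,1]`. The default
#' satellite level matches a gorilla-like 83.3 percent average; spacers
#' default to the hypomethylated ~40 percent regime.
#'
#' @param capset output of [simulate_cap_set()].
#' @param level_satellite,level_spacer region means, in `[0,1]`.
#' @param noise_sd per-site normal noise sd before truncation.
#' @param cpg_spacing bp between simulated CpG sites.
#' @param coverage read coverage reported per site.
#' @param seed integer seed.
#' @return methylation data.frame (seq_id, start, end, coverage,
#'   methylated_fraction), bedMethyl-serialisable.
#' @export
simulate_methylation <- function(capset, level_satellite = 0.833,
                                 level_spacer = 0.40, noise_sd = 0.05,
                                 cpg_spacing = 50, coverage = 30, seed = 1) {
  stopifnot(level_satellite >= 0, level_satellite <= 1,
            level_spacer >= 0, level_spacer <= 1, noise_sd >= 0)
  with_seed(seed, {
    out <- lapply(names(capset$caps), function(cap_id) {
      len <- nchar(capset$caps[[cap_id]])
      pos <- seq(0, len - 2, by = cpg_spacing)
      arr <- capset$truth$arrays
      arr <- arr[arr$seq_id == cap_id, , drop = FALSE]
      arr <- arr[order(arr$start), , drop = FALSE]
      in_array <- rep(FALSE, length(pos))
      if (nrow(arr)) {
        idx <- findInterval(pos, arr$start)
        in_array <- idx >= 1 & pos < arr$end[pmax(idx, 1)]
      }
      mu <- ifelse(in_array, level_satellite, level_spacer)
      frac <- pmin(1, pmax(0, rnorm(length(pos), mu, noise_sd)))
      data.frame(seq_id = cap_id, start = pos, end = pos + 2,
                 coverage = coverage, methylated_fraction = frac)
    })
    do.call(rbind, out)
  })
}

#' Simulate a variant catalog with planted co-occurrence groups
#'
#' Generates a satellite variant catalog in which variants fall into
#' `n_groups` co-occurrence groups: variants of one group are concentrated
#' in that group's caps. Used to exercise variant clustering with known
#' truth.
#'
#' @param n_caps number of caps.
#' @param n_groups number of planted variant groups.
#' @param variants_per_group variants in each group.
#' @param units_per_cap total unit count per cap.
#' @param background fraction of each cap's units drawn from all variants
#'   uniformly (0 gives perfectly separable groups).
#' @param seed integer seed.
#' @return a `variant_catalog` (see [classify_variants()]) with an extra
#'   `truth_group` integer vector (per variant).
#' @export
simulate_variant_catalog <- function(n_caps = 20, n_groups = 6,
                                     variants_per_group = 25,
                                     units_per_cap = 5000,
                                     background = 0.02, seed = 1) {
  with_seed(seed, {
    n_var <- n_groups * variants_per_group
    group <- rep(seq_len(n_groups), each = variants_per_group)
    cap_group <- rep(seq_len(n_groups), length.out = n_caps)
    counts <- matrix(0, n_caps, n_var,
                     dimnames = list(sprintf("cap%02d", seq_len(n_caps)),
                                     sprintf("v%d", seq_len(n_var))))
    abundance <- rgamma(n_var, shape = 2)  # per-variant, shared across caps
    for (ci in seq_len(n_caps)) {
      w <- abundance * (group == cap_group[ci])
      w <- (1 - background) * w / sum(w) + background / n_var
      counts[ci, ] <- as.numeric(stats::rmultinom(1, units_per_cap, w))
    }
    total <- colSums(counts)
    catalog <- list(variants = data.frame(variant_id = seq_len(n_var),
                                          sequence = NA_character_,
                                          count = total),
                    counts = counts, truth_group = group,
                    truth_cap_group = cap_group)
    class(catalog) <- "variant_catalog"
    catalog
  })
}

#' Simulate windows with planted higher-order block archetypes
#'
#' Builds per-window satellite unit sets whose variant-cluster composition
#' follows one of `n_types` planted archetypes, to exercise the
#' second-step (block typing) k-means with known truth.
#'
#' @param n_caps number of caps.
#' @param windows_per_cap 20 kbp windows per cap.
#' @param n_types planted archetypes (block types).
#' @param n_clusters variant clusters the compositions are defined over.
#' @param units_per_window units per window.
#' @param purity weight of the archetype's dominant clusters (rest spread
#'   uniformly).
#' @param window bp per window.
#' @param seed integer seed.
#' @return list with `units` (seq_id, start, end, cluster), `cap_extents`
#'   interval data.frame, and `truth` (per-window archetype labels).
#' @export
simulate_block_windows <- function(n_caps = 20, windows_per_cap = 40,
                                   n_types = 8, n_clusters = 6,
                                   units_per_window = 300, purity = 0.9,
                                   window = 20000, seed = 1) {
  stopifnot(n_types >= 2, n_clusters >= 2)
  with_seed(seed, {
    # archetypes: near-pure single clusters first, then balanced pairs
    arch <- matrix((1 - purity) / (n_clusters - 1), n_types, n_clusters)
    for (ty in seq_len(n_types)) {
      if (ty <= n_clusters) {
        arch[ty, ty] <- purity
      } else {
        pair <- c((ty - n_clusters - 1) %% n_clusters + 1,
                  (ty - n_clusters) %% n_clusters + 1)
        arch[ty, ] <- (1 - purity) / max(1, n_clusters - 2)
        arch[ty, pair] <- purity / 2
      }
      arch[ty, ] <- arch[ty, ] / sum(arch[ty, ])
    }
    units_l <- list(); truth_l <- list()
    for (ci in seq_len(n_caps)) {
      cap_id <- sprintf("cap%02d", ci)
      types <- sample(rep(seq_len(n_types), length.out = windows_per_cap))
      for (wi in seq_len(windows_per_cap)) {
        cnt <- as.numeric(stats::rmultinom(1, units_per_window,
                                           arch[types[wi], ]))
        cl <- rep(seq_len(n_clusters), cnt)
        w0 <- (wi - 1) * window
        pos <- sort(sample.int(window - 32, length(cl)))
        units_l[[length(units_l) + 1]] <-
          data.frame(seq_id = cap_id, start = w0 + pos, end = w0 + pos + 32,
                     cluster = sample(cl))
      }
      truth_l[[ci]] <- data.frame(seq_id = cap_id,
                                  start = (seq_len(windows_per_cap) - 1) * window,
                                  end = seq_len(windows_per_cap) * window,
                                  type = types)
    }
    extents <- intervals(sprintf("cap%02d", seq_len(n_caps)), 0,
                         windows_per_cap * window)
    list(units = do.call(rbind, units_l), cap_extents = extents,
         truth = do.call(rbind, truth_l))
  })
}
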
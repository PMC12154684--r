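# Euchromatin-heterochromatin boundary definition, insertion calling
# from syntenic alignment, methylation profiling and density folds.

#' Define euchromatin-boundary regions
#'
#' For a p-arm cap `[s,e)` the boundary is the `width` bp immediately
#' proximal: `[e, e+width)`; for a q-arm cap, `[s-width, s)`. Arms
#' without a cap get the terminal `width` bp of the chromosome
#' (anchor "chromosome_tip"). Regions are clamped to the chromosome and
#' never overlap their cap. The `transition` column marks which region
#' edge touches the heterochromatin ("start" for p-arms and left tips,
#' "end" for q-arms and right tips), so profiles can be oriented
#' heterochromatin-to-euchromatin.
#'
#' @param caps interval data.frame of cap extents with an `arm` column
#'   ("p" or "q"); `seq_id` is the chromosome.
#' @param chrom_sizes named numeric vector of chromosome lengths; every
#'   chromosome present gets two boundary regions (capped or tip).
#' @param width region width, bp.
#' @return interval data.frame with `anchor`, `arm` and `transition`
#'   columns.
#' @export
define_boundary_regions <- function(caps, chrom_sizes, width = 2000000) {
  out <- list()
  for (cn in names(chrom_sizes)) {
    L <- chrom_sizes[[cn]]
    for (arm in c("p", "q")) {
      cap <- caps[caps$seq_id == cn & caps$arm == arm, , drop = FALSE]
      if (nrow(cap)) {
        if (arm == "p") {
          s <- cap$end[1]; e <- min(cap$end[1] + width, L)
          tr <- "start"
        } else {
          s <- max(0, cap$start[1] - width); e <- cap$start[1]
          tr <- "end"
        }
        anchor <- "cap_proximal_edge"
      } else {
        if (arm == "p") { s <- 0; e <- min(width, L); tr <- "start" }
        else { s <- max(0, L - width); e <- L; tr <- "end" }
        anchor <- "chromosome_tip"
      }
      if (e > s) {
        row <- intervals(cn, s, e, name = paste0(cn, arm))
        row$anchor <- anchor; row$arm <- arm; row$transition <- tr
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call insertions from syntenic alignment blocks
#'
#' Walks consecutive alignment blocks sorted on the query (the derived
#' genome): an unaligned query gap of at least `min_event` bp whose
#' reference-side gap is smaller than `min_event` is an insertion
#' (query sequence with no reference homolog). When secondary whole-
#' genome hits are supplied each insertion is classified by its best
#' overlapping hit: `same_chromosome`, `nonhomologous`, or `unplaced`
#' when nothing overlaps.
#'
#' @param blocks data.frame with query, query_start, query_end,
#'   target_start, target_end (one query vs its reference homolog).
#' @param min_event minimum structural event size, bp.
#' @param secondary optional data.frame of secondary hits with
#'   query_start, query_end, target (chromosome name of the hit).
#' @param reference reference chromosome name used for the
#'   same-chromosome call.
#' @return interval data.frame of insertions with `size` and
#'   `origin_class` columns.
#' @export
detect_insertions <- function(blocks, min_event = 50, secondary = NULL,
                              reference = NULL) {
  empty <- {
    e <- empty_intervals()
    e$size <- numeric(); e$origin_class <- character(); e
  }
  if (nrow(blocks) < 2) return(empty)
  b <- blocks[order(blocks$query_start), , drop = FALSE]
  qgap <- b$query_start[-1] - b$query_end[-nrow(b)]
  tgap <- b$target_start[-1] - b$target_end[-nrow(b)]
  ins <- which(qgap >= min_event & abs(tgap) < min_event)
  if (!length(ins)) return(empty)
  s <- b$query_end[ins]; e <- b$query_start[ins + 1]
  cls <- rep("unplaced", length(ins))
  if (!is.null(secondary) && nrow(secondary)) {
    for (i in seq_along(ins)) {
      ov <- pmax(0, pmin(e[i], secondary$query_end) -
                   pmax(s[i], secondary$query_start))
      if (max(ov) > 0) {
        hit <- secondary$target[which.max(ov)]
        cls[i] <- if (!is.null(reference) && hit == reference) {
          "same_chromosome"
        } else "nonhomologous"
      }
    }
  }
  out <- intervals(b$query[ins], s, e,
                   name = sprintf("ins%d", seq_along(ins)))
  out$size <- e - s
  out$origin_class <- cls
  out
}

#' Coverage-weighted mean methylation per region
#'
#' @param methyl methylation data.frame (seq_id, start, end, coverage,
#'   methylated_fraction).
#' @param regions interval data.frame.
#' @return `regions` with `mean_methylation` and `n_sites` columns.
#' @export
methylation_region_means <- function(methyl, regions) {
  regions$mean_methylation <- NA_real_
  regions$n_sites <- 0L
  for (i in seq_len(nrow(regions))) {
    sel <- methyl$seq_id == regions$seq_id[i] &
      methyl$start >= regions$start[i] & methyl$start < regions$end[i]
    if (any(sel)) {
      w <- methyl$coverage[sel]
      regions$mean_methylation[i] <-
        sum(w * methyl$methylated_fraction[sel]) / sum(w)
      regions$n_sites[i] <- sum(sel)
    }
  }
  regions
}

#' Binned methylation profile across anchored regions
#'
#' Regions are re-anchored at their heterochromatin transition edge and
#' read heterochromatin-to-euchromatin (p- and q-arm regions therefore
#' superimpose). Within each region the coverage-weighted mean fraction
#' is computed per `bin`; the profile reports the mean and standard
#' deviation across regions per bin. Bins with no CpG in a region are
#' missing for that region.
#'
#' @param methyl methylation data.frame.
#' @param regions regions from [define_boundary_regions()] (or any
#'   intervals; a missing `transition` column defaults to "start").
#' @param bin bin width, bp.
#' @return data.frame with bin `offset` (bp from the transition), `mean`,
#'   `sd` and `n` (regions contributing).
#' @export
methylation_profile <- function(methyl, regions, bin = 10000) {
  if (is.null(regions$transition)) regions$transition <- "start"
  per_region <- list()
  for (i in seq_len(nrow(regions))) {
    sel <- methyl$seq_id == regions$seq_id[i] &
      methyl$start >= regions$start[i] & methyl$start < regions$end[i]
    if (!any(sel)) next
    pos <- methyl$start[sel]
    off <- if (regions$transition[i] == "start") {
      pos - regions$start[i]
    } else {
      regions$end[i] - pos - 1
    }
    bi <- floor(off / bin)
    w <- methyl$coverage[sel]
    v <- methyl$methylated_fraction[sel]
    agg <- vapply(split(seq_along(bi), bi), function(idx) {
      sum(w[idx] * v[idx]) / sum(w[idx])
    }, numeric(1))
    per_region[[i]] <- data.frame(bin = as.integer(names(agg)),
                                  value = unname(agg))
  }
  per_region <- per_region[!vapply(per_region, is.null, logical(1))]
  if (!length(per_region)) {
    return(data.frame(offset = numeric(), mean = numeric(),
                      sd = numeric(), n = integer()))
  }
  all <- do.call(rbind, per_region)
  out <- do.call(rbind, lapply(split(all$value, all$bin), function(v) {
    data.frame(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
               n = length(v))
  }))
  out$offset <- as.integer(rownames(out)) * bin
  rownames(out) <- NULL
  out[order(out$offset), c("offset", "mean", "sd", "n")]
}

#' Feature density fold change in regions
#'
#' Density of features inside the regions (bp of overlap, or count of
#' overlapping features, per region bp) divided by the genome-wide
#' density.
#'
#' @param features,regions interval data.frames.
#' @param genome_sizes named numeric vector of chromosome lengths.
#' @param mode "bp" or "count".
#' @return the fold change (1 means no enrichment).
#' @export
density_fold <- function(features, regions, genome_sizes,
                         mode = c("bp", "count")) {
  mode <- match.arg(mode)
  ft <- flatten_targets(regions)
  ov <- numeric(nrow(features))
  for (cn in unique(features$seq_id)) {
    idx <- features$seq_id == cn
    ov[idx] <- if (cn %in% names(ft)) {
      feat_overlap_bp(ft[[cn]], features$start[idx], features$end[idx])
    } else 0
  }
  region_bp <- sum(vapply(ft, function(f) f$cum[length(f$cum)], numeric(1)))
  genome_bp <- sum(genome_sizes)
  if (mode == "bp") {
    (sum(ov) / region_bp) / (sum(features$end - features$start) / genome_bp)
  } else {
    (sum(ov > 0) / region_bp) / (nrow(features) / genome_bp)
  }
}
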
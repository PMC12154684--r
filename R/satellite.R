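# Decomposition of cap sequences into satellite units, variants, arrays
# and spacers.

#' The pCht satellite consensus monomer
#'
#' The 32-bp consensus of the African great ape subterminal satellite
#' (pCht / StSat).
#'
#' @return uppercase DNA string of length 32.
#' @export
pcht_consensus <- function() "GATATTTCCATGTTTATACAGATAGCGGTGTA"

#' Minimum retained unit span
#'
#' Satellite hits are retained only when their span exceeds
#' `floor(min_len_frac * nchar(consensus))` bp; at the 32-bp consensus and
#' the default 90 percent fraction this is the ">28 bp" rule.
#'
#' @param consensus monomer consensus string.
#' @param min_len_frac minimum span as a fraction of the consensus length.
#' @return integer cutoff: spans must be strictly greater than this.
#' @export
unit_retention_cutoff <- function(consensus = pcht_consensus(),
                                  min_len_frac = 0.9) {
  as.integer(floor(min_len_frac * nchar(consensus)))
}

#' Scan a sequence for satellite units
#'
#' Finds a maximal non-overlapping set of approximate matches of the
#' monomer consensus on both strands. Candidate hits come from an
#' edit-distance scan; each is realigned globally to the consensus to
#' obtain its exact identity (matches / aligned columns, gaps included).
#' Hits with span greater than `floor(min_len_frac * |consensus|)` and
#' identity at least `min_identity` are kept, selected greedily by
#' descending alignment score with ties broken by leftmost start and then
#' the plus strand.
#'
#' @param seq a single DNA string; its name (if any) becomes the seq_id.
#' @param consensus monomer consensus (A/C/G/T only).
#' @param min_len_frac minimum unit span as a fraction of the consensus.
#' @param min_identity identity floor in `[0,1]` (satellite units are
#'   generally more than 80 percent identical to the consensus).
#' @param seq_id sequence name override.
#' @return interval data.frame with extra columns `unit_sequence`
#'   (strand-normalized to consensus orientation) and `identity`; `score`
#'   holds the identity as well.
#' @export
scan_units <- function(seq, consensus = pcht_consensus(),
                       min_len_frac = 0.9, min_identity = 0.8,
                       seq_id = NULL) {
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus contains non-ACGT characters", call. = FALSE)
  }
  if (nchar(consensus) < 16) stop("consensus too short", call. = FALSE)
  if (is.null(seq_id)) seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  seq <- toupper(as.character(seq)[1])
  lc <- nchar(consensus)
  min_span <- unit_retention_cutoff(consensus, min_len_frac)
  e_max <- floor((1 - min_identity) * lc) + 1L
  subj <- Biostrings::DNAString(seq)
  hits <- list()
  for (str in c("+", "-")) {
    pat <- if (str == "+") consensus else revcomp(consensus)
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = e_max, with.indels = TRUE)
    if (length(m)) {
      hits[[str]] <- data.frame(start = IRanges::start(m) - 1,
                                end = IRanges::end(m), strand = str)
    }
  }
  hits <- do.call(rbind, hits)
  empty <- cbind(empty_intervals(),
                 data.frame(unit_sequence = character(),
                            identity = numeric()))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits[hits$end - hits$start > min_span, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  useq <- substring(seq, hits$start + 1, hits$end)
  useq[hits$strand == "-"] <- revcomp(useq[hits$strand == "-"])
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(useq),
                                       Biostrings::DNAString(consensus),
                                       type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  cols <- aln_columns(aln)
  nmat <- Biostrings::nmatch(aln)
  ident <- nmat / cols
  score <- 2 * nmat - cols  # matches minus non-match columns
  keep <- ident >= min_identity
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  useq <- useq[keep]; ident <- ident[keep]; score <- score[keep]
  ord <- order(-score, hits$start, hits$strand)
  occupied <- logical(nchar(seq))
  sel <- logical(nrow(hits))
  for (i in ord) {
    span <- (hits$start[i] + 1):hits$end[i]
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      sel[i] <- TRUE
    }
  }
  hits <- hits[sel, , drop = FALSE]
  useq <- useq[sel]; ident <- ident[sel]
  o <- order(hits$start)
  out <- intervals(seq_id, hits$start[o], hits$end[o],
                   name = sprintf("u%d", seq_along(o)),
                   score = round(ident[o], 4), strand = hits$strand[o])
  out$unit_sequence <- useq[o]
  out$identity <- ident[o]
  out
}

#' Classify satellite units into variants
#'
#' Identical (strand-normalized) unit strings share one variant id;
#' variant ids are assigned by descending global count with ties broken
#' lexicographically by sequence.
#'
#' @param units unit data.frame from [scan_units()] (rows may span many
#'   caps; `seq_id` identifies the cap).
#' @return a `variant_catalog`: list with `variants` (variant_id,
#'   sequence, count), `counts` (cap x variant matrix) and `units` (the
#'   input with a `variant_id` column).
#' @export
classify_variants <- function(units) {
  stopifnot(nrow(units) > 0)
  tab <- table(units$unit_sequence)
  df <- data.frame(sequence = names(tab), count = as.integer(tab))
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  df$variant_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  vid <- df$variant_id[match(units$unit_sequence, df$sequence)]
  units$variant_id <- vid
  caps <- sort(unique(units$seq_id))
  counts <- matrix(0L, length(caps), nrow(df),
                   dimnames = list(caps, sprintf("v%d", df$variant_id)))
  t2 <- table(factor(units$seq_id, caps), factor(vid, df$variant_id))
  counts[, ] <- as.integer(t2)
  out <- list(variants = df[, c("variant_id", "sequence", "count")],
              counts = counts, units = units)
  class(out) <- "variant_catalog"
  out
}

#' Merge consecutive satellite units into arrays
#'
#' Consecutive units on the same sequence are merged while the gap between
#' them is at most `max_gap` bp.
#'
#' @param units unit data.frame sorted or sortable by start.
#' @param max_gap maximum intra-array gap, bp.
#' @return interval data.frame of arrays with `unit_count` and
#'   `mean_identity` columns.
#' @export
merge_arrays <- function(units, max_gap = 1000) {
  if (!nrow(units)) {
    out <- empty_intervals()
    out$unit_count <- integer(); out$mean_identity <- numeric()
    return(out)
  }
  units <- units[order(units$seq_id, units$start), , drop = FALSE]
  res <- lapply(split(units, units$seq_id), function(u) {
    gap <- c(Inf, u$start[-1] - u$end[-nrow(u)])
    grp <- cumsum(gap > max_gap)
    do.call(rbind, lapply(split(u, grp), function(g) {
      data.frame(seq_id = g$seq_id[1], start = min(g$start),
                 end = max(g$end), unit_count = nrow(g),
                 mean_identity = mean(g$identity))
    }))
  })
  res <- do.call(rbind, res)
  out <- intervals(res$seq_id, res$start, res$end,
                   name = sprintf("array%d", seq_len(nrow(res))),
                   score = round(res$mean_identity, 4))
  out$unit_count <- res$unit_count
  out$mean_identity <- res$mean_identity
  rownames(out) <- NULL
  out
}

#' Call spacer intervals between satellite arrays
#'
#' Complements the arrays within the cap extent; gaps of at least
#' `min_spacer_len` bp are reported as spacers (the subtraction of
#' satellite arrays from the full subterminal region). When a spacer
#' template and the cap sequence are supplied, each gap is refined to the
#' span of the best template alignment within it.
#'
#' @param cap_extent single-row interval data.frame spanning the cap.
#' @param arrays array intervals on the same sequence.
#' @param min_spacer_len minimum reported gap, bp.
#' @param spacer_template optional template sequence for refinement.
#' @param cap_seq cap sequence (required when refining).
#' @return interval data.frame of spacers with `spacer_id` and `class`
#'   ("subterminal" for gaps internal to the cap) columns.
#' @export
call_spacers <- function(cap_extent, arrays, min_spacer_len = 5000,
                         spacer_template = NULL, cap_seq = NULL) {
  arrays <- arrays[arrays$seq_id == cap_extent$seq_id[1], , drop = FALSE]
  arrays <- arrays[order(arrays$start), , drop = FALSE]
  empty <- {
    e <- empty_intervals()
    e$spacer_id <- integer(); e$class <- character(); e
  }
  if (nrow(arrays) < 1) return(empty)
  bounds_s <- c(cap_extent$start[1], arrays$end)
  bounds_e <- c(arrays$start, cap_extent$end[1])
  gs <- bounds_s; ge <- bounds_e
  keep <- ge - gs >= min_spacer_len
  gs <- gs[keep]; ge <- ge[keep]
  if (!length(gs)) return(empty)
  if (!is.null(spacer_template) && !is.null(cap_seq)) {
    for (i in seq_along(gs)) {
      gap_seq <- substr(cap_seq, gs[i] + 1, ge[i])
      blocks <- anchor_chain_align(setNames(spacer_template, "template"),
                                   setNames(gap_seq, "gap"),
                                   k = 21, stride = 20)
      if (nrow(blocks)) {
        best <- blocks[which.max(blocks$length), ]
        gs[i] <- gs[i] + best$target_start
        ge[i] <- gs[i] + (best$target_end - best$target_start)
      }
    }
  }
  out <- intervals(cap_extent$seq_id[1], gs, ge,
                   name = sprintf("spacer%d", seq_along(gs)))
  out$spacer_id <- seq_along(gs)
  out$class <- "subterminal"
  out
}

#' Derive a consensus and base-frequency profile from units
#'
#' Units are aligned to the supplied coordinate frame (insertions relative
#' to the frame are dropped, deletions counted as gaps) and the
#' column-wise majority base is taken. Profile columns are normalized over
#' the observed A/C/G/T counts, so they sum to 1 at every position.
#'
#' @param units unit data.frame (uses `unit_sequence`) or a character
#'   vector of unit strings.
#' @param frame coordinate frame, usually the scanning consensus.
#' @return list with `consensus` (string, same length as `frame`) and
#'   `profile` (4 x L matrix of base frequencies).
#' @export
derive_consensus <- function(units, frame = pcht_consensus()) {
  useq <- if (is.data.frame(units)) units$unit_sequence else units
  stopifnot(length(useq) >= 1)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(useq),
                                       Biostrings::DNAString(frame),
                                       type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 2, gapExtension = 1)
  mat <- Biostrings::consensusMatrix(Biostrings::aligned(aln))
  bases <- DNA_BASES
  prof <- mat[bases, , drop = FALSE]
  tot <- colSums(prof)
  tot[tot == 0] <- 1
  prof <- sweep(prof, 2, tot, "/")
  cons <- paste(bases[apply(prof, 2, which.max)], collapse = "")
  list(consensus = cons, profile = prof)
}
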
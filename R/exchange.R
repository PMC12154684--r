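# Anchor-based pairwise cap alignment, windowed identity, and ectopic
# exchange candidate calling with breakpoint refinement.

# k-mer anchor positions (0-based) of `pat_seq` sampled at `stride`
# against `sub_seq`; patterns hitting the subject more than max_occ times
# are dropped (tandem satellite k-mers would otherwise explode the
# anchor set)
kmer_anchors <- function(pat_seq, sub_seq, k, stride, max_occ) {
  np <- nchar(pat_seq)
  if (np < k || nchar(sub_seq) < k) {
    return(data.frame(q = numeric(0), t = numeric(0)))
  }
  qpos <- seq(1, np - k + 1, by = stride)
  kmers <- substring(pat_seq, qpos, qpos + k - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  qpos <- qpos[keep]; kmers <- kmers[keep]
  if (!length(qpos)) return(data.frame(q = numeric(0), t = numeric(0)))
  uk <- unique(kmers)
  pd <- Biostrings::PDict(uk)
  mh <- Biostrings::matchPDict(pd, Biostrings::DNAString(sub_seq))
  nh <- lengths(mh)
  starts <- lapply(seq_along(uk), function(i) {
    if (nh[i] == 0 || nh[i] > max_occ) integer(0) else IRanges::start(mh[[i]])
  })
  idx <- match(kmers, uk)
  counts <- vapply(starts, length, integer(1))[idx]
  data.frame(q = rep(qpos, counts) - 1,
             t = unlist(starts[idx], use.names = FALSE) - 1)
}

# colinear chaining: anchors are grouped per exact diagonal and split
# where the query gap exceeds max_chain_gap. Gapped homology shows up as
# several exact-diagonal chains, re-joined downstream
# (detect_exchange_candidates merges diagonal-consistent blocks).
chain_anchors <- function(anc, k, max_chain_gap) {
  anc$d <- anc$t - anc$q
  chains <- list()
  for (g in split(anc, anc$d)) {
    g <- g[order(g$q), , drop = FALSE]
    sub <- cumsum(c(TRUE, (g$q[-1] - g$q[-nrow(g)]) > max_chain_gap))
    chains <- c(chains, split(g, sub))
  }
  chains
}

# count equal characters between two equal-length strings
str_matches <- function(a, b) {
  if (!nchar(a)) return(0)
  sum(charToRaw(a) == charToRaw(b))
}

# merge chained anchors into maximal exact segments (same diagonal,
# overlapping/contiguous)
exact_segments <- function(ch, k) {
  segs <- list()
  cur <- NULL
  for (i in seq_len(nrow(ch))) {
    q <- ch$q[i]; t <- ch$t[i]; d <- ch$d[i]
    if (!is.null(cur) && d == cur$d && q <= cur$qe && q >= cur$qs) {
      cur$qe <- max(cur$qe, q + k); cur$te <- cur$qe + d
      cur$n_anchors <- cur$n_anchors + 1
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
      cur <- list(qs = q, qe = q + k, ts = t, te = t + k, d = d,
                  n_anchors = 1)
    }
  }
  segs[[length(segs) + 1]] <- cur
  segs
}

#' Align two cap sequences by anchor chaining
#'
#' Exact k-mer anchors (sampled every `stride` bp on both sequences, both
#' strands, with high-multiplicity k-mers dropped) are chained by diagonal
#' consistency; the sequence between consecutive anchors is compared
#' directly (equal-length gaps) or by global alignment (short unequal
#' gaps) to give an exact per-block identity: matches over aligned
#' columns, gap columns included. Blocks carried by fewer than two
#' anchors are discarded. Anchors are collected from both sequences so
#' the result is symmetric under swapping the pair (after coordinate
#' swap).
#'
#' @param capA,capB named single-sequence character vectors (query and
#'   target).
#' @param k anchor k-mer length; the default (51) targets the
#'   high-identity regime where exact long k-mers are dense.
#' @param stride anchor sampling stride, bp.
#' @param max_chain_gap maximum gap between chained anchors, bp.
#' @param max_occ subject-multiplicity cutoff for anchor k-mers.
#' @param align_gap_limit longest unequal-length inter-anchor gap closed
#'   by global alignment; longer uneven gaps split the block.
#' @return data.frame of alignment blocks: query, target, query_start,
#'   query_end, target_start, target_end, strand, identity, length,
#'   matches, columns, n_anchors. Coordinates 0-based half-open on the
#'   respective cap.
#' @export
anchor_chain_align <- function(capA, capB, k = 51, stride = 50,
                               max_chain_gap = 50000, max_occ = 10,
                               align_gap_limit = 5000) {
  qname <- if (!is.null(names(capA))) names(capA)[1] else "capA"
  tname <- if (!is.null(names(capB))) names(capB)[1] else "capB"
  A <- toupper(as.character(capA)[1])
  B <- toupper(as.character(capB)[1])
  stopifnot(nchar(A) >= k, nchar(B) >= k)
  nB <- nchar(B)
  out <- list()
  for (str in c("+", "-")) {
    Bs <- if (str == "+") B else revcomp(B)
    a1 <- kmer_anchors(A, Bs, k, stride, max_occ)
    a2 <- kmer_anchors(Bs, A, k, stride, max_occ)
    anc <- unique(rbind(a1, data.frame(q = a2$t, t = a2$q)))
    if (!nrow(anc)) next
    for (ch in chain_anchors(anc, k, max_chain_gap)) {
      if (nrow(ch) < 2) next
      segs <- exact_segments(ch, k)
      # accumulate blocks, splitting at unalignable gaps
      blk <- NULL
      flush <- function(blk) {
        if (is.null(blk) || blk$n_anchors < 2) return(NULL)
        ts <- blk$ts; te <- blk$te
        if (str == "-") { ts <- nB - blk$te; te <- nB - blk$ts }
        data.frame(query = qname, target = tname,
                   query_start = blk$qs, query_end = blk$qe,
                   target_start = ts, target_end = te, strand = str,
                   identity = blk$matches / blk$columns,
                   length = blk$qe - blk$qs, matches = blk$matches,
                   columns = blk$columns, n_anchors = blk$n_anchors)
      }
      for (si in seq_along(segs)) {
        s <- segs[[si]]
        slen <- s$qe - s$qs
        if (is.null(blk)) {
          blk <- list(qs = s$qs, qe = s$qe, ts = s$ts, te = s$te,
                      matches = slen, columns = slen,
                      n_anchors = s$n_anchors)
          next
        }
        qgap <- s$qs - blk$qe
        tgap <- s$ts - blk$te
        trim <- max(0, -qgap, -tgap)
        qs <- s$qs + trim; ts2 <- s$ts + trim
        qgap <- qs - blk$qe; tgap <- ts2 - blk$te
        seglen <- s$qe - qs
        if (seglen <= 0) next
        uneven <- qgap != tgap
        split_here <- (uneven && max(qgap, tgap) > align_gap_limit) ||
          max(qgap, tgap) > max_chain_gap
        gm <- gc <- 0
        if (!split_here && max(qgap, tgap) > 0) {
          # cheap screen first: a gap whose direct comparison is far below
          # the homologous regime does not align -- break the chain there
          # rather than dilute the block identity
          mlen <- min(qgap, tgap)
          pre_id <- if (mlen > 0) {
            str_matches(substr(A, blk$qe + 1, blk$qe + mlen),
                        substr(Bs, blk$te + 1, blk$te + mlen)) / mlen
          } else 1
          if (max(qgap, tgap) >= 200 && pre_id < 0.7) {
            split_here <- TRUE
          } else if (qgap == tgap) {
            gm <- pre_id * qgap; gc <- qgap
          } else if (qgap == 0 || tgap == 0) {
            gm <- 0; gc <- max(qgap, tgap)
          } else {
            sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                           mismatch = -1,
                                                           baseOnly = FALSE)
            aln <- Biostrings::pairwiseAlignment(
              Biostrings::DNAString(substr(A, blk$qe + 1, blk$qe + qgap)),
              Biostrings::DNAString(substr(Bs, blk$te + 1, blk$te + tgap)),
              type = "global", substitutionMatrix = sm,
              gapOpening = 2, gapExtension = 1)
            gm <- Biostrings::nmatch(aln); gc <- aln_columns(aln)
          }
        }
        if (split_here) {
          out[[length(out) + 1]] <- flush(blk)
          blk <- list(qs = qs, qe = s$qe, ts = ts2, te = s$te,
                      matches = seglen, columns = seglen,
                      n_anchors = s$n_anchors)
          next
        }
        blk$matches <- blk$matches + gm + seglen
        blk$columns <- blk$columns + gc + seglen
        blk$qe <- s$qe; blk$te <- s$te
        blk$n_anchors <- blk$n_anchors + s$n_anchors
      }
      out[[length(out) + 1]] <- flush(blk)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(query = character(), target = character(),
                      query_start = numeric(), query_end = numeric(),
                      target_start = numeric(), target_end = numeric(),
                      strand = character(), identity = numeric(),
                      length = numeric(), matches = numeric(),
                      columns = numeric(), n_anchors = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$query_start, res$target_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Windowed identity and coverage of a cap pair
#'
#' Each non-overlapping query window takes the identity of the block
#' overlapping it most (by bp); windows with no block are uncovered.
#' Coverage is the union of block query spans divided by the cap length,
#' and `weighted_identity` is the column-weighted mean block identity.
#'
#' @param blocks alignment blocks of one cap pair.
#' @param cap_len query cap length, bp.
#' @param window window size, bp.
#' @return list with `windows` (start, end, identity with NA when
#'   uncovered), `coverage`, and `weighted_identity`.
#' @export
windowed_identity <- function(blocks, cap_len, window = 50000) {
  ws <- seq(0, cap_len - 1, by = window)
  we <- pmin(ws + window, cap_len)
  ident <- rep(NA_real_, length(ws))
  for (i in seq_along(ws)) {
    ov <- pmax(0, pmin(we[i], blocks$query_end) -
                 pmax(ws[i], blocks$query_start))
    if (length(ov) && max(ov) > 0) {
      ident[i] <- blocks$identity[which.max(ov)]
    }
  }
  cov_bp <- if (nrow(blocks)) {
    ir <- IRanges::reduce(IRanges::IRanges(blocks$query_start + 1,
                                           blocks$query_end))
    sum(IRanges::width(ir))
  } else 0
  wident <- if (nrow(blocks)) {
    sum(blocks$identity * blocks$columns) / sum(blocks$columns)
  } else NA_real_
  list(windows = data.frame(start = ws, end = we, identity = ident),
       coverage = cov_bp / cap_len, weighted_identity = wident)
}

#' High-identity cap pair classification
#'
#' The screen used for allelic comparisons: a pair is "high identity"
#' when its weighted identity exceeds 0.99 and its alignment coverage
#' exceeds 0.5.
#'
#' @param blocks alignment blocks of the pair.
#' @param cap_len query cap length.
#' @return logical.
#' @export
high_identity_pair <- function(blocks, cap_len) {
  w <- windowed_identity(blocks, cap_len)
  isTRUE(w$weighted_identity > 0.99 && w$coverage > 0.5)
}

# identity of the refine window [qs, qs+w) on the working diagonal d
window_ident_at <- function(A, Bs, qs, d, w) {
  if (qs < 0 || qs + w > nchar(A)) return(0)
  ts <- qs + d
  if (ts < 0 || ts + w > nchar(Bs)) return(0)
  str_matches(substr(A, qs + 1, qs + w), substr(Bs, ts + 1, ts + w)) / w
}

#' Detect ectopic exchange candidates between two caps
#'
#' Diagonal-consistent blocks are merged (gaps up to `max_chain_gap`);
#' merged blocks with identity at least `min_identity` over at least
#' `min_len` bp are candidates (the ">99.5 percent identity, >1 Mbp"
#' screen for recent events). When the cap sequences are supplied, each
#' breakpoint is refined by walking outward from the candidate interior
#' in `refine_step` windows until the windowed identity stays below
#' `transition_identity` for three consecutive windows; the reported
#' uncertainty is `refine_step`. When spacers are supplied, the distance
#' from each breakpoint to the nearest spacer is attached.
#'
#' @param blocks alignment blocks from [anchor_chain_align()] (query =
#'   acceptor cap).
#' @param capA,capB optional query/target sequences, enabling refinement.
#' @param spacers optional spacer intervals on the query cap.
#' @param min_identity identity threshold.
#' @param min_len minimum merged length, bp.
#' @param refine_step refinement window, bp (also the reported
#'   breakpoint uncertainty).
#' @param transition_identity windowed identity below which the exchange
#'   is considered ended.
#' @param max_chain_gap merge gap, bp.
#' @param merge_band maximum diagonal offset between merged blocks, bp
#'   (absorbs indel drift without merging off-diagonal blocks).
#' @return data.frame of candidates with refined breakpoints `bp1`,
#'   `bp2` (query coordinates), `bp_uncertainty`, and (with spacers)
#'   `bp1_spacer_dist`, `bp2_spacer_dist`.
#' @export
detect_exchange_candidates <- function(blocks, capA = NULL, capB = NULL,
                                       spacers = NULL,
                                       min_identity = 0.995,
                                       min_len = 1000000,
                                       refine_step = 2000,
                                       transition_identity = 0.99,
                                       max_chain_gap = 50000,
                                       merge_band = 2000) {
  empty <- data.frame(query = character(), target = character(),
                      query_start = numeric(), query_end = numeric(),
                      target_start = numeric(), target_end = numeric(),
                      strand = character(), identity = numeric(),
                      length = numeric(), bp1 = numeric(), bp2 = numeric(),
                      bp_uncertainty = numeric())
  if (!nrow(blocks)) return(empty)
  merged <- list()
  for (str in unique(blocks$strand)) {
    b <- blocks[blocks$strand == str, , drop = FALSE]
    b <- b[order(b$query_start), , drop = FALSE]
    b$d <- b$target_start - b$query_start
    grp <- integer(nrow(b))
    cur <- 1; grp[1] <- 1
    if (nrow(b) > 1) {
      for (i in 2:nrow(b)) {
        prev <- max(which(grp == cur))
        if (b$query_start[i] - b$query_end[prev] <= max_chain_gap &&
            abs(b$d[i] - b$d[prev]) <= merge_band) {
          grp[i] <- cur
        } else {
          cur <- cur + 1; grp[i] <- cur
        }
      }
    }
    for (g in split(b, grp)) {
      merged[[length(merged) + 1]] <- data.frame(
        query = g$query[1], target = g$target[1],
        query_start = min(g$query_start), query_end = max(g$query_end),
        target_start = min(g$target_start), target_end = max(g$target_end),
        strand = str,
        identity = sum(g$matches) / sum(g$columns),
        length = max(g$query_end) - min(g$query_start))
    }
  }
  cand <- do.call(rbind, merged)
  cand <- cand[cand$identity >= min_identity & cand$length >= min_len, ,
               drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$bp1 <- cand$query_start
  cand$bp2 <- cand$query_end
  cand$bp_uncertainty <- refine_step
  if (!is.null(capA) && !is.null(capB)) {
    A <- toupper(as.character(capA)[1])
    B <- toupper(as.character(capB)[1])
    for (i in seq_len(nrow(cand))) {
      Bs <- if (cand$strand[i] == "+") B else revcomp(B)
      ts <- if (cand$strand[i] == "+") cand$target_start[i] else
        nchar(B) - cand$target_end[i]
      d <- ts - cand$query_start[i]
      w <- refine_step
      center <- floor((cand$query_start[i] + cand$query_end[i]) / 2)
      center <- center - center %% w
      walk <- function(dir) {
        x <- center
        bad <- 0; last_good <- center
        repeat {
          xs <- if (dir < 0) x - w else x
          id <- window_ident_at(A, Bs, xs, d, w)
          if (id >= transition_identity) {
            bad <- 0
            last_good <- if (dir < 0) xs else xs + w
          } else {
            bad <- bad + 1
            if (bad >= 3) return(last_good)
          }
          x <- x + dir * w
          if (x < 0 || x > nchar(A)) return(last_good)
        }
      }
      cand$bp1[i] <- walk(-1L)
      cand$bp2[i] <- walk(+1L)
    }
  }
  if (!is.null(spacers)) {
    sp <- spacers[spacers$seq_id == cand$query[1], , drop = FALSE]
    cand$bp1_spacer_dist <- nearest_spacer_distance(cand$bp1, sp)
    cand$bp2_spacer_dist <- nearest_spacer_distance(cand$bp2, sp)
  }
  rownames(cand) <- NULL
  cand
}

#' Distance from positions to the nearest spacer
#'
#' Zero when a position lies inside a spacer, otherwise the minimum edge
#' distance.
#'
#' @param positions numeric vector of 0-based positions.
#' @param spacers spacer interval data.frame (single sequence).
#' @return numeric vector of distances, bp.
#' @export
nearest_spacer_distance <- function(positions, spacers) {
  if (!nrow(spacers)) return(rep(Inf, length(positions)))
  s <- sort(spacers$start); e <- spacers$end[order(spacers$start)]
  vapply(positions, function(p) {
    inside <- any(s <= p & p < e)
    if (inside) return(0)
    min(abs(c(s - p, p - e)))
  }, numeric(1))
}
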
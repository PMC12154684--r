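# Independent oracles used to validate the implementation. These are
# deliberately naive (line-by-line parsing, exhaustive scans, explicit
# enumeration) and share no code with the package internals.

# minimal FASTA parser: readLines + string splitting
naive_read_fasta <- function(path) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  stopifnot(length(idx) > 0 || length(lines) == 0)
  if (!length(idx)) return(setNames(character(0), character(0)))
  ends <- c(idx[-1] - 1, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    if (ends[i] < idx[i] + 1) "" else
      paste(lines[(idx[i] + 1):ends[i]], collapse = "")
  }, "")
  names(seqs) <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  toupper(seqs)
}

# exhaustive ungapped scan: slide the consensus (both strands) over every
# offset, score by match count, and greedily pick non-overlapping hits.
# Valid oracle for substitution-only tandem arrays.
oracle_scan_units <- function(seq, consensus, min_identity = 0.8) {
  lc <- nchar(consensus)
  n <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  sc <- strsplit(seq, "")[[1]]
  score_at <- function(pat) {
    pc <- strsplit(pat, "")[[1]]
    vapply(0:(n - lc), function(off) {
      sum(sc[(off + 1):(off + lc)] == pc)
    }, numeric(1))
  }
  fwd <- score_at(consensus)
  rev <- score_at(rc)
  cand <- data.frame(start = rep(0:(n - lc), 2),
                     score = c(fwd, rev),
                     strand = rep(c("+", "-"), each = n - lc + 1))
  cand <- cand[cand$score / lc >= min_identity, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$start, cand$strand), , drop = FALSE]
  occupied <- logical(n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1):(cand$start[i] + lc)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$end <- out$start + lc
  out
}

# brute-force RF: enumerate bipartitions by deleting each internal edge
# and flood-filling the two components of the remaining graph
oracle_bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  edges <- tree$edge
  keys <- character(0)
  for (i in seq_len(nrow(edges))) {
    rem <- edges[-i, , drop = FALSE]
    # flood fill from one endpoint of the removed edge
    side <- edges[i, 1]
    seen <- side
    repeat {
      nb <- unique(c(rem[rem[, 1] %in% seen, 2], rem[rem[, 2] %in% seen, 1]))
      new <- setdiff(nb, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    tips1 <- sort(labs[seen[seen <= n]])
    if (length(tips1) < 2 || length(tips1) > n - 2) next
    ref <- sort(labs)[1]
    if (ref %in% tips1) tips1 <- sort(setdiff(labs, tips1))
    if (length(tips1) < 2) next
    keys <- c(keys, paste(tips1, collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# exhaustive nearest-distance over every spacer edge
oracle_nearest <- function(pos, spacers) {
  vapply(pos, function(p) {
    best <- Inf
    for (i in seq_len(nrow(spacers))) {
      s <- spacers$start[i]; e <- spacers$end[i]
      if (p >= s && p < e) return(0)
      best <- min(best, abs(p - s), abs(p - e))
    }
    best
  }, numeric(1))
}

# brute-force bp overlap of features with (possibly overlapping) regions
oracle_overlap_bp <- function(features, regions) {
  total <- 0
  for (i in seq_len(nrow(features))) {
    covered <- integer(0)
    r <- regions[regions$seq_id == features$seq_id[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      s <- max(features$start[i], r$start[j])
      e <- min(features$end[i], r$end[j])
      if (e > s) covered <- union(covered, s:(e - 1))
    }
    total <- total + length(covered)
  }
  total
}

# accuracy under the best greedy one-to-one label matching
label_match_accuracy <- function(truth, labels) {
  tab <- table(truth, labels)
  acc <- 0
  used_r <- used_c <- integer(0)
  for (k in seq_len(min(dim(tab)))) {
    t2 <- tab
    if (length(used_r)) t2[used_r, ] <- -1
    if (length(used_c)) t2[, used_c] <- -1
    idx <- which(t2 == max(t2), arr.ind = TRUE)[1, ]
    acc <- acc + tab[idx[1], idx[2]]
    used_r <- c(used_r, idx[1]); used_c <- c(used_c, idx[2])
  }
  acc / length(truth)
}

# recall/precision of called intervals vs truth by >=50% overlap of the
# evaluated element
interval_recall <- function(truth, calls) {
  if (!nrow(truth)) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    cc <- calls[calls$seq_id == truth$seq_id[i], , drop = FALSE]
    if (!nrow(cc)) return(FALSE)
    ov <- pmax(0, pmin(truth$end[i], cc$end) - pmax(truth$start[i], cc$start))
    max(ov) >= 0.5 * (truth$end[i] - truth$start[i])
  }, logical(1))
  mean(hit)
}
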
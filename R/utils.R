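# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence") {
  if (grepl("[^ACGTN]", x)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what),
         call. = FALSE)
  }
  invisible(x)
}

# split a DNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Construct a genomic interval table
#'
#' All coordinates in the package are 0-based, half-open (BED convention).
#' Strand "." means unstranded.
#'
#' @param seq_id character vector of sequence names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of "+", "-", "." per row.
#' @param name,score optional annotation columns.
#' @return a data.frame with columns seq_id, start, end, name, score, strand.
#' @export
intervals <- function(seq_id, start, end, strand = ".", name = ".",
                      score = 0) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate", call. = FALSE)
  if (any(start >= end)) stop("interval with start >= end", call. = FALSE)
  if (length(start) == 0) return(empty_intervals())
  data.frame(seq_id = as.character(seq_id), start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(seq_id = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

# total bp of overlap between one interval [s,e) and a set of intervals on
# the same sequence (intervals assumed disjoint)
overlap_bp <- function(s, e, starts, ends) {
  sum(pmax(0, pmin(e, ends) - pmax(s, starts)))
}

# per-row total overlap of `a` rows with the (possibly overlapping) rows of
# `b`, matched on seq_id; b is flattened to disjoint cover first
interval_overlap_bp <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    bi <- b[b$seq_id == a$seq_id[i], , drop = FALSE]
    if (nrow(bi) == 0) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(bi$start + 1, bi$end))
    overlap_bp(a$start[i], a$end[i], IRanges::start(ir) - 1,
               IRanges::end(ir))
  }, numeric(1))
}

# Jaccard index of two intervals on the same sequence
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) return(0)
  inter / uni
}

# total aligned columns of a PairwiseAlignments object (matches +
# mismatches + inserted + deleted columns)
aln_columns <- function(aln) {
  ind <- Biostrings::nindel(aln)
  Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ind)[, 2] + Biostrings::deletion(ind)[, 2]
}
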
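# Readers and writers for the standard formats used throughout the package.
# Coordinates are 0-based half-open everywhere (BED convention); only log
# and display output is 1-based.

#' Read a FASTA file
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of uppercase sequences; names are the
#'   full header words up to the first whitespace.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal character in sequence of record '",
         names(seqs)[which(bad)[1]], "'", call. = FALSE)
  }
  if (length(seqs) && any(!nzchar(names(seqs)))) {
    stop("FASTA record with empty id", call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly. Round-trips through [read_fasta()] exactly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) && length(seqs)) {
    stop("sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

bed_parse_error <- function(path, line_no, msg) {
  stop(sprintf("%s: line %d: %s", path, line_no, msg), call. = FALSE)
}

#' Read a BED6 file
#'
#' @param path path to a tab-separated BED6 file.
#' @return interval data.frame (see [intervals()]); 0-based half-open
#'   coordinates preserved verbatim.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(intervals(character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6)) {
    bed_parse_error(path, which(n < 6)[1], "expected 6 tab-separated columns")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) bed_parse_error(path, which(bad)[1], "non-integer coordinate")
  if (any(start < 0)) {
    bed_parse_error(path, which(start < 0)[1], "negative coordinate")
  }
  if (any(start >= end)) {
    bed_parse_error(path, which(start >= end)[1], "start >= end")
  }
  intervals(m[, 1], start, end, strand = m[, 6], name = m[, 4],
            score = suppressWarnings(as.numeric(m[, 5])))
}

#' Write intervals as BED6
#'
#' @param x interval data.frame.
#' @param path output path.
#' @return `path`, invisibly. Output order is the row order of `x`, so
#'   sorted input yields deterministic sorted output.
#' @export
write_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$seq_id, as.integer(x$start),
                   as.integer(x$end), x$name,
                   formatC(x$score, format = "fg"), x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedMethyl (9+2) file
#'
#' Standard bedMethyl layout: columns 1-3 the interval, column 10 valid
#' coverage, column 11 percent methylated. The percentage is divided by 100
#' on read. Extra columns beyond 11 are ignored with a warning.
#'
#' @param path path to the tab-separated file.
#' @return data.frame with seq_id, start, end, coverage,
#'   methylated_fraction (in `[0,1]`).
#' @export
read_bedmethyl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(seq_id = character(), start = numeric(),
                      end = numeric(), coverage = numeric(),
                      methylated_fraction = numeric())
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 11)) {
    bed_parse_error(path, which(n < 11)[1],
                    "expected at least 11 tab-separated columns (bedMethyl 9+2)")
  }
  if (any(n > 11)) {
    warning("ignoring extra columns beyond 11 in '", path, "'", call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, c(1:3, 10:11)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) bed_parse_error(path, which(bad)[1], "non-integer coordinate")
  if (any(start < 0)) {
    bed_parse_error(path, which(start < 0)[1], "negative coordinate")
  }
  if (any(start >= end)) {
    bed_parse_error(path, which(start >= end)[1], "start >= end")
  }
  cov <- suppressWarnings(as.numeric(m[, 4]))
  pct <- suppressWarnings(as.numeric(m[, 5]))
  if (any(is.na(cov) | cov < 0)) {
    bed_parse_error(path, which(is.na(cov) | cov < 0)[1], "bad coverage")
  }
  if (any(is.na(pct) | pct < 0 | pct > 100)) {
    bed_parse_error(path, which(is.na(pct) | pct < 0 | pct > 100)[1],
                    "percent methylated outside [0,100]")
  }
  data.frame(seq_id = m[, 1], start = start, end = end, coverage = cov,
             methylated_fraction = pct / 100)
}

#' Write methylation records as bedMethyl (9+2)
#'
#' @param x data.frame as returned by [read_bedmethyl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\tm\t%d\t.\t%d\t%d\t0,0,0\t%d\t%s",
                   x$seq_id, as.integer(x$start), as.integer(x$end),
                   as.integer(x$coverage), as.integer(x$start),
                   as.integer(x$end), as.integer(x$coverage),
                   formatC(100 * x$methylated_fraction, format = "fg"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around ape's Newick parser and serializer; parse-write-
#' parse is the identity on topology, branch lengths and labels.
#'
#' @param path file path.
#' @return for `read_newick`, an ape `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in '", path, "'", call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an ape `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Minimal reader for externally produced pairwise alignments: the 12
#' mandatory PAF columns. Coordinates remain 0-based half-open.
#'
#' @param path path to an uncompressed PAF file.
#' @return data.frame with query/target names, lengths, starts, ends,
#'   strand, residue matches, alignment block length, mapq, and a derived
#'   `identity` = matches / block length.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("query", "query_len", "query_start", "query_end", "strand",
            "target", "target_len", "target_start", "target_end",
            "matches", "block_len", "mapq")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character()), 12), cols))
    out$identity <- numeric()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 12)) {
    bed_parse_error(path, which(n < 12)[1], "expected >= 12 PAF columns")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  out <- data.frame(query = m[, 1], query_len = as.numeric(m[, 2]),
                    query_start = as.numeric(m[, 3]),
                    query_end = as.numeric(m[, 4]), strand = m[, 5],
                    target = m[, 6], target_len = as.numeric(m[, 7]),
                    target_start = as.numeric(m[, 8]),
                    target_end = as.numeric(m[, 9]),
                    matches = as.numeric(m[, 10]),
                    block_len = as.numeric(m[, 11]),
                    mapq = as.numeric(m[, 12]))
  if (any(out$query_start < 0 | out$target_start < 0)) {
    stop("negative coordinate in PAF '", path, "'", call. = FALSE)
  }
  out$identity <- ifelse(out$block_len > 0, out$matches / out$block_len, NA)
  out
}
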
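# Tabular homology-hit format: 11 tab-separated columns, no header line:
#   query_id  subject_id  subject_genome  raw_score  bit_score  evalue
#   q_start  q_end  s_start  s_end  frame
# Coordinates are 1-based inclusive; frame is 0 for protein-protein hits and
# +/-1..3 for translated hits (DNA coordinates on the forward strand).

HIT_COLS <- c("query_id", "subject_id", "subject_genome", "raw_score",
              "bit_score", "evalue", "q_start", "q_end", "s_start", "s_end",
              "frame")

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_genome = character(), raw_score = integer(),
             bit_score = numeric(), evalue = numeric(), q_start = integer(),
             q_end = integer(), s_start = integer(), s_end = integer(),
             frame = integer(), stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits), all(HIT_COLS %in% names(hits)))
  if (nrow(hits) == 0) return(invisible(hits))
  num <- c("raw_score", "bit_score", "evalue", "q_start", "q_end",
           "s_start", "s_end", "frame")
  for (col in num) {
    if (!is.numeric(hits[[col]]) || anyNA(hits[[col]]))
      stop("non-numeric or missing value in hit column ", col,
           " (line ", which(is.na(suppressWarnings(as.numeric(hits[[col]]))))[1],
           ")")
  }
  bad <- which(hits$q_start > hits$q_end | hits$s_start > hits$s_end)
  if (length(bad))
    stop("invalid hit coordinates (start > end) at line ", bad[1])
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  if (!all(hits$frame %in% c(0L, 1L, 2L, 3L, -1L, -2L, -3L)))
    stop("frame must be 0 or +/-1..3")
  invisible(hits)
}

#' Read a tabular homology-hit file
#'
#' The native format is the headerless 11-column TSV documented above. The
#' 12-column "outfmt 6" dialect of common search tools (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) can be
#' ingested with \code{format = "outfmt6"}; since that dialect carries no
#' genome label or raw score, \code{subject_genome} must then be supplied
#' and the raw score is back-computed from the bit score under
#' \code{scoring}.
#'
#' @param path TSV file of hits.
#' @param format \code{"native"} or \code{"outfmt6"}.
#' @param subject_genome genome label for every row (outfmt6 only).
#' @param scoring scoring scheme used to invert bit scores (outfmt6 only).
#' @return a data frame of hits in file order.
#' @export
read_hit_table <- function(path, format = c("native", "outfmt6"),
                           subject_genome = NULL, scoring = scoring_scheme()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (format == "native") {
    if (ncol(raw) != 11)
      stop("native hit table must have 11 columns, found ", ncol(raw))
    names(raw) <- HIT_COLS
    for (col in c("raw_score", "bit_score", "evalue")) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(v))
        stop("non-numeric ", col, " at line ", which(is.na(v))[1])
      raw[[col]] <- v
    }
    for (col in c("q_start", "q_end", "s_start", "s_end", "frame")) {
      v <- suppressWarnings(as.integer(raw[[col]]))
      if (anyNA(v))
        stop("non-integer ", col, " at line ", which(is.na(v))[1])
      raw[[col]] <- v
    }
    raw$raw_score <- as.integer(raw$raw_score)
    hits <- raw
  } else {
    if (ncol(raw) != 12)
      stop("outfmt6 table must have 12 columns, found ", ncol(raw))
    if (is.null(subject_genome))
      stop("outfmt6 input needs an explicit subject_genome")
    ev <- suppressWarnings(as.numeric(raw[[11]]))
    bs <- suppressWarnings(as.numeric(raw[[12]]))
    if (anyNA(ev)) stop("non-numeric E-value at line ", which(is.na(ev))[1])
    if (anyNA(bs)) stop("non-numeric bit score at line ", which(is.na(bs))[1])
    hits <- data.frame(
      query_id = raw[[1]], subject_id = raw[[2]],
      subject_genome = subject_genome,
      raw_score = as.integer(round((bs * log(2) + log(scoring$K)) /
                                     scoring$lambda)),
      bit_score = bs, evalue = ev,
      q_start = as.integer(raw[[7]]), q_end = as.integer(raw[[8]]),
      s_start = pmin(as.integer(raw[[9]]), as.integer(raw[[10]])),
      s_end = pmax(as.integer(raw[[9]]), as.integer(raw[[10]])),
      frame = 0L, stringsAsFactors = FALSE)
  }
  validate_hits(hits)
  hits
}

#' Write hits in the native 11-column TSV format
#'
#' E-values and bit scores are serialized in scientific notation with seven
#' significant digits, so a write/read round trip preserves them to well
#' within six significant digits.
#'
#' @param hits data frame of hits.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  out <- hits[, HIT_COLS]
  out$evalue <- sprintf("%.6e", out$evalue)
  out$bit_score <- sprintf("%.6e", out$bit_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
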
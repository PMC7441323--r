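#' Construct a set of sequence records
#'
#' The package-wide container for sequences is a plain data frame with one
#' row per sequence and columns \code{seq_id}, \code{genome_id},
#' \code{residues} and \code{moltype} (\code{"protein"} or \code{"dna"}).
#' Residues are stored uppercase; proteins use the 20 canonical amino acids
#' plus \code{X}, DNA uses \code{ACGTN}. Sequence ids must be unique within
#' a genome.
#'
#' @param seq_id,genome_id character vectors (recycled for \code{genome_id}).
#' @param residues character vector of sequences.
#' @param moltype \code{"protein"} or \code{"dna"}.
#' @return a validated \code{data.frame} of records.
#' @export
seq_records <- function(seq_id, residues, genome_id, moltype) {
  moltype <- match.arg(moltype, c("protein", "dna"))
  rec <- data.frame(seq_id = as.character(seq_id),
                    genome_id = rep_len(as.character(genome_id), length(seq_id)),
                    residues = toupper(as.character(residues)),
                    moltype = rep_len(moltype, length(seq_id)),
                    stringsAsFactors = FALSE)
  validate_seq_records(rec)
  rec
}

validate_seq_records <- function(rec) {
  stopifnot(is.data.frame(rec),
            all(c("seq_id", "genome_id", "residues", "moltype") %in% names(rec)))
  if (any(!nzchar(rec$residues)))
    stop("empty sequence for record ", rec$seq_id[!nzchar(rec$residues)][1])
  dup <- duplicated(rec[, c("genome_id", "seq_id")])
  if (any(dup))
    stop("duplicate seq_id within genome: ", rec$seq_id[dup][1])
  for (i in seq_len(nrow(rec))) {
    alphabet <- if (rec$moltype[i] == "protein") PROTEIN_ALPHABET else DNA_ALPHABET
    bad <- regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")),
                   rec$residues[i])
    if (bad > 0)
      stop(sprintf("invalid character '%s' at position %d of record %s",
                   substr(rec$residues[i], bad, bad), bad, rec$seq_id[i]))
  }
  invisible(rec)
}

#' Read a FASTA file into sequence records
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; this wrapper adds
#' the screen's validation: the header token before the first whitespace
#' becomes \code{seq_id}, wrapped lines are concatenated, input case is
#' folded to uppercase, duplicated ids and out-of-alphabet characters are
#' errors (the error names the record and position).
#'
#' @param path FASTA file.
#' @param moltype \code{"protein"} or \code{"dna"}.
#' @param genome_id genome label attached to every record; defaults to the
#'   file name without extension.
#' @return a \code{seq_records} data frame, in file order.
#' @export
read_fasta <- function(path, moltype, genome_id = NULL) {
  moltype <- match.arg(moltype, c("protein", "dna"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("empty or malformed FASTA file: ",
                                           path, call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA header in ", path, ": ", ids[duplicated(ids)][1])
  seq_records(ids, as.character(set), genome_id, moltype)
}

#' Write sequence records as FASTA
#'
#' Sequences are wrapped at a fixed line width (default 60 columns), so
#' \code{write_fasta} followed by [read_fasta()] reproduces the records.
#'
#' @param rec a \code{seq_records} data frame.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(rec, path, width = 60L) {
  validate_seq_records(rec)
  set <- Biostrings::BStringSet(setNames(rec$residues, rec$seq_id))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
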
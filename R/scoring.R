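#' Build a scoring scheme for protein local alignment
#'
#' Bundles a symmetric integer substitution matrix, affine gap penalties and
#' the ungapped Karlin-Altschul parameters \eqn{\lambda} (nats) and \eqn{K}
#' used to convert raw scores into bit scores and E-values. The default
#' mirrors common protein-search settings: BLOSUM62, gap open -11, gap
#' extend -1, \eqn{\lambda = 0.3176}, \eqn{K = 0.134}. A gap of length L
#' scores \code{gap_open + L * gap_extend}.
#'
#' Two deliberate overrides of the stock BLOSUM62 table: the ambiguity
#' residue \code{X} scores 0 against everything, and the stop character
#' \code{*} (which only arises in translated frames) scores -4 against
#' everything, so extensions never cross a stop profitably.
#'
#' @param matrix integer substitution matrix with residue dimnames; defaults
#'   to BLOSUM62 restricted to the 20 canonical residues plus \code{X} and
#'   \code{*} with the overrides above.
#' @param gap_open gap-opening score, an integer \eqn{\le 0}.
#' @param gap_extend per-residue gap-extension score, an integer \eqn{\le 0}.
#' @param lambda,K positive Karlin-Altschul parameters for the ungapped
#'   model; see [evalue()].
#' @return an object of class \code{scoring_scheme}.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["W", "W"]
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = -11L, gap_extend = -1L,
                           lambda = 0.3176, K = 0.134) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("substitution matrix must be square")
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix needs identical row/column residue names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be scores <= 0")
  if (!is.finite(lambda) || lambda <= 0 || !is.finite(K) || K <= 0)
    stop("lambda and K must be finite and > 0")
  keep <- intersect(names(AA_BACKGROUND), rownames(matrix))
  if (length(keep) < 20)
    stop("matrix must cover the 20 canonical amino acids")
  f <- AA_BACKGROUND[keep]
  exp_score <- sum(outer(f, f) * matrix[keep, keep])
  if (exp_score >= 0)
    stop("expected substitution score under background frequencies must be negative")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: %d-letter matrix, gap %d/%d, lambda %.4f, K %.3f\n",
              nrow(x$matrix), x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

# BLOSUM62 (from Biostrings) restricted to the 20 canonical residues plus
# X and '*', with X scored 0 and '*' scored -4 against everything.
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b62 <- env$BLOSUM62
  letters <- c(AA20, "X", "*")
  m <- b62[letters, letters]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m["*", ] <- -4L
  m[, "*"] <- -4L
  storage.mode(m) <- "integer"
  m
}

# Map a residue string to 0-based matrix indices; errors name the offender.
encode_residues <- function(x, alphabet, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d of %s", chars[p], p, what))
  }
  idx - 1L
}
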
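# PresenceMatrix: per focal gene x genome evidence table. Stored as three
# aligned matrices (best E-value, presence flag, evidence source) over all
# ingroup and outgroup genomes, with the genome roles kept alongside.

new_presence_matrix <- function(genes, config) {
  genomes <- c(ingroup_genomes(config), config$outgroup_genomes)
  role <- setNames(c(rep("ingroup", length(ingroup_genomes(config))),
                     rep("outgroup", length(config$outgroup_genomes))),
                   genomes)
  ev <- matrix(NA_real_, length(genes), length(genomes),
               dimnames = list(genes, genomes))
  pres <- matrix(FALSE, length(genes), length(genomes),
                 dimnames = list(genes, genomes))
  src <- matrix("none", length(genes), length(genomes),
                dimnames = list(genes, genomes))
  structure(list(evalue = ev, present = pres, evidence = src,
                 role = role, focal = config$focal_genome,
                 e_ingroup = config$e_ingroup,
                 e_exclusion = config$e_exclusion),
            class = "presence_matrix")
}

threshold_for <- function(pm, genome)
  ifelse(pm$role[genome] == "ingroup", pm$e_ingroup, pm$e_exclusion)

#' Build the presence/absence evidence matrix
#'
#' Records, for every focal gene and every ingroup/outgroup genome, the best
#' (minimum) E-value among the supplied hits; a cell is present when its
#' best E-value is strictly below the threshold for that genome's role
#' (ingroup threshold for ingroup genomes, exclusion threshold for
#' outgroups). Hits whose subject genome is the focal genome are discarded:
#' a gene trivially matches itself, so the focal genome never supplies
#' presence evidence.
#'
#' @param focal_proteome protein \code{seq_records} being screened.
#' @param hits hit data frame (any mix of genomes); hits referencing a
#'   genome absent from the configuration are an error.
#' @param config a [screen_config()].
#' @return a \code{presence_matrix}.
#' @export
build_presence_matrix <- function(focal_proteome, hits, config) {
  validate_hits(hits)
  pm <- new_presence_matrix(sort(focal_proteome$seq_id), config)
  hits <- hits[hits$subject_genome != config$focal_genome, , drop = FALSE]
  if (nrow(hits)) {
    known <- c(names(pm$role))
    bad <- setdiff(unique(hits$subject_genome), known)
    if (length(bad))
      stop("hit references unknown genome: ", bad[1])
    hits <- hits[hits$query_id %in% rownames(pm$evalue), , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      g <- hits$query_id[r]; G <- hits$subject_genome[r]
      e <- hits$evalue[r]
      if (is.na(pm$evalue[g, G]) || e < pm$evalue[g, G])
        pm$evalue[g, G] <- e
    }
    for (G in colnames(pm$present)) {
      thr <- threshold_for(pm, G)
      p <- !is.na(pm$evalue[, G]) & pm$evalue[, G] < thr
      pm$present[, G] <- p
      pm$evidence[p, G] <- "annotated"
    }
  }
  pm
}

#' Per-phylum ingroup presence criterion
#'
#' TRUE when every ingroup phylum contains at least one genome with
#' presence. Unless \code{allow_focal_evidence} is set, the focal genome is
#' ignored, so its phylum must be satisfied by a non-focal member genome.
#'
#' @param row named logical vector of presence over (at least) the ingroup
#'   genomes, e.g. one row of \code{pm$present}.
#' @param config a [screen_config()].
#' @return logical.
#' @export
ingroup_criterion <- function(row, config) {
  for (ph in names(config$ingroup_phyla)) {
    members <- config$ingroup_phyla[[ph]]
    if (!config$allow_focal_evidence)
      members <- setdiff(members, config$focal_genome)
    if (length(members) == 0 || !any(row[members], na.rm = TRUE))
      return(FALSE)
  }
  TRUE
}

#' Outgroup and reference-database exclusion
#'
#' A candidate is excluded when any outgroup-genome hit, or any
#' exclusion-database hit whose subject taxon lies outside the ingroup
#' clade, has an E-value strictly below the exclusion threshold.
#' Exclusion-database subjects labeled with an ingroup-clade taxon never
#' disqualify (reference databases inevitably contain clade entries).
#'
#' @param gene_id focal gene.
#' @param outgroup_hits hits of this gene against outgroup proteomes.
#' @param exclusion_hits hits against exclusion databases, carrying a
#'   \code{subject_taxon} column; a missing taxon label is an error.
#' @param config a [screen_config()].
#' @return list with \code{excluded} (logical) and \code{offending}, a data
#'   frame of disqualifying sources and their best E-values.
#' @export
outgroup_exclusion <- function(gene_id, outgroup_hits, exclusion_hits,
                               config) {
  off <- list()
  og <- outgroup_hits[outgroup_hits$query_id == gene_id &
                        outgroup_hits$evalue < config$e_exclusion, ,
                      drop = FALSE]
  if (nrow(og)) {
    best <- tapply(og$evalue, og$subject_genome, min)
    off[[1]] <- data.frame(source = names(best), evalue = as.numeric(best),
                           stringsAsFactors = FALSE)
  }
  if (!is.null(exclusion_hits) && nrow(exclusion_hits)) {
    if (!"subject_taxon" %in% names(exclusion_hits))
      stop("exclusion-database hits need a subject_taxon column")
    ex <- exclusion_hits[exclusion_hits$query_id == gene_id, , drop = FALSE]
    if (anyNA(ex$subject_taxon) || any(!nzchar(ex$subject_taxon)))
      stop("exclusion-database sequence without taxon label (gene ",
           gene_id, ")")
    ex <- ex[!(ex$subject_taxon %in% config$clade_taxa) &
               ex$evalue < config$e_exclusion, , drop = FALSE]
    if (nrow(ex)) {
      best <- tapply(ex$evalue, ex$subject_genome, min)
      off[[2]] <- data.frame(source = names(best), evalue = as.numeric(best),
                             stringsAsFactors = FALSE)
    }
  }
  off <- do.call(rbind, off)
  if (is.null(off))
    off <- data.frame(source = character(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  off <- off[order(off$source), , drop = FALSE]
  rownames(off) <- NULL
  list(excluded = nrow(off) > 0, offending = off)
}

#' Translated-search rescue of unannotated homologs
#'
#' Re-tests only the ingroup cells currently absent, for genomes with
#' scaffold DNA configured: the focal protein is searched against the
#' genome's six-frame translation at the rescue threshold, and a qualifying
#' hit flips the cell to present with evidence \code{"rescued"}. Present
#' cells are never touched and outgroup cells are never rescued.
#'
#' @param pm a \code{presence_matrix}.
#' @param focal_proteome the screened \code{seq_records}.
#' @param config a [screen_config()].
#' @param genome_dna named list genome id -> nucleotide \code{seq_records};
#'   defaults to reading the paths in \code{config$genome_dna}.
#' @param scoring a [scoring_scheme()].
#' @return the updated \code{presence_matrix}.
#' @export
rescue_unannotated <- function(pm, focal_proteome, config,
                               genome_dna = NULL,
                               scoring = scoring_scheme()) {
  if (is.null(genome_dna)) {
    if (is.null(config$genome_dna)) return(pm)
    genome_dna <- lapply(names(config$genome_dna), function(g)
      read_fasta(config$genome_dna[[g]], "dna", genome_id = g))
    names(genome_dna) <- names(config$genome_dna)
  }
  targets <- intersect(names(genome_dna), ingroup_genomes(config))
  targets <- setdiff(targets, config$focal_genome)
  for (G in sort(targets)) {
    absent <- rownames(pm$present)[!pm$present[, G]]
    for (g in absent) {
      q <- focal_proteome[focal_proteome$seq_id == g, , drop = FALSE]
      if (nrow(q) == 0) next
      hits <- translated_search(q, genome_dna[[G]], scoring,
                                threshold = config$e_rescue)
      if (nrow(hits) == 0) next
      best <- min(hits$evalue)
      pm$present[g, G] <- TRUE
      pm$evidence[g, G] <- "rescued"
      pm$evalue[g, G] <- min(best, pm$evalue[g, G], na.rm = TRUE)
    }
  }
  pm
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d genes x %d genomes (%d ingroup, %d outgroup)\n",
              nrow(x$present), ncol(x$present),
              sum(x$role == "ingroup"), sum(x$role == "outgroup")))
  cat(sprintf("  present cells: %d annotated, %d rescued\n",
              sum(x$evidence == "annotated"), sum(x$evidence == "rescued")))
  invisible(x)
}
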
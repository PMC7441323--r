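#' Define a screen configuration
#'
#' Declares the focal genome, the ingroup phyla with their member genomes,
#' the outgroup genomes, optional reference exclusion databases, the three
#' E-value thresholds and the search engine. Defaults encode the screen's
#' canonical run: ingroup presence below \code{1e-7}, outgroup/reference
#' exclusion below \code{1e-5}, translated rescue below \code{1e-7}, all
#' strict inequalities.
#'
#' @param focal_genome genome id of the proteome being screened; must belong
#'   to exactly one ingroup phylum.
#' @param ingroup_phyla named list, phylum name -> character vector of
#'   genome ids; phyla must be pairwise disjoint and disjoint from the
#'   outgroups.
#' @param outgroup_genomes character vector of outgroup genome ids.
#' @param exclusion_dbs list of database descriptors, each a list with
#'   elements \code{name}, \code{path} (FASTA) and \code{taxa} (path of a
#'   two-column TSV \code{seq_id <TAB> taxon}); may be empty.
#' @param e_ingroup,e_exclusion,e_rescue strictly positive E-value
#'   thresholds.
#' @param proteomes optional named list/vector genome id -> protein FASTA
#'   path (required when running from files).
#' @param genome_dna optional named list/vector genome id -> nucleotide
#'   FASTA path (scaffolds), enabling the rescue stage for those genomes.
#' @param clade_taxa taxon labels considered inside the ingroup clade when
#'   filtering exclusion-database hits; defaults to the phylum names plus
#'   all ingroup genome ids.
#' @param engine \code{"internal"} (run the built-in search) or
#'   \code{"external_hits"} (ingest hit tables produced elsewhere).
#' @param allow_focal_evidence if \code{TRUE}, presence in the focal genome
#'   itself may satisfy its phylum's criterion; by default the criterion
#'   must be met by a non-focal member, since a gene trivially matches
#'   itself.
#' @param rescue_outgroups if \code{TRUE}, translated search is also used to
#'   disqualify candidates via unannotated outgroup loci (an extension; off
#'   by default, matching a rescue round run on ingroup genomes only).
#' @return an object of class \code{screen_config}.
#' @export
screen_config <- function(focal_genome, ingroup_phyla, outgroup_genomes,
                          exclusion_dbs = list(),
                          e_ingroup = 1e-7, e_exclusion = 1e-5,
                          e_rescue = 1e-7,
                          proteomes = NULL, genome_dna = NULL,
                          clade_taxa = NULL,
                          engine = c("internal", "external_hits"),
                          allow_focal_evidence = FALSE,
                          rescue_outgroups = FALSE) {
  engine <- match.arg(engine)
  if (!is.list(ingroup_phyla) || is.null(names(ingroup_phyla)) ||
      any(!nzchar(names(ingroup_phyla))))
    stop("ingroup_phyla must be a named list of genome-id vectors")
  ingroup_phyla <- lapply(ingroup_phyla, as.character)
  members <- unlist(ingroup_phyla, use.names = FALSE)
  if (anyDuplicated(members))
    stop("ingroup phyla overlap: genome ",
         members[duplicated(members)][1], " listed in two phyla")
  outgroup_genomes <- as.character(outgroup_genomes)
  if (length(intersect(members, outgroup_genomes)))
    stop("genome listed both as ingroup and outgroup: ",
         intersect(members, outgroup_genomes)[1])
  in_phy <- vapply(ingroup_phyla, function(g) focal_genome %in% g, logical(1))
  if (sum(in_phy) != 1)
    stop("focal genome must belong to exactly one ingroup phylum")
  for (thr in c(e_ingroup, e_exclusion, e_rescue))
    if (!is.numeric(thr) || !is.finite(thr) || thr <= 0)
      stop("E-value thresholds must be strictly positive")
  if (is.null(clade_taxa))
    clade_taxa <- c(names(ingroup_phyla), members)
  for (db in exclusion_dbs)
    if (is.null(db$name) || is.null(db$path))
      stop("each exclusion db needs a name and a path")
  structure(list(focal_genome = focal_genome,
                 ingroup_phyla = ingroup_phyla,
                 outgroup_genomes = outgroup_genomes,
                 exclusion_dbs = exclusion_dbs,
                 e_ingroup = e_ingroup, e_exclusion = e_exclusion,
                 e_rescue = e_rescue,
                 proteomes = proteomes, genome_dna = genome_dna,
                 clade_taxa = as.character(clade_taxa),
                 engine = engine,
                 allow_focal_evidence = isTRUE(allow_focal_evidence),
                 rescue_outgroups = isTRUE(rescue_outgroups)),
            class = "screen_config")
}

#' Load a screen configuration from a YAML file
#'
#' The file mirrors the arguments of [screen_config()]; omitted thresholds
#' take the defaults (1e-7 ingroup, 1e-5 exclusion, 1e-7 rescue). Relative
#' paths are resolved against the directory of the config file.
#'
#' @param path YAML file.
#' @return a validated \code{screen_config}.
#' @export
load_screen_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(x)
      if (grepl("^/", x)) x else file.path(base, x), character(1))
  }
  dbs <- lapply(y$exclusion_dbs, function(db) {
    db$path <- rel(db$path)
    if (!is.null(db$taxa)) db$taxa <- rel(db$taxa)
    db
  })
  screen_config(
    focal_genome = y$focal_genome,
    ingroup_phyla = y$ingroup_phyla,
    outgroup_genomes = unlist(y$outgroup_genomes),
    exclusion_dbs = dbs,
    e_ingroup = y$e_ingroup %||% 1e-7,
    e_exclusion = y$e_exclusion %||% 1e-5,
    e_rescue = y$e_rescue %||% 1e-7,
    proteomes = if (!is.null(y$proteomes)) as.list(rel(unlist(y$proteomes))),
    genome_dna = if (!is.null(y$genome_dna)) as.list(rel(unlist(y$genome_dna))),
    clade_taxa = y$clade_taxa,
    engine = y$engine %||% "internal",
    allow_focal_evidence = y$allow_focal_evidence %||% FALSE,
    rescue_outgroups = y$rescue_outgroups %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ingroup_genomes <- function(config)
  unlist(config$ingroup_phyla, use.names = FALSE)

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(paste0("screen_config: focal %s; %d ingroup genomes in %d phyla;",
                     " %d outgroups; thresholds %g/%g/%g; engine %s\n"),
              x$focal_genome, length(ingroup_genomes(x)),
              length(x$ingroup_phyla), length(x$outgroup_genomes),
              x$e_ingroup, x$e_exclusion, x$e_rescue, x$engine))
  invisible(x)
}
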
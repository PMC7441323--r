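#' Run the full taxonomically-restricted-gene screen
#'
#' Executes the screen's stages in order: build the presence/absence
#' evidence matrix from homology hits, run the translated-search rescue
#' round on absent ingroup cells, apply the per-phylum ingroup criterion,
#' then the outgroup/reference exclusion. Verdicts:
#' \describe{
#'   \item{lineage_specific}{passes the ingroup criterion and nothing
#'     disqualifies it -- the screen's positive outcome.}
#'   \item{rejected_ingroup}{some ingroup phylum has no detectable homolog
#'     (even after rescue).}
#'   \item{rejected_outgroup}{detectable in an outgroup genome or an
#'     extra-clade reference entry below the exclusion threshold.}
#' }
#' The result is deterministic given the inputs and invariant to the order
#' in which genes, genomes or hit rows are supplied.
#'
#' @param config a [screen_config()].
#' @param proteomes named list genome id -> protein \code{seq_records}; when
#'   \code{NULL}, read from \code{config$proteomes} paths. Must include the
#'   focal genome; with the internal engine it must cover all ingroup and
#'   outgroup genomes.
#' @param genome_dna named list genome id -> nucleotide \code{seq_records}
#'   for the rescue stage (or \code{NULL} to read from config paths; rescue
#'   is skipped for genomes without DNA).
#' @param exclusion_dbs named list db name -> list(records, taxa) where
#'   \code{records} is a protein \code{seq_records} and \code{taxa} a data
#'   frame \code{seq_id, taxon}; when \code{NULL}, read from
#'   \code{config$exclusion_dbs} descriptors.
#' @param hits externally produced hit data frame (engine
#'   \code{"external_hits"}); exclusion-database hits are recognized by
#'   \code{subject_genome} equal to the db name and joined with its taxon
#'   labels.
#' @param scoring a [scoring_scheme()].
#' @return an object of class \code{trg_screen}: list with \code{candidates}
#'   (one row per focal gene: verdict and evidence trail), \code{matrix}
#'   (the \code{presence_matrix}), \code{hits}, \code{report} (the TSV-ready
#'   report table) and \code{config}.
#' @export
run_screen <- function(config, proteomes = NULL, genome_dna = NULL,
                       exclusion_dbs = NULL, hits = NULL,
                       scoring = scoring_scheme()) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(proteomes)) {
    if (is.null(config$proteomes))
      stop("no proteomes supplied and none configured")
    proteomes <- lapply(names(config$proteomes), function(g)
      read_fasta(config$proteomes[[g]], "protein", genome_id = g))
    names(proteomes) <- names(config$proteomes)
  }
  focal <- proteomes[[config$focal_genome]]
  if (is.null(focal)) stop("focal proteome not supplied")
  if (is.null(exclusion_dbs) && length(config$exclusion_dbs)) {
    exclusion_dbs <- lapply(config$exclusion_dbs, function(db) {
      taxa <- utils::read.delim(db$taxa, header = FALSE, sep = "\t",
                                col.names = c("seq_id", "taxon"),
                                stringsAsFactors = FALSE)
      list(records = read_fasta(db$path, "protein", genome_id = db$name),
           taxa = taxa)
    })
    names(exclusion_dbs) <- vapply(config$exclusion_dbs, `[[`, "", "name")
  }
  if (nrow(focal) == 0) {
    empty <- empty_candidates()
    return(structure(list(candidates = empty, matrix = NULL,
                          hits = empty_hits(), exclusion_hits = empty_hits(),
                          report = screen_report(empty, NULL, empty_hits(),
                                                 config),
                          config = config),
                     class = "trg_screen"))
  }

  db_names <- names(exclusion_dbs) %||% character(0)
  if (config$engine == "internal") {
    search_one <- function(G) {
      subj <- proteomes[[G]]
      if (is.null(subj)) stop("no proteome supplied for genome ", G)
      search_proteome(focal, subj, scoring)
    }
    genome_targets <- sort(c(setdiff(ingroup_genomes(config),
                                     config$focal_genome),
                             config$outgroup_genomes))
    hits <- do.call(rbind, c(list(empty_hits()),
                             lapply(genome_targets, search_one)))
    exclusion_hits <- do.call(rbind, c(list(empty_hits()),
      lapply(sort(db_names), function(nm)
        search_proteome(focal, exclusion_dbs[[nm]]$records, scoring))))
  } else {
    if (is.null(hits)) stop("external_hits engine needs a hit table")
    validate_hits(hits)
    is_db <- hits$subject_genome %in% db_names
    exclusion_hits <- hits[is_db, , drop = FALSE]
    hits <- hits[!is_db, , drop = FALSE]
  }
  if (nrow(exclusion_hits)) {
    taxa <- do.call(rbind, lapply(names(exclusion_dbs), function(nm)
      cbind(exclusion_dbs[[nm]]$taxa, db = nm)))
    exclusion_hits$subject_taxon <-
      taxa$taxon[match(paste(exclusion_hits$subject_genome,
                             exclusion_hits$subject_id),
                       paste(taxa$db, taxa$seq_id))]
  } else if (nrow(exclusion_hits) == 0) {
    exclusion_hits$subject_taxon <- character(0)
  }

  pm <- build_presence_matrix(focal, hits, config)
  pm <- rescue_unannotated(pm, focal, config, genome_dna, scoring)

  genes <- rownames(pm$present)
  og_hits <- hits[hits$subject_genome %in% config$outgroup_genomes, ,
                  drop = FALSE]
  cand <- lapply(genes, function(g) {
    passes <- ingroup_criterion(pm$present[g, ], config)
    excl <- outgroup_exclusion(g, og_hits, exclusion_hits, config)
    rescued <- colnames(pm$evidence)[pm$evidence[g, ] == "rescued"]
    verdict <- if (!passes) "rejected_ingroup"
      else if (excl$excluded) "rejected_outgroup"
      else "lineage_specific"
    data.frame(gene_id = g, passes_ingroup = passes,
               excluded_by = paste(sprintf("%s:%.3g", excl$offending$source,
                                           excl$offending$evalue),
                                   collapse = ","),
               rescued_in = paste(rescued, collapse = ","),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  structure(list(candidates = cand, matrix = pm, hits = hits,
                 exclusion_hits = exclusion_hits,
                 report = screen_report(cand, pm, hits, config),
                 config = config),
            class = "trg_screen")
}

empty_candidates <- function()
  data.frame(gene_id = character(), passes_ingroup = logical(),
             excluded_by = character(), rescued_in = character(),
             verdict = character(), stringsAsFactors = FALSE)

# One row per focal gene: verdict, per-phylum and per-outgroup best E,
# rescue evidence, novelty class (filled by classify_candidates()).
screen_report <- function(cand, pm, hits, config) {
  rep <- data.frame(gene_id = cand$gene_id, verdict = cand$verdict,
                    stringsAsFactors = FALSE)
  for (ph in names(config$ingroup_phyla)) {
    col <- paste0("best_e_", ph)
    rep[[col]] <- vapply(cand$gene_id, function(g) {
      if (is.null(pm)) return(NA_real_)
      members <- setdiff(config$ingroup_phyla[[ph]], config$focal_genome)
      suppressWarnings(min(pm$evalue[g, members], na.rm = TRUE))
    }, numeric(1))
  }
  for (G in config$outgroup_genomes) {
    rep[[paste0("best_e_", G)]] <- vapply(cand$gene_id, function(g) {
      if (is.null(pm)) return(NA_real_)
      pm$evalue[g, G]
    }, numeric(1))
  }
  rep$rescued_in <- cand$rescued_in
  rep$excluded_by <- cand$excluded_by
  rep$novelty_class <- rep(NA_character_, nrow(rep))
  rep[order(rep$gene_id), , drop = FALSE]
}

#' Write a screen report as TSV
#' @param screen a \code{trg_screen} (or its \code{report} data frame).
#' @param path output file.
#' @export
write_screen_report <- function(screen, path) {
  rep <- if (inherits(screen, "trg_screen")) screen$report else screen
  out <- rep
  for (col in grep("^best_e_", names(out), value = TRUE))
    out[[col]] <- ifelse(is.finite(out[[col]]),
                         sprintf("%.6e", out[[col]]), "NA")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.trg_screen <- function(x, ...) {
  tab <- table(factor(x$candidates$verdict,
                      c("lineage_specific", "rejected_ingroup",
                        "rejected_outgroup")))
  cat(sprintf("trg_screen: %d genes screened against %d genomes\n",
              nrow(x$candidates), length(x$matrix$role)))
  cat(sprintf("  lineage_specific %d | rejected_ingroup %d | rejected_outgroup %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}
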
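#' Top-k baseline reference selection
#'
#' Simple reduction baselines: per contig, keep the k references with the
#' highest summarized score S (ties: larger S, then smaller reference id),
#' and take the union over contigs. k = 1 assumes a perfect assembly where
#' each contig is a single strain; k = 3 bounds the selection when at most
#' three strains can collapse into one contig.
#'
#' @param table A \code{contig_scores} data frame.
#' @param k Number of references kept per contig (>= 1).
#' @return Sorted character vector of selected reference ids.
#' @export
baseline_top_k <- function(table, k) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(table) == 0L) return(character())
  tab <- table[order(table$contig, -table$score, table$ref), ]
  rank_in_contig <- stats::ave(seq_len(nrow(tab)), tab$contig,
                               FUN = seq_along)
  sort(unique(tab$ref[rank_in_contig <= k]))
}

#' Reduce a reference database from contig mappings
#'
#' Full database-reduction stage: summarize contig-to-reference harmonic
#' scores, split contigs into unique (one mapped reference) and non-unique;
#' run the EM soft clustering on the non-unique contigs; classify each
#' contig at the species level; then select, per contig, the top
#' (estimate + offset) same-species references by posterior. References
#' that are the single target of a unique contig are included directly,
#' and those contigs take their species label from that target.
#'
#' @param contig_paf A \code{paf} data frame of contig-to-database
#'   alignments, or a path to a PAF file.
#' @param tax A \code{taxonomy_map} or path to a taxonomy TSV.
#' @param est Named integer vector of collapsed-strain estimates, or a path
#'   to an estimates TSV; missing contigs default to 1.
#' @param offset Extra references per contig beyond the estimate (default 2).
#' @param max_iter,tol EM stopping parameters (see [run_em()]).
#' @param literal_mstep See [em_step()].
#' @param em_all Run the EM over all contigs rather than only the
#'   non-unique ones (default FALSE).
#' @return An object of class \code{strainsift_reduction}: list with
#'   \code{refs} (sorted selected reference ids), \code{provenance}
#'   (selection table incl. unique-contig rows), \code{species} (contig ->
#'   species taxid), \code{em} (final EM state or NULL when every contig was
#'   unique), \code{unique_contigs}, \code{nonunique_contigs}.
#' @examples
#' b <- generate_community(community_spec(seed = 1))
#' red <- reduce_database(b$contig_paf, b$taxonomy, b$estimates)
#' red
#' @export
reduce_database <- function(contig_paf, tax, est = integer(), offset = 2L,
                            max_iter = 100L, tol = 1e-6,
                            literal_mstep = FALSE, em_all = FALSE) {
  if (is.character(contig_paf)) contig_paf <- read_paf(contig_paf)
  if (is.character(tax)) tax <- read_taxonomy(tax)
  if (is.character(est)) est <- read_estimates(est)
  scores <- summarize_contig_scores(contig_paf)
  if (nrow(scores) == 0L) stop("no contig mappings with positive score")
  n_refs <- tapply(scores$ref, scores$contig, function(x) length(unique(x)))
  uniq_contigs <- names(n_refs)[n_refs == 1L]
  nonu_contigs <- names(n_refs)[n_refs > 1L]
  if (em_all) {
    em_scores <- scores
  } else {
    em_scores <- scores[scores$contig %in% nonu_contigs, , drop = FALSE]
  }

  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  uniq_rows <- scores[scores$contig %in% uniq_contigs, , drop = FALSE]
  missing <- setdiff(unique(scores$ref), tax$seq_id)
  if (length(missing)) {
    stop("reference(s) absent from taxonomy: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }

  em <- NULL
  species <- stats::setNames(as.integer(sp_of_ref[uniq_rows$ref]),
                             uniq_rows$contig)
  prov <- NULL
  if (nrow(em_scores) > 0L) {
    em <- run_em(em_scores, max_iter = max_iter, tol = tol,
                 literal_mstep = literal_mstep)
    em_species <- classify_contig_species(em, tax)
    # unique-contig labels win where both exist (em_all mode)
    species <- c(em_species[setdiff(names(em_species), names(species))],
                 species)
    prov <- select_references(em, em_species, tax, est = est,
                              offset = offset)
  }

  # unique-contig targets bypass the budget: posterior 1, rank 1
  if (nrow(uniq_rows) > 0L) {
    uniq_prov <- data.frame(
      contig = uniq_rows$contig, ref = uniq_rows$ref,
      posterior = 1, score = uniq_rows$score, rank = 1L,
      budget = NA_integer_,
      species_taxid = as.integer(sp_of_ref[uniq_rows$ref]),
      stringsAsFactors = FALSE
    )
    prov <- rbind(as.data.frame(prov), uniq_prov)
  } else {
    prov <- as.data.frame(prov)
  }
  prov <- prov[order(prov$contig, prov$rank, prov$ref), ]
  rownames(prov) <- NULL

  out <- list(refs = sort(unique(prov$ref)),
              provenance = prov,
              species = species[order(names(species))],
              em = em,
              unique_contigs = sort(uniq_contigs),
              nonunique_contigs = sort(nonu_contigs),
              offset = as.integer(offset))
  class(out) <- "strainsift_reduction"
  out
}

#' @export
print.strainsift_reduction <- function(x, ...) {
  cat("Reduced reference database\n")
  cat("  selected references:", length(x$refs), "\n")
  cat("  contigs:", length(x$species),
      sprintf("(%d unique, %d multi-mapped)\n",
              length(x$unique_contigs), length(x$nonunique_contigs)))
  if (!is.null(x$em)) {
    cat("  EM iterations:", x$em$iterations,
        " final log-likelihood:", format(x$em$loglik, digits = 8), "\n")
  }
  invisible(x)
}

#' @export
summary.strainsift_reduction <- function(object, ...) {
  print(object)
  sp <- table(object$provenance$species_taxid[
    !duplicated(object$provenance$ref)])
  cat("  references per species:\n")
  print(sp)
  invisible(object)
}

#' Write reduction outputs
#'
#' Emits \code{reduced_refs.txt} (one reference id per line),
#' \code{reduction_provenance.tsv}, and \code{em_trace.tsv} (iteration,
#' log-likelihood) under \code{out_dir}.
#'
#' @param reduction A \code{strainsift_reduction}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reduction <- function(reduction, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "reduced_refs.txt")
  writeLines(reduction$refs, p1)
  p2 <- file.path(out_dir, "reduction_provenance.tsv")
  utils::write.table(as.data.frame(reduction$provenance), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p3 <- file.path(out_dir, "em_trace.tsv")
  tr <- if (is.null(reduction$em)) {
    data.frame(iteration = integer(), loglik = numeric())
  } else {
    data.frame(iteration = seq_along(reduction$em$loglik_trace),
               loglik = reduction$em$loglik_trace)
  }
  utils::write.table(tr, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
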
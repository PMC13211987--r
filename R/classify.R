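#' Species-level assignment of reads
#'
#' For each read, the maximum score per species is the best match-ratio
#' score over that species' references; the read is assigned the species
#' attaining the overall maximum. Reads whose best score is tied exactly
#' across two or more species (rare, usually a taxonomic inconsistency
#' between near-identical genomes filed under different species) are
#' distributed uniformly at random among the tied species. The draw uses a
#' single generator seeded once and consumed in sorted read-id order, so
#' results do not depend on input file order.
#'
#' @param table A \code{read_scores} data frame.
#' @param tax A \code{taxonomy_map}.
#' @param seed Integer seed for the cross-species tie draws.
#' @param tol Score tolerance used when comparing species maxima (default 0).
#' @return A data frame with columns \code{read}, \code{species_taxid},
#'   \code{tie_broken} (logical: TRUE when the species was drawn at random).
#' @export
assign_species <- function(table, tax, seed = 42L, tol = 0) {
  if (nrow(table) == 0L) {
    return(data.frame(read = character(), species_taxid = integer(),
                      tie_broken = logical(), stringsAsFactors = FALSE))
  }
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  sp <- sp_of_ref[table$ref]
  stopifnot(!anyNA(sp))
  key <- paste(table$read, sp, sep = "\r")
  smax <- tapply(table$score, key, max)
  parts <- strsplit(names(smax), "\r", fixed = TRUE)
  tab <- data.frame(read = vapply(parts, `[`, "", 1L),
                    species = as.integer(vapply(parts, `[`, "", 2L)),
                    smax = as.numeric(smax), stringsAsFactors = FALSE)
  best <- tapply(tab$smax, tab$read, max)
  tab <- tab[tab$smax >= best[tab$read] - tol, , drop = FALSE]
  reads <- sort(unique(tab$read))
  n_tied <- table(tab$read)
  out <- data.frame(read = reads,
                    species_taxid = NA_integer_,
                    tie_broken = as.logical(n_tied[reads] > 1L),
                    stringsAsFactors = FALSE)
  # deterministic part
  single <- tab[tab$read %in% names(n_tied)[n_tied == 1L], ]
  out$species_taxid[match(single$read, out$read)] <- single$species
  # random draws in sorted read order from one seeded stream
  tied_reads <- sort(names(n_tied)[n_tied > 1L])
  if (length(tied_reads)) {
    rng <- local_rng(seed)
    for (r in tied_reads) {
      cand <- sort(tab$species[tab$read == r])
      out$species_taxid[out$read == r] <- rng$sample1(cand)
    }
  }
  out
}

# Small self-contained RNG wrapper so species-tie draws never disturb the
# caller's .Random.seed.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env <- new.env()
  env$state <- state
  env$sample1 <- function(x) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    val <- x[sample.int(length(x), 1L)]
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    val
  }
  env
}

#' Per-reference unique / non-unique mapping counts within species
#'
#' Within each species, U_i counts the reads whose single best hit is
#' reference i, N_i counts the reads best-score-tied across two or more
#' references including i, and M_i = U_i + N_i is the total mapping
#' support. A reference truly present in the sample should accumulate the
#' largest M_i in its cluster.
#'
#' @param table A \code{read_scores} data frame.
#' @param species_of_read Data frame from [assign_species()].
#' @param tax A \code{taxonomy_map}.
#' @param tol Best-score tie tolerance (default 0).
#' @return A data frame of class \code{reference_stats} with columns
#'   \code{ref}, \code{species_taxid}, \code{unique_count},
#'   \code{nonunique_count}, \code{total}.
#' @export
build_reference_stats <- function(table, species_of_read, tax, tol = 0) {
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  sp_read <- stats::setNames(species_of_read$species_taxid,
                             species_of_read$read)
  # restrict each read's candidates to its assigned species
  tab <- table[sp_of_ref[table$ref] == sp_read[table$read], , drop = FALSE]
  part <- partition_reads(tab, tol = tol)
  best <- part$best
  u <- table(best$ref[best$read %in% part$unique])
  n <- table(best$ref[best$read %in% part$nonunique])
  refs <- sort(unique(best$ref))
  out <- data.frame(
    ref = refs,
    species_taxid = as.integer(sp_of_ref[refs]),
    unique_count = as.integer(ifelse(refs %in% names(u), u[refs], 0L)),
    nonunique_count = as.integer(ifelse(refs %in% names(n), n[refs], 0L)),
    stringsAsFactors = FALSE
  )
  out$total <- out$unique_count + out$nonunique_count
  rownames(out) <- NULL
  class(out) <- c("reference_stats", "data.frame")
  out
}

#' Group references sharing ambiguous reads, per species
#'
#' Within each species, two references are linked when at least
#' \code{min_shared} reads are best-score-tied between them; clusters are
#' the connected components of this graph. References sharing many reads
#' likely cover overlapping genomic regions of near-identical strains.
#'
#' @param table A \code{read_scores} data frame.
#' @param species_of_read Data frame from [assign_species()].
#' @param tax A \code{taxonomy_map}.
#' @param tol Best-score tie tolerance (default 0).
#' @param min_shared Minimum number of shared tied reads to draw an edge
#'   (default 1).
#' @return A data frame with columns \code{ref}, \code{species_taxid},
#'   \code{cluster} (integer id, unique across species).
#' @export
group_species_references <- function(table, species_of_read, tax, tol = 0,
                                     min_shared = 1L) {
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  sp_read <- stats::setNames(species_of_read$species_taxid,
                             species_of_read$read)
  tab <- table[sp_of_ref[table$ref] == sp_read[table$read], , drop = FALSE]
  part <- partition_reads(tab, tol = tol)
  best <- part$best
  refs <- sort(unique(best$ref))
  if (length(refs) == 0L) {
    return(data.frame(ref = character(), species_taxid = integer(),
                      cluster = integer(), stringsAsFactors = FALSE))
  }
  # edges: pairs of references tied on the same read
  tied <- best[best$read %in% part$nonunique, , drop = FALSE]
  edges <- character(0)
  if (nrow(tied)) {
    by_read <- split(tied$ref, tied$read)
    pair_list <- lapply(by_read, function(r) {
      r <- sort(unique(r))
      if (length(r) < 2L) return(NULL)
      cm <- utils::combn(r, 2L)
      paste(cm[1L, ], cm[2L, ], sep = "\r")
    })
    pair_counts <- table(unlist(pair_list, use.names = FALSE))
    edges <- names(pair_counts)[pair_counts >= min_shared]
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(refs)
  if (length(edges)) {
    em <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  out <- data.frame(ref = refs,
                    species_taxid = as.integer(sp_of_ref[refs]),
                    cluster = as.integer(comp[refs]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reassign non-unique reads inside reference clusters
#'
#' Every best-score-tied read is reassigned to the reference with the
#' largest total mapping count M_j among its tied candidates' cluster
#' (ties on M_j: larger unique count U_j, then smaller reference id).
#' Unique reads keep their single best hit.
#'
#' @param clusters Data frame from [group_species_references()].
#' @param stats A \code{reference_stats} data frame.
#' @param table A \code{read_scores} data frame.
#' @param species_of_read Data frame from [assign_species()].
#' @param tax A \code{taxonomy_map}.
#' @param tol Best-score tie tolerance (default 0).
#' @return A data frame with columns \code{read}, \code{ref}, \code{score},
#'   \code{status} (\code{unique} or \code{reassigned}).
#' @export
reassign_nonunique <- function(clusters, stats, table, species_of_read,
                               tax, tol = 0) {
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  sp_read <- stats::setNames(species_of_read$species_taxid,
                             species_of_read$read)
  tab <- table[sp_of_ref[table$ref] == sp_read[table$read], , drop = FALSE]
  part <- partition_reads(tab, tol = tol)
  best <- part$best
  cl_of_ref <- stats::setNames(clusters$cluster, clusters$ref)
  m_of_ref <- stats::setNames(stats$total, stats$ref)
  u_of_ref <- stats::setNames(stats$unique_count, stats$ref)

  uniq <- best[best$read %in% part$unique, , drop = FALSE]
  out_u <- data.frame(read = uniq$read, ref = uniq$ref, score = uniq$score,
                      status = rep("unique", nrow(uniq)),
                      stringsAsFactors = FALSE)

  tied <- best[best$read %in% part$nonunique, , drop = FALSE]
  out_n <- NULL
  if (nrow(tied)) {
    # target cluster: the component containing the read's top-listed
    # candidate (all candidates share it when tol = 0)
    ord <- order(tied$read, -tied$score,
                 -as.numeric(m_of_ref[tied$ref]),
                 -as.numeric(u_of_ref[tied$ref]), tied$ref)
    tied <- tied[ord, ]
    top <- tied[!duplicated(tied$read), , drop = FALSE]
    target_cluster <- cl_of_ref[top$ref]
    # winner of each cluster: argmax M, tie-break larger U then smaller id
    cl_tab <- clusters
    cl_tab$m <- as.numeric(m_of_ref[cl_tab$ref])
    cl_tab$u <- as.numeric(u_of_ref[cl_tab$ref])
    cl_tab$m[is.na(cl_tab$m)] <- 0
    cl_tab$u[is.na(cl_tab$u)] <- 0
    cl_tab <- cl_tab[order(cl_tab$cluster, -cl_tab$m, -cl_tab$u,
                           cl_tab$ref), ]
    winner <- cl_tab[!duplicated(cl_tab$cluster), ]
    win_of_cluster <- stats::setNames(winner$ref, winner$cluster)
    assigned <- win_of_cluster[as.character(target_cluster)]
    sc <- stats::setNames(top$score, top$read)
    out_n <- data.frame(read = top$read, ref = as.character(assigned),
                        score = as.numeric(sc[top$read]),
                        status = "reassigned", stringsAsFactors = FALSE)
  }
  out <- rbind(out_u, out_n)
  out <- out[order(out$read), ]
  rownames(out) <- NULL
  out
}

#' Classify reads against a reference database
#'
#' Orchestrates the full read-classification stage: match-ratio scoring
#' with best-hit retention per (read, reference) pair, unique/non-unique
#' partition, species-level assignment (with seeded random resolution of
#' exact cross-species ties), per-reference mapping statistics, tie-graph
#' clustering of same-species references, and argmax reassignment of
#' non-unique reads to the best-supported reference of their cluster.
#' Reads mapped only to references absent from the taxonomy are reported
#' unclassified with a warning. This stage alone classifies reads against
#' a full, un-reduced database.
#'
#' @param read_paf A \code{paf} data frame of read-to-database alignments,
#'   or a path to a PAF file.
#' @param tax A \code{taxonomy_map} or path to a taxonomy TSV.
#' @param seed Seed for cross-species tie draws (default 42).
#' @param tol Best-score tie tolerance (default 0).
#' @param min_shared Minimum shared tied reads for a cluster edge.
#' @param read_ids Optional character vector of all read ids in the sample;
#'   reads with no mapping are emitted with status \code{unclassified}.
#' @return An object of class \code{read_assignments}: a data frame with
#'   columns \code{read_id}, \code{ref_id}, \code{strain_taxid},
#'   \code{species_taxid}, \code{score}, \code{status} (one of
#'   \code{unique}, \code{reassigned}, \code{species_tie_random},
#'   \code{unclassified}), sorted by read id. Attributes carry the
#'   \code{read_scores} table and \code{reference_stats}.
#' @examples
#' b <- generate_community(community_spec(seed = 1))
#' cls <- classify_reads(b$read_paf, b$taxonomy, seed = 1,
#'                       read_ids = b$truth$read_id)
#' table(cls$status)
#' @export
classify_reads <- function(read_paf, tax, seed = 42L, tol = 0,
                           min_shared = 1L, read_ids = NULL) {
  if (is.character(read_paf)) read_paf <- read_paf(read_paf)
  if (is.character(tax)) tax <- read_taxonomy(tax)
  table <- read_score_table(read_paf)

  orphan_reads <- character()
  unknown <- !table$ref %in% tax$seq_id
  if (any(unknown)) {
    known_reads <- unique(table$read[!unknown])
    orphan_reads <- setdiff(unique(table$read[unknown]), known_reads)
    if (length(orphan_reads)) {
      warning(length(orphan_reads),
              " read(s) mapped only to references absent from the ",
              "taxonomy; reported unclassified")
    }
    table <- table[!unknown, , drop = FALSE]
  }

  sp_read <- assign_species(table, tax, seed = seed, tol = tol)
  stats <- build_reference_stats(table, sp_read, tax, tol = tol)
  clusters <- group_species_references(table, sp_read, tax, tol = tol,
                                       min_shared = min_shared)
  calls <- reassign_nonunique(clusters, stats, table, sp_read, tax,
                              tol = tol)

  strain_of_ref <- stats::setNames(tax$strain_taxid, tax$seq_id)
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  tie_broken <- stats::setNames(sp_read$tie_broken, sp_read$read)
  status <- calls$status
  status[tie_broken[calls$read]] <- "species_tie_random"
  out <- data.frame(
    read_id = calls$read,
    ref_id = calls$ref,
    strain_taxid = as.integer(strain_of_ref[calls$ref]),
    species_taxid = as.integer(sp_of_ref[calls$ref]),
    score = calls$score,
    status = status,
    stringsAsFactors = FALSE
  )
  missing_ids <- union(orphan_reads,
                       if (is.null(read_ids)) character()
                       else setdiff(read_ids, out$read_id))
  if (length(missing_ids)) {
    out <- rbind(out, data.frame(
      read_id = sort(missing_ids), ref_id = NA_character_,
      strain_taxid = NA_integer_, species_taxid = NA_integer_,
      score = NA_real_, status = "unclassified",
      stringsAsFactors = FALSE
    ))
  }
  out <- out[order(out$read_id), ]
  rownames(out) <- NULL
  class(out) <- c("read_assignments", "data.frame")
  attr(out, "read_scores") <- table
  attr(out, "reference_stats") <- stats
  attr(out, "clusters") <- clusters
  attr(out, "species_of_read") <- sp_read
  out
}

#' @export
print.read_assignments <- function(x, ...) {
  cat("Read assignments:", nrow(x), "reads\n")
  print(table(x$status))
  invisible(x)
}

#' @export
summary.read_assignments <- function(object, ...) {
  print(object)
  called <- object[!is.na(object$ref_id), ]
  if (nrow(called)) {
    cat("Top references by read count:\n")
    print(utils::head(sort(table(called$ref_id), decreasing = TRUE), 10L))
  }
  invisible(object)
}
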
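#' Binary read-support vectors per reference
#'
#' For each species, builds a binary matrix with one row per reference and
#' one column per read: bit (i, k) is set when read k strongly supports
#' reference i, i.e. reference i attains read k's maximum score within the
#' species (within the tie tolerance). References never supported by any
#' read are omitted.
#'
#' @param table A \code{read_scores} data frame.
#' @param tax A \code{taxonomy_map}.
#' @param species_of_read Optional data frame from [assign_species()]; when
#'   supplied, each read contributes only within its assigned species.
#'   Otherwise every read contributes to every species it maps into.
#' @param tol Tie tolerance on the within-species maximum (default 0).
#' @return A named list (by species taxid) of binary matrices
#'   (references x reads).
#' @export
build_support_vectors <- function(table, tax, species_of_read = NULL,
                                  tol = 0) {
  sp_of_ref <- stats::setNames(tax$species_taxid, tax$seq_id)
  tab <- table[table$ref %in% tax$seq_id, , drop = FALSE]
  tab$species <- as.integer(sp_of_ref[tab$ref])
  if (!is.null(species_of_read)) {
    sp_read <- stats::setNames(species_of_read$species_taxid,
                               species_of_read$read)
    tab <- tab[tab$species == sp_read[tab$read], , drop = FALSE]
  }
  out <- lapply(split(tab, tab$species), function(sub) {
    best <- tapply(sub$score, sub$read, max)
    hit <- sub[sub$score >= best[sub$read] - tol, , drop = FALSE]
    refs <- sort(unique(hit$ref))
    reads <- sort(unique(hit$read))
    m <- matrix(0L, length(refs), length(reads),
                dimnames = list(refs, reads))
    m[cbind(hit$ref, hit$read)] <- 1L
    m
  })
  out
}

#' Jaccard distance between binary support vectors
#'
#' 1 - |intersection| / |union| of the set bits.
#'
#' @param u,v Binary (0/1) vectors of equal length, each with at least one
#'   set bit.
#' @return Distance in [0, 1]; 0 for identical supports, 1 for disjoint.
#' @export
jaccard_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  if (sum(u) == 0 || sum(v) == 0) stop("zero support vector")
  1 - sum(u & v) / sum(u | v)
}

# Pairwise Jaccard distance matrix over matrix rows.
jaccard_matrix <- function(m) {
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d
}

# DBSCAN over a precomputed distance matrix. A point is core when at least
# min_samples points (itself included) lie within eps; clusters grow from
# core points through eps-reachability; non-core border points join the
# first cluster that reaches them; remaining points are noise (label 0).
dbscan_precomputed <- function(d, eps, min_samples) {
  n <- nrow(d)
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_samples
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(neighbors[[i]], i)
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, neighbors[[j]])
      }
    }
  }
  labels
}

#' Density clustering of references by shared read support
#'
#' Runs DBSCAN over the precomputed Jaccard distance matrix of the binary
#' support vectors, per species. With the default \code{min_samples = 1}
#' every reference is a core point and the clusters are exactly the
#' connected components of the graph joining references at Jaccard
#' distance <= \code{eps}; two references therefore merge when their read
#' supports overlap by more than 1 - eps. Each cluster's representative is
#' the member with the largest total mapping count M (ties: smaller id).
#'
#' @param support Named list of binary support matrices (from
#'   [build_support_vectors()]).
#' @param stats Optional \code{reference_stats} for representative choice;
#'   when absent, row sums of the support matrix are used as M.
#' @param eps Maximum Jaccard distance for two references to be
#'   density-reachable (default 0.9).
#' @param min_samples Minimum neighbourhood size for a core point
#'   (default 1).
#' @return An object of class \code{strain_clusters}: a data frame with
#'   columns \code{species_taxid}, \code{cluster} (unique across species),
#'   \code{ref}, \code{representative}.
#' @export
density_cluster <- function(support, stats = NULL, eps = 0.9,
                            min_samples = 1L) {
  if (length(support) == 0L) stop("empty support matrix list")
  m_of_ref <- if (!is.null(stats)) {
    stats::setNames(stats$total, stats$ref)
  } else NULL
  next_id <- 0L
  rows <- lapply(names(support), function(sp) {
    m <- support[[sp]]
    keep <- rowSums(m) > 0L
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    ord <- order(rownames(m))
    m <- m[ord, , drop = FALSE]
    d <- jaccard_matrix(m)
    labels <- dbscan_precomputed(d, eps, min_samples)
    # noise points (possible when min_samples > 1) become singletons
    noise <- labels == 0L
    labels[noise] <- max(labels) + seq_len(sum(noise))
    data.frame(species_taxid = as.integer(sp),
               cluster = labels, ref = rownames(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no supported references")
  # make cluster ids unique across species
  key <- paste(out$species_taxid, out$cluster, sep = "\r")
  out$cluster <- as.integer(factor(key, levels = unique(key)))
  # representative per cluster: max M, ties smaller id
  support_m <- unlist(lapply(support, rowSums))
  names(support_m) <- unlist(lapply(support, rownames))
  m_val <- if (is.null(m_of_ref)) {
    as.numeric(support_m[out$ref])
  } else {
    v <- as.numeric(m_of_ref[out$ref])
    v[is.na(v)] <- 0
    v
  }
  ord <- order(out$cluster, -m_val, out$ref)
  first <- out[ord, ][!duplicated(out$cluster[ord]), ]
  rep_of_cluster <- stats::setNames(first$ref, first$cluster)
  out$representative <- as.character(rep_of_cluster[as.character(out$cluster)])
  rownames(out) <- NULL
  class(out) <- c("strain_clusters", "data.frame")
  out
}

#' Cluster-level abundance
#'
#' Sums member read counts within each reference cluster and reports the
#' total under the cluster representative's id. References carrying reads
#' but absent from the clustering are kept as their own singletons so
#' totals are conserved.
#'
#' @param assignments A \code{read_assignments} data frame.
#' @param clusters A \code{strain_clusters} data frame.
#' @return An \code{abundance_profile} keyed by representative ids.
#' @export
cluster_abundance <- function(assignments, clusters) {
  prof <- count_abundance(assignments)
  rep_of_ref <- stats::setNames(clusters$representative, clusters$ref)
  rep_id <- as.character(rep_of_ref[prof$ref_id])
  rep_id[is.na(rep_id)] <- prof$ref_id[is.na(rep_id)]
  counts <- rowsum(prof$read_count, rep_id)
  out <- data.frame(ref_id = rownames(counts),
                    read_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$relative_count <- out$read_count / sum(out$read_count)
  out <- out[order(out$ref_id), ]
  rownames(out) <- NULL
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' @export
print.strain_clusters <- function(x, ...) {
  cat("Reference clusters:", length(unique(x$cluster)), "clusters over",
      nrow(x), "references in", length(unique(x$species_taxid)),
      "species\n")
  invisible(x)
}

#' Write clustering outputs
#'
#' Emits \code{clusters.tsv} (cluster_id, representative, members) under
#' \code{out_dir}.
#'
#' @param clusters A \code{strain_clusters} data frame.
#' @param out_dir Output directory.
#' @return Invisibly, the path written.
#' @export
write_clusters <- function(clusters, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  members <- tapply(clusters$ref, clusters$cluster,
                    function(x) paste(sort(x), collapse = ","))
  reps <- tapply(clusters$representative, clusters$cluster, `[`, 1L)
  tab <- data.frame(cluster_id = as.integer(names(members)),
                    representative = as.character(reps[names(members)]),
                    members = as.character(members),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster_id), ]
  p <- file.path(out_dir, "clusters.tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
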
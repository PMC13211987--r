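#' Specify a synthetic community
#'
#' Describes a mock long-read metagenome at the mapping level: a reference
#' database of \code{n_refs} genomes, a community of
#' \code{n_species_present * strains_per_species} present strains, and the
#' ambiguity structure of contig and read mappings. Each present species
#' also contains \code{decoys_per_species} closely related references that
#' are absent from the sample; remaining database entries are filler
#' species with one reference each. No sequences are simulated — the
#' generator emits PAF records whose match counts and spans realize the
#' requested score structure directly, which is all the classifier
#' consumes.
#'
#' @param n_refs Database size G (default 50).
#' @param n_species_present Species with community members (default 4).
#' @param strains_per_species Present strains per such species (default 2,
#'   so K = 8 by default).
#' @param decoys_per_species Absent same-species references (default 3).
#' @param reads_per_strain Reads drawn from each present strain
#'   (default 200); a vector of length K sets uneven abundances.
#' @param contigs_per_strain Assembled contigs per present strain
#'   (default 3).
#' @param similarity Pairwise within-species similarity in [0, 1]; the
#'   contig score margin separating a true strain from its same-species
#'   neighbours shrinks linearly to 0 as similarity reaches 1
#'   (default 0.5).
#' @param tie_fraction Fraction of each strain's reads emitted as exact
#'   best-score ties with a present sibling strain (default 0.2; forced to
#'   0 when \code{strains_per_species} is 1).
#' @param junk_fraction,random_fraction,chimera_fraction Fractions of
#'   additional unmappable junk / random reads and chimeric reads
#'   (defaults 0.01 each, the Badread simulator's defaults).
#' @param read_length Typical read length in bp (default 5000,
#'   log-normal spread).
#' @param contig_length Typical contig span in bp (default 40000).
#' @param ref_length Reference genome length in bp (default 1e6).
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of the spec.
#' @return A \code{community_spec} list.
#' @export
community_spec <- function(n_refs = 50L, n_species_present = 4L,
                           strains_per_species = 2L,
                           decoys_per_species = 3L,
                           reads_per_strain = 200L,
                           contigs_per_strain = 3L,
                           similarity = 0.5, tie_fraction = 0.2,
                           junk_fraction = 0.01, random_fraction = 0.01,
                           chimera_fraction = 0.01,
                           read_length = 5000L, contig_length = 40000L,
                           ref_length = 1000000L, seed = 42L) {
  k <- n_species_present * strains_per_species
  if (k > n_refs) stop("more present strains than database references")
  need <- n_species_present * (strains_per_species + decoys_per_species)
  if (need > n_refs) stop("species structure needs more references than n_refs")
  if (similarity < 0 || similarity > 1) stop("similarity must be in [0, 1]")
  if (tie_fraction < 0 || tie_fraction > 1) {
    stop("tie_fraction must be in [0, 1]")
  }
  if (strains_per_species == 1L) tie_fraction <- 0
  reads_per_strain <- as.integer(rep(reads_per_strain, length.out = k))
  spec <- list(n_refs = as.integer(n_refs),
               n_species_present = as.integer(n_species_present),
               strains_per_species = as.integer(strains_per_species),
               decoys_per_species = as.integer(decoys_per_species),
               reads_per_strain = reads_per_strain,
               abundances = reads_per_strain / sum(reads_per_strain),
               contigs_per_strain = as.integer(contigs_per_strain),
               similarity = similarity, tie_fraction = tie_fraction,
               junk_fraction = junk_fraction,
               random_fraction = random_fraction,
               chimera_fraction = chimera_fraction,
               read_length = as.integer(read_length),
               contig_length = as.integer(contig_length),
               ref_length = as.integer(ref_length),
               seed = as.integer(seed))
  class(spec) <- "community_spec"
  spec
}

# Database layout: species taxids, strain taxids, present flags.
community_layout <- function(spec) {
  per_sp <- spec$strains_per_species + spec$decoys_per_species
  n_struct <- spec$n_species_present * per_sp
  n_filler <- spec$n_refs - n_struct
  ref_id <- sprintf("ref%03d", seq_len(spec$n_refs))
  species <- integer(spec$n_refs)
  present <- logical(spec$n_refs)
  idx <- 1L
  for (s in seq_len(spec$n_species_present)) {
    sp_tax <- 100000L + s
    for (j in seq_len(per_sp)) {
      species[idx] <- sp_tax
      present[idx] <- j <= spec$strains_per_species
      idx <- idx + 1L
    }
  }
  if (n_filler > 0L) {
    species[idx:spec$n_refs] <- 200000L + seq_len(n_filler)
  }
  list(ref_id = ref_id, species_taxid = species,
       strain_taxid = 500000L + seq_len(spec$n_refs),
       present = present)
}

#' Generate a synthetic community bundle
#'
#' Produces, deterministically under the spec's seed, every input the
#' pipeline consumes: a taxonomy map, contig-to-database and
#' read-to-database PAF files, per-contig collapsed-strain estimates, and
#' a ground-truth table with Badread-style labels. Present strains receive
#' contigs whose summarized scores dominate absent same-species references
#' by a margin shrinking with \code{similarity}; a \code{tie_fraction} of
#' reads is emitted as exact best-score ties between present sibling
#' strains; junk and random reads have no mappings at all.
#'
#' @param spec A \code{community_spec}.
#' @return A \code{community_bundle} list with elements \code{taxonomy},
#'   \code{contig_paf}, \code{read_paf}, \code{estimates}, \code{truth},
#'   \code{present_strains} (character vector of true reference ids) and
#'   \code{spec}.
#' @examples
#' b <- generate_community(community_spec(seed = 7))
#' length(b$present_strains)
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  lay <- community_layout(spec)
  tax <- taxonomy_map(lay$ref_id, lay$strain_taxid, lay$species_taxid,
                      rep(spec$ref_length, spec$n_refs))
  present_refs <- lay$ref_id[lay$present]

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  contigs <- make_contig_paf(spec, lay)
  reads <- make_read_paf(spec, lay)

  bundle <- list(taxonomy = tax,
                 contig_paf = contigs$paf,
                 estimates = contigs$estimates,
                 read_paf = reads$paf,
                 truth = reads$truth,
                 present_strains = present_refs,
                 spec = spec)
  class(bundle) <- "community_bundle"
  bundle
}

# Contig mappings: each present strain contributes contigs mapping best to
# that strain; same-species references score lower by a margin shrinking
# with similarity; one weak cross-species mapping adds realistic noise.
make_contig_paf <- function(spec, lay) {
  margin <- 0.08 * (1 - spec$similarity)
  per_sp <- spec$strains_per_species + spec$decoys_per_species
  rows <- list()
  est <- integer()
  ctg_i <- 0L
  filler <- lay$ref_id[lay$species_taxid >= 200000L]
  for (i in which(lay$present)) {
    sp <- lay$species_taxid[i]
    siblings <- lay$ref_id[lay$species_taxid == sp]
    for (k in seq_len(spec$contigs_per_strain)) {
      ctg_i <- ctg_i + 1L
      cid <- sprintf("contig%04d", ctg_i)
      span <- round(spec$contig_length * stats::runif(1, 0.8, 1.2))
      qlen <- span + 200L
      targets <- siblings
      q <- ifelse(targets == lay$ref_id[i], 0.98,
                  0.98 - margin - stats::runif(length(targets), 0, 0.02))
      if (length(filler) && stats::runif(1) < 0.3) {
        targets <- c(targets, filler[sample.int(length(filler), 1L)])
        q <- c(q, stats::runif(1, 0.55, 0.70))
      }
      n_match <- round(q * span)
      tstart <- sample.int(spec$ref_length - span, length(targets))
      rows[[length(rows) + 1L]] <- paf_record(
        query_name = cid, query_len = qlen, query_start = 100L,
        query_end = 100L + span, strand = "+",
        target_name = targets, target_len = spec$ref_length,
        target_start = tstart, target_end = tstart + span,
        residue_matches = n_match, alignment_block_len = span,
        mapq = 60L
      )
      est[cid] <- 1L
    }
  }
  paf <- do.call(rbind, rows)
  class(paf) <- c("paf", "data.frame")
  list(paf = paf, estimates = est)
}

# Read mappings: per present strain, good reads (a tie_fraction of them
# exactly tied with a sibling present strain), then junk/random reads with
# no mappings and chimeras mapped to one of their two sources.
make_read_paf <- function(spec, lay) {
  margin_r <- 0.05 + 0.03 * (1 - spec$similarity)
  rows <- list()
  truth_rows <- list()
  present_idx <- which(lay$present)
  read_i <- 0L
  k <- 0L
  for (i in present_idx) {
    k <- k + 1L
    sp <- lay$species_taxid[i]
    sib_present <- setdiff(lay$ref_id[lay$species_taxid == sp & lay$present],
                           lay$ref_id[i])
    sib_all <- setdiff(lay$ref_id[lay$species_taxid == sp], lay$ref_id[i])
    n_reads <- spec$reads_per_strain[k]
    n_tie <- round(spec$tie_fraction * n_reads)
    for (j in seq_len(n_reads)) {
      read_i <- read_i + 1L
      rid <- sprintf("read%06d", read_i)
      rl <- max(500L, round(stats::rlnorm(1, log(spec$read_length), 0.3)))
      span <- rl
      q <- stats::runif(1, 0.93, 0.985)
      n_match <- round(q * span)
      tied <- j <= n_tie && length(sib_present) > 0L
      targets <- lay$ref_id[i]
      nm <- n_match
      if (tied) {
        mate <- sib_present[sample.int(length(sib_present), 1L)]
        targets <- c(targets, mate)
        nm <- c(n_match, n_match)
      }
      # lower-scoring secondary hits to the other same-species refs
      others <- setdiff(sib_all, targets)
      if (length(others)) {
        q2 <- pmax(0.5, q - margin_r - stats::runif(length(others), 0, 0.02))
        targets <- c(targets, others)
        nm <- c(nm, round(q2 * span))
      }
      tstart <- sample.int(spec$ref_length - span, length(targets))
      rows[[length(rows) + 1L]] <- paf_record(
        query_name = rid, query_len = rl, query_start = 0L,
        query_end = span, strand = "+",
        target_name = targets, target_len = spec$ref_length,
        target_start = tstart, target_end = tstart + span,
        residue_matches = nm, alignment_block_len = span, mapq = 60L
      )
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(read_id = rid, true_ref_id = lay$ref_id[i],
                   badread_label = "good", stringsAsFactors = FALSE)
    }
  }
  n_good <- read_i
  extra <- function(frac, label, mapped) {
    n <- round(frac * n_good)
    for (j in seq_len(n)) {
      read_i <<- read_i + 1L
      rid <- sprintf("read%06d", read_i)
      if (mapped) {
        src <- present_idx[sample.int(length(present_idx), 1L)]
        rl <- max(500L, round(stats::rlnorm(1, log(spec$read_length), 0.3)))
        span <- max(400L, round(rl * 0.5))
        n_match <- round(stats::runif(1, 0.90, 0.97) * span)
        tstart <- sample.int(spec$ref_length - span, 1L)
        rows[[length(rows) + 1L]] <<- paf_record(
          query_name = rid, query_len = rl, query_start = 0L,
          query_end = span, strand = "+",
          target_name = lay$ref_id[src], target_len = spec$ref_length,
          target_start = tstart, target_end = tstart + span,
          residue_matches = n_match, alignment_block_len = span,
          mapq = 60L
        )
        truth_rows[[length(truth_rows) + 1L]] <<-
          data.frame(read_id = rid, true_ref_id = lay$ref_id[src],
                     badread_label = label, stringsAsFactors = FALSE)
      } else {
        truth_rows[[length(truth_rows) + 1L]] <<-
          data.frame(read_id = rid, true_ref_id = NA_character_,
                     badread_label = label, stringsAsFactors = FALSE)
      }
    }
  }
  extra(spec$chimera_fraction, "chimera", mapped = TRUE)
  extra(spec$junk_fraction, "junk", mapped = FALSE)
  extra(spec$random_fraction, "random", mapped = FALSE)
  paf <- do.call(rbind, rows)
  class(paf) <- c("paf", "data.frame")
  truth <- do.call(rbind, truth_rows)
  truth <- truth_table(truth$read_id, truth$true_ref_id,
                       truth$badread_label)
  list(paf = paf, truth = truth)
}

#' Generate a collapsed-contig fixture
#'
#' Emulates the assembly artifact where n closely related strains merge
#' into one consensus contig: the contig maps with (near-)equal top scores
#' to all n present strains of one species, and the collapsed-strain
#' estimate for that contig equals n, so the budgeted selection
#' (estimate + offset) must retain every one of the n strains.
#'
#' @param spec A \code{community_spec} whose \code{strains_per_species} is
#'   at least \code{n}.
#' @param n Number of strains collapsed into the contig (default 2).
#' @return A list with \code{contig_paf}, \code{estimates} (the collapsed
#'   contig's estimate equals \code{n}), \code{taxonomy},
#'   \code{collapsed_contig} (its id) and \code{true_strains} (the n
#'   reference ids that must be recovered).
#' @export
generate_collapsed_contigs <- function(spec, n = 2L) {
  stopifnot(inherits(spec, "community_spec"))
  if (spec$strains_per_species < n) {
    stop("species structure has fewer than n present strains")
  }
  bundle <- generate_community(spec)
  lay <- community_layout(spec)
  sp <- lay$species_taxid[which(lay$present)[1L]]
  collapsed <- lay$ref_id[lay$species_taxid == sp & lay$present][seq_len(n)]
  siblings <- setdiff(lay$ref_id[lay$species_taxid == sp], collapsed)
  span <- spec$contig_length
  cid <- "contig_collapsed"
  targets <- c(collapsed, siblings)
  q <- c(rep(0.98, n), rep(0.90, length(siblings)))
  paf <- paf_record(
    query_name = cid, query_len = span + 200L, query_start = 100L,
    query_end = 100L + span, strand = "+",
    target_name = targets, target_len = spec$ref_length,
    target_start = 1000L, target_end = 1000L + span,
    residue_matches = round(q * span), alignment_block_len = span,
    mapq = 60L
  )
  contig_paf <- rbind(as.data.frame(bundle$contig_paf), as.data.frame(paf))
  class(contig_paf) <- c("paf", "data.frame")
  est <- bundle$estimates
  est[cid] <- as.integer(n)
  list(contig_paf = contig_paf, estimates = est,
       taxonomy = bundle$taxonomy, collapsed_contig = cid,
       true_strains = collapsed)
}

#' Write a community bundle to disk
#'
#' Emits \code{taxonomy.tsv}, \code{contigs.paf}, \code{reads.paf},
#' \code{estimates.tsv}, \code{truth.tsv} and a \code{manifest.tsv}
#' recording the spec fields, under \code{out_dir}. Rewriting the same
#' bundle produces byte-identical files.
#'
#' @param bundle A \code{community_bundle}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    contig_paf = file.path(out_dir, "contigs.paf"),
    read_paf = file.path(out_dir, "reads.paf"),
    estimates = file.path(out_dir, "estimates.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  write_taxonomy(bundle$taxonomy, paths["taxonomy"])
  write_paf(bundle$contig_paf, paths["contig_paf"])
  write_paf(bundle$read_paf, paths["read_paf"])
  write_estimates(bundle$estimates, paths["estimates"])
  write_truth(bundle$truth, paths["truth"])
  sp <- bundle$spec
  man <- data.frame(
    field = names(sp),
    value = vapply(sp, function(v) paste(format(v), collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(man, paths["manifest"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @export
print.community_bundle <- function(x, ...) {
  cat("Synthetic community bundle\n")
  cat("  database references:", nrow(x$taxonomy), "\n")
  cat("  present strains:", length(x$present_strains), "\n")
  cat("  contig mappings:", nrow(x$contig_paf), "\n")
  cat("  read mappings:", nrow(x$read_paf),
      "(", length(unique(x$read_paf$query_name)), "reads )\n")
  cat("  truth reads:", nrow(x$truth), "\n")
  invisible(x)
}

#' Keep only PAF records whose target is in a reference set
#'
#' Used to re-scope a full-database mapping file to a reduced database
#' without re-mapping.
#'
#' @param paf A \code{paf} data frame.
#' @param refs Character vector of reference ids to keep.
#' @return The filtered \code{paf}.
#' @export
filter_paf_targets <- function(paf, refs) {
  out <- paf[paf$target_name %in% refs, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paf", "data.frame")
  out
}
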
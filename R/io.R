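#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated columns of the Pairwise mApping
#' Format emitted by minimap2. Optional SAM-style tags beyond column 12 are
#' ignored. Coordinates follow the PAF convention: 0-based, half-open.
#'
#' @param path Path to a PAF file. An empty file yields a zero-row table.
#' @return A data frame of class \code{paf} with one row per alignment and
#'   columns \code{query_name}, \code{query_len}, \code{query_start},
#'   \code{query_end}, \code{strand}, \code{target_name}, \code{target_len},
#'   \code{target_start}, \code{target_end}, \code{residue_matches},
#'   \code{alignment_block_len}, \code{mapq}. Input record order is preserved.
#' @examples
#' paf <- paf_record("c1", 1000, 0, 900, "+", "r1", 5000, 100, 1000, 850, 900, 60)
#' tf <- tempfile(fileext = ".paf")
#' write_paf(paf, tf)
#' read_paf(tf)
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("malformed PAF line ", bad, ": expected >= 12 tab-separated fields, got ",
         nf[bad])
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12L)))
  int_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  ints <- suppressWarnings(
    lapply(int_cols, function(j) as.integer(m[, j]))
  )
  for (k in seq_along(int_cols)) {
    bad <- which(is.na(ints[[k]]))
    if (length(bad)) {
      stop("malformed PAF line ", bad[1L], ": non-integer value '",
           m[bad[1L], int_cols[k]], "' in column ", int_cols[k])
    }
  }
  paf <- data.frame(
    query_name = m[, 1], query_len = ints[[1]],
    query_start = ints[[2]], query_end = ints[[3]],
    strand = m[, 5],
    target_name = m[, 6], target_len = ints[[4]],
    target_start = ints[[5]], target_end = ints[[6]],
    residue_matches = ints[[7]], alignment_block_len = ints[[8]],
    mapq = ints[[9]],
    stringsAsFactors = FALSE
  )
  validate_paf(paf)
  class(paf) <- c("paf", "data.frame")
  paf
}

empty_paf <- function() {
  paf <- data.frame(
    query_name = character(), query_len = integer(),
    query_start = integer(), query_end = integer(), strand = character(),
    target_name = character(), target_len = integer(),
    target_start = integer(), target_end = integer(),
    residue_matches = integer(), alignment_block_len = integer(),
    mapq = integer(), stringsAsFactors = FALSE
  )
  class(paf) <- c("paf", "data.frame")
  paf
}

#' Construct PAF records in memory
#'
#' Convenience constructor used by the synthetic-community generator and in
#' tests; arguments are recycled to a common length.
#'
#' @param query_name,query_len,query_start,query_end,strand Query-side fields.
#' @param target_name,target_len,target_start,target_end Target-side fields.
#' @param residue_matches Number of exact residue matches (column 10).
#' @param alignment_block_len Alignment block length (column 11).
#' @param mapq Mapping quality, 0-255.
#' @return A \code{paf} data frame.
#' @export
paf_record <- function(query_name, query_len, query_start, query_end,
                       strand, target_name, target_len, target_start,
                       target_end, residue_matches, alignment_block_len,
                       mapq = 60L) {
  paf <- data.frame(
    query_name = as.character(query_name), query_len = as.integer(query_len),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    strand = as.character(strand),
    target_name = as.character(target_name),
    target_len = as.integer(target_len),
    target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    residue_matches = as.integer(residue_matches),
    alignment_block_len = as.integer(alignment_block_len),
    mapq = as.integer(mapq),
    stringsAsFactors = FALSE
  )
  validate_paf(paf)
  class(paf) <- c("paf", "data.frame")
  paf
}

validate_paf <- function(paf) {
  if (nrow(paf) == 0L) return(invisible(paf))
  with(paf, {
    bad <- which(!(query_start < query_end & query_end <= query_len &
                   target_start < target_end & target_end <= target_len))
    if (length(bad)) stop("invalid PAF coordinates at record ", bad[1L])
    bad <- which(residue_matches > alignment_block_len)
    if (length(bad)) {
      stop("residue_matches exceeds alignment_block_len at record ", bad[1L])
    }
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop("invalid strand at record ", bad[1L])
  })
  invisible(paf)
}

#' Write PAF records
#'
#' Writes the 12 mandatory columns, tab-separated, one record per line;
#' round-trips byte-for-byte with [read_paf()] on the mandatory columns.
#'
#' @param paf A \code{paf} data frame.
#' @param path Output path.
#' @export
write_paf <- function(paf, path) {
  cols <- c("query_name", "query_len", "query_start", "query_end", "strand",
            "target_name", "target_len", "target_start", "target_end",
            "residue_matches", "alignment_block_len", "mapq")
  m <- vapply(cols, function(cn) as.character(paf[[cn]]), character(nrow(paf)))
  if (nrow(paf) == 1L) m <- matrix(m, nrow = 1L)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a taxonomy map
#'
#' The taxonomy sidecar is a TSV with header columns \code{seq_id},
#' \code{strain_taxid}, \code{species_taxid}, \code{length}: one row per
#' database sequence, linking each reference to its strain- and species-level
#' taxids and its length in bp.
#'
#' @param path Path to the taxonomy TSV.
#' @return A data frame of class \code{taxonomy_map} keyed by unique
#'   \code{seq_id}.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(seq_id = "character"))
  need <- c("seq_id", "strain_taxid", "species_taxid", "length")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("taxonomy file missing column(s): ", paste(missing, collapse = ", "))
  }
  for (cn in c("strain_taxid", "species_taxid", "length")) {
    if (!is.numeric(tab[[cn]]) || any(tab[[cn]] != floor(tab[[cn]]))) {
      stop("taxonomy column '", cn, "' must be integer")
    }
    tab[[cn]] <- as.integer(tab[[cn]])
  }
  taxonomy_map(tab$seq_id, tab$strain_taxid, tab$species_taxid, tab$length)
}

#' Construct a taxonomy map in memory
#'
#' @param seq_id Character vector of unique sequence ids.
#' @param strain_taxid,species_taxid Integer taxids; each strain taxid must
#'   map to exactly one species taxid.
#' @param length Positive sequence lengths in bp.
#' @return A \code{taxonomy_map} data frame.
#' @export
taxonomy_map <- function(seq_id, strain_taxid, species_taxid, length) {
  if (anyDuplicated(seq_id)) {
    stop("duplicate seq_id in taxonomy: ",
         seq_id[duplicated(seq_id)][1L])
  }
  sp_of_strain <- tapply(species_taxid, strain_taxid,
                         function(x) length(unique(x)))
  if (any(sp_of_strain > 1L)) {
    stop("strain_taxid mapping to multiple species_taxid: ",
         names(sp_of_strain)[sp_of_strain > 1L][1L])
  }
  if (any(length <= 0L)) stop("non-positive sequence length in taxonomy")
  tab <- data.frame(seq_id = as.character(seq_id),
                    strain_taxid = as.integer(strain_taxid),
                    species_taxid = as.integer(species_taxid),
                    length = as.integer(length),
                    stringsAsFactors = FALSE)
  class(tab) <- c("taxonomy_map", "data.frame")
  tab
}

#' Write a taxonomy map
#' @param tax A \code{taxonomy_map}.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax)[order(tax$seq_id), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-contig collapsed-strain estimates
#'
#' TSV with header columns \code{contig_id} and \code{n_strains}: the
#' estimated number of strains collapsed into each assembled contig (the
#' count a strain-separation tool such as HairSplitter reports). This count
#' sets the per-contig selection budget during database reduction. Contigs
#' absent from the table are treated downstream as single-strain
#' (estimate 1).
#'
#' @param path Path to the estimates TSV.
#' @return A named integer vector (names = contig ids, values >= 1).
#' @export
read_estimates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(contig_id = "character"))
  need <- c("contig_id", "n_strains")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("estimates file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$contig_id)) {
    stop("duplicate contig_id in estimates: ",
         tab$contig_id[duplicated(tab$contig_id)][1L])
  }
  if (any(tab$n_strains < 1L)) stop("collapsed-strain estimates must be >= 1")
  stats::setNames(as.integer(tab$n_strains), tab$contig_id)
}

#' Write collapsed-strain estimates
#' @param est Named integer vector of estimates.
#' @param path Output path.
#' @export
write_estimates <- function(est, path) {
  tab <- data.frame(contig_id = names(est), n_strains = as.integer(est),
                    stringsAsFactors = FALSE)
  utils::write.table(tab[order(tab$contig_id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ground-truth read labels
#'
#' TSV with header columns \code{read_id}, \code{true_ref_id},
#' \code{badread_label}; labels follow the Badread simulator vocabulary
#' (\code{good}, \code{random}, \code{junk}, \code{chimera}). Reads labelled
#' \code{random} or \code{junk} have no true source and may carry an empty or
#' \code{NA} reference.
#'
#' @param path Path to the truth TSV.
#' @return A data frame of class \code{truth_table}.
#' @export
read_truth <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = c(read_id = "character"))
  need <- c("read_id", "true_ref_id", "badread_label")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("truth file missing column(s): ", paste(missing, collapse = ", "))
  }
  truth_table(tab$read_id, tab$true_ref_id, tab$badread_label)
}

#' Construct a truth table in memory
#' @param read_id Unique read ids.
#' @param true_ref_id True source reference per read (NA for random/junk).
#' @param badread_label One of good, random, junk, chimera per read.
#' @return A \code{truth_table} data frame.
#' @export
truth_table <- function(read_id, true_ref_id, badread_label) {
  if (anyDuplicated(read_id)) {
    stop("duplicate read_id in truth table: ",
         read_id[duplicated(read_id)][1L])
  }
  ok <- badread_label %in% c("good", "random", "junk", "chimera")
  if (!all(ok)) stop("unknown badread_label: ", badread_label[!ok][1L])
  needs_ref <- !badread_label %in% c("random", "junk")
  if (any(needs_ref & is.na(true_ref_id))) {
    stop("read with label '", badread_label[needs_ref & is.na(true_ref_id)][1L],
         "' lacks a true reference")
  }
  tab <- data.frame(read_id = as.character(read_id),
                    true_ref_id = as.character(true_ref_id),
                    badread_label = as.character(badread_label),
                    stringsAsFactors = FALSE)
  class(tab) <- c("truth_table", "data.frame")
  tab
}

#' Write a truth table
#' @param truth A \code{truth_table}.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth)[order(truth$read_id), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a read-classification table
#'
#' Columns, in stable order: \code{read_id}, \code{ref_id},
#' \code{strain_taxid}, \code{species_taxid}, \code{score}, \code{status};
#' rows sorted by \code{read_id} so reruns are byte-identical.
#'
#' @param assignments A \code{read_assignments} data frame
#'   (see [classify_reads()]).
#' @param path Output path.
#' @export
write_classification <- function(assignments, path) {
  cols <- c("read_id", "ref_id", "strain_taxid", "species_taxid",
            "score", "status")
  tab <- as.data.frame(assignments)[, cols]
  tab <- tab[order(tab$read_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a classification table
#' @param path Path written by [write_classification()].
#' @return A \code{read_assignments} data frame.
#' @export
read_classification <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA"),
                           colClasses = c(read_id = "character"))
  tab$ref_id <- as.character(tab$ref_id)
  class(tab) <- c("read_assignments", "data.frame")
  tab
}

#' Write an abundance profile
#'
#' Columns: \code{ref_id}, \code{read_count}, \code{relative_count},
#' \code{length_normalized}; rows sorted by \code{ref_id}.
#'
#' @param profile An \code{abundance_profile} data frame.
#' @param path Output path.
#' @export
write_abundance <- function(profile, path) {
  cols <- c("ref_id", "read_count", "relative_count", "length_normalized")
  tab <- as.data.frame(profile)
  for (cn in setdiff(cols, names(tab))) tab[[cn]] <- NA_real_
  tab <- tab[, cols]
  tab <- tab[order(tab$ref_id), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an abundance profile
#' @param path Path written by [write_abundance()].
#' @return An \code{abundance_profile} data frame.
#' @export
read_abundance <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(ref_id = "character"))
  class(tab) <- c("abundance_profile", "data.frame")
  tab
}
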
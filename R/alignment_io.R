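#' Grouped segment alignments
#'
#' A `grouped_alignment` bundles one aligned chromosome segment (one sequence
#' per strain, equal lengths, residues `A/C/G/T/-/N`) with the phylogroup
#' label of every strain, an optional outgroup strain, and the identifier of
#' the strain panel the segment belongs to. It is the unit of input for
#' conversion detection, event enumeration and tree building.
#'
#' @param sequences Named character vector; one upper-case residue string per
#'   strain, all of identical length.
#' @param groups Named character vector mapping every strain id in
#'   `sequences` to its group label (e.g. `"A"`, `"B1"`).
#' @param segment_id Identifier of the chromosome segment.
#' @param outgroup Optional strain id used only for tree rooting; excluded
#'   from polymorphism calling and pair scanning.
#' @param panel_id Identifier of the strain panel this segment was sequenced
#'   in (segments sharing a panel share pairing opportunities).
#' @return An object of class `grouped_alignment`: a list with elements
#'   `segment_id`, `sequences`, `groups`, `outgroup`, `panel_id`.
#' @export
grouped_alignment <- function(sequences, groups, segment_id,
                              outgroup = NULL, panel_id = "panel1") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by strain id")
  sequences <- vapply(sequences, toupper, character(1))
  lens <- nchar(sequences)
  if (any(lens < 1L)) stop("alignment length must be >= 1")
  if (length(unique(lens)) != 1L) {
    tab <- table(lens)
    # majority length wins; ties go to the longer, naming the shorter strain
    ref <- as.integer(names(tab)[order(-tab, -as.integer(names(tab)))][1])
    bad <- names(sequences)[lens != ref]
    stop("sequence length mismatch for strain(s): ", paste(bad, collapse = ", "))
  }
  bad_res <- regexpr("[^ACGTN-]", sequences)
  if (any(bad_res > 0L)) {
    i <- which(bad_res > 0L)[1]
    stop(sprintf("unknown residue '%s' in strain %s at column %d",
                 substr(sequences[i], bad_res[i], bad_res[i]),
                 names(sequences)[i], bad_res[i]))
  }
  missing_group <- setdiff(names(sequences), names(groups))
  if (length(missing_group))
    stop("no group label for strain(s): ", paste(missing_group, collapse = ", "))
  groups <- groups[names(sequences)]
  if (any(is.na(groups) | !nzchar(groups))) stop("group labels must be nonempty")
  if (!is.null(outgroup) && !outgroup %in% names(sequences))
    stop("outgroup '", outgroup, "' is not a strain in the alignment")
  structure(
    list(segment_id = as.character(segment_id),
         sequences = sequences,
         groups = setNames(as.character(groups), names(sequences)),
         outgroup = outgroup,
         panel_id = as.character(panel_id)),
    class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  grp <- table(x$groups[setdiff(names(x$sequences), x$outgroup)])
  cat(sprintf("grouped_alignment '%s' (panel %s): %d strains x %d columns\n",
              x$segment_id, x$panel_id, length(x$sequences),
              nchar(x$sequences[[1]])))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      if (!is.null(x$outgroup)) sprintf("| outgroup: %s", x$outgroup) else "", "\n")
  invisible(x)
}

#' Alignment length of a grouped alignment
#' @param aln A [grouped_alignment()].
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(aln) nchar(aln$sequences[[1]])

#' Strain ids of the ingroup (everything but the outgroup)
#' @param aln A [grouped_alignment()].
#' @return Character vector of strain ids.
#' @export
ingroup_strains <- function(aln) setdiff(names(aln$sequences), aln$outgroup)

# residues as a strains x columns character matrix
aln_matrix <- function(aln, strains = names(aln$sequences)) {
  m <- do.call(rbind, strsplit(aln$sequences[strains], "", fixed = TRUE))
  rownames(m) <- strains
  m
}

#' Read a strain metadata table
#'
#' Tab-separated with header columns `strain_id`, `group`, `panel_id`,
#' `is_outgroup` (logical or 0/1). Strain ids must be unique, group labels
#' nonempty, and each panel may declare at most one outgroup.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four columns, `is_outgroup` as logical.
#' @export
read_strain_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("strain_id", "group", "panel_id", "is_outgroup")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md <- md[, need]
  if (anyDuplicated(md$strain_id)) stop("duplicate strain_id in metadata")
  if (any(!nzchar(md$group))) stop("empty group label in metadata")
  md$is_outgroup <- md$is_outgroup %in% c("TRUE", "true", "1")
  n_out <- tapply(md$is_outgroup, md$panel_id, sum)
  if (any(n_out > 1L))
    stop("more than one outgroup declared for panel(s): ",
         paste(names(n_out)[n_out > 1L], collapse = ", "))
  md
}

#' Write a strain metadata table
#' @param md Metadata data.frame as returned by [read_strain_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_strain_metadata <- function(md, path) {
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a grouped segment alignment from FASTA plus metadata
#'
#' Reads an aligned multi-FASTA (one record per strain) and attaches group
#' labels from a metadata table. Record ids are the first whitespace-separated
#' token of each FASTA header. Strains present in the metadata but absent from
#' the FASTA are reported and dropped; strains present in the FASTA but not in
#' the metadata are an error, as are unequal lengths or unknown residues.
#'
#' @param fasta_path Path to the aligned multi-FASTA file.
#' @param metadata Either a path to a metadata TSV (see
#'   [read_strain_metadata()]) or an already-read metadata data.frame.
#' @param segment_id Segment identifier to record on the alignment.
#' @return A [grouped_alignment()].
#' @examples
#' # a small synthetic segment bundled with the package
#' fa <- system.file("extdata", "example_segment.fasta",
#'                   package = "phylorecomb")
#' md <- system.file("extdata", "example_metadata.tsv",
#'                   package = "phylorecomb")
#' read_grouped_alignment(fa, md, segment_id = "seg1")
#' @export
read_grouped_alignment <- function(fasta_path, metadata, segment_id) {
  md <- if (is.character(metadata)) read_strain_metadata(metadata) else metadata
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", fasta_path)
  x <- setNames(toupper(as.character(seqs)), ids)
  unknown <- setdiff(ids, md$strain_id)
  if (length(unknown))
    stop("strain(s) in FASTA but not in metadata: ",
         paste(unknown, collapse = ", "))
  dropped <- setdiff(md$strain_id, ids)
  if (length(dropped))
    message("dropping strain(s) absent from FASTA: ",
            paste(dropped, collapse = ", "))
  md <- md[md$strain_id %in% ids, , drop = FALSE]
  panel <- unique(md$panel_id)
  if (length(panel) != 1L)
    stop("strains in one segment must belong to a single panel; found: ",
         paste(panel, collapse = ", "))
  outg <- md$strain_id[md$is_outgroup]
  grouped_alignment(x[md$strain_id],
                    setNames(md$group, md$strain_id),
                    segment_id = segment_id,
                    outgroup = if (length(outg)) outg else NULL,
                    panel_id = panel)
}

#' Write a grouped alignment as multi-FASTA
#' @param aln A [grouped_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_grouped_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$sequences), path)
  invisible(path)
}

#' Mask converted regions out of an alignment
#'
#' Replaces the residues of both strains of each detected fragment over the
#' fragment's interval with the alignment gap `-`, so that complete-deletion
#' tree building downstream excludes the converted signal. Coordinates are
#' 0-based half-open alignment columns. The input alignment is not modified.
#'
#' @param aln A [grouped_alignment()].
#' @param fragments A `conversion_fragments` data.frame (see
#'   [detect_fragments()]); only `strain1`, `strain2`, `start`, `end`,
#'   `segment_id` are used. May have zero rows.
#' @return A new [grouped_alignment()] with masked residues.
#' @export
mask_fragments <- function(aln, fragments) {
  stopifnot(inherits(aln, "grouped_alignment"))
  if (NROW(fragments) == 0L) return(aln)
  L <- alignment_length(aln)
  if (any(fragments$segment_id != aln$segment_id))
    stop("fragment segment_id does not match alignment '", aln$segment_id, "'")
  if (any(fragments$start < 0L) || any(fragments$end > L) ||
      any(fragments$start >= fragments$end))
    stop("fragment coordinates out of range [0, ", L, ")")
  chars <- strsplit(aln$sequences, "", fixed = TRUE)
  for (i in seq_len(nrow(fragments))) {
    cols <- (fragments$start[i] + 1L):fragments$end[i]  # to 1-based
    for (s in c(fragments$strain1[i], fragments$strain2[i])) {
      if (!s %in% names(chars)) stop("fragment strain '", s, "' not in alignment")
      chars[[s]][cols] <- "-"
    }
  }
  out <- aln
  out$sequences <- vapply(chars, paste, character(1), collapse = "")
  out
}
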
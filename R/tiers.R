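#' Three-tier enumeration of conversion events
#'
#' Detected fragments are tallied at three increasingly stringent tiers:
#' tier 1 counts every fragment as an independent event; tier 2 merges
#' duplicates, i.e. fragments within the same segment and group-pair category
#' whose alignment borders `(start, end)` are identical (the signature of a
#' single ancestral transfer inherited by several descendant strains); tier 3
#' counts at most one event per segment and category, since most fragments in
#' a cell overlap. Intra-group fragments are tiered by the same rules.
#'
#' @param fragments A `conversion_fragments` data.frame (possibly from
#'   several segments, e.g. `rbind` of per-segment results).
#' @return An object of class `tier_events`: list with `tier`, `counts`
#'   (data.frame `segment_id`, `category`, `count`, sorted), and `provenance`
#'   (named list mapping each event id to the row indices of its contributing
#'   fragments).
#' @name tier_events
NULL

new_tier_events <- function(tier, counts, provenance) {
  counts <- counts[order(counts$segment_id, counts$category), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(tier = tier, counts = counts, provenance = provenance),
            class = "tier_events")
}

tally_by_key <- function(fragments, key, tier) {
  if (NROW(fragments) == 0L) {
    return(new_tier_events(tier,
      data.frame(segment_id = character(), category = character(),
                 count = integer(), stringsAsFactors = FALSE),
      list()))
  }
  prov <- split(seq_len(nrow(fragments)), key)
  cell <- vapply(prov, function(i)
    paste(fragments$segment_id[i[1]], fragments$category[i[1]], sep = "\r"),
    character(1))
  counts <- as.data.frame(table(cell), stringsAsFactors = FALSE)
  parts <- strsplit(counts$cell, "\r", fixed = TRUE)
  counts <- data.frame(
    segment_id = vapply(parts, `[`, character(1), 1L),
    category = vapply(parts, `[`, character(1), 2L),
    count = as.integer(counts$Freq),
    stringsAsFactors = FALSE)
  names(prov) <- paste0("t", tier, "_", names(prov))
  new_tier_events(tier, counts, prov)
}

#' @describeIn tier_events every fragment is one event.
#' @export
tier1_events <- function(fragments) {
  key <- if (NROW(fragments)) paste(fragments$segment_id, fragments$category,
                                    seq_len(nrow(fragments)), sep = "|")
         else character()
  tally_by_key(fragments, key, 1L)
}

#' @describeIn tier_events fragments with identical `(start, end)` borders
#'   within a segment and category collapse to one event.
#' @export
tier2_events <- function(fragments) {
  key <- if (NROW(fragments)) paste(fragments$segment_id, fragments$category,
                                    fragments$start, fragments$end, sep = "|")
         else character()
  tally_by_key(fragments, key, 2L)
}

#' @describeIn tier_events at most one event per `(segment, category)` cell.
#' @export
tier3_events <- function(fragments) {
  key <- if (NROW(fragments)) paste(fragments$segment_id, fragments$category,
                                    sep = "|")
         else character()
  ev <- tally_by_key(fragments, key, 3L)
  # tally_by_key counted fragments per cell; tier 3 counts cells
  ev$counts$count <- pmin(ev$counts$count, 1L)
  ev
}

#' @export
print.tier_events <- function(x, ...) {
  cat(sprintf("tier %d events: %d event(s) in %d cell(s)\n",
              x$tier, sum(x$counts$count), nrow(x$counts)))
  if (nrow(x$counts)) print.data.frame(x$counts, ...)
  invisible(x)
}

#' Total event count of a tier enumeration
#' @param events A `tier_events` object.
#' @param which `"all"`, `"inter"` or `"intra"` categories.
#' @return Integer total.
#' @export
total_events <- function(events, which = c("all", "inter", "intra")) {
  which <- match.arg(which)
  cnt <- events$counts
  if (which != "all")
    cnt <- cnt[startsWith(cnt$category, paste0(which, ":")), , drop = FALSE]
  sum(cnt$count)
}

#' Write tier counts as TSV and provenance as JSON
#' @param events A `tier_events` object.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_tier_events <- function(events, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(events$counts, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(events$provenance, json_path, auto_unbox = FALSE,
                         pretty = TRUE)
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Strain-pairing opportunity table
#'
#' The null-model weights for the exchange tests: for every panel, the number
#' of intra-group pairs per group (`choose(n_g, 2)`) and inter-group pairs
#' per unordered group pair (`n_g1 * n_g2`). Expected conversion counts for a
#' category are proportional to its pair count within each segment's panel.
#'
#' @param panels Named list; one named integer vector of group sizes per
#'   panel, e.g. `list(p1 = c(A = 5, B1 = 6))`.
#' @param segments Named character vector mapping each segment id to its
#'   panel id.
#' @param inter_totals Optional named numeric vector overriding, per panel,
#'   the denominator used for inter-group weights (by default the panel's
#'   total inter-group pair count). Needed only to reproduce reported
#'   statistics whose panel totals are given rather than derived.
#' @return Object of class `opportunity_table`.
#' @export
opportunity_table <- function(panels, segments, inter_totals = NULL) {
  stopifnot(length(panels) >= 1L, all(segments %in% names(panels)))
  pan <- lapply(panels, function(sz) {
    stopifnot(all(sz >= 0), length(sz) >= 1L, !is.null(names(sz)))
    sz <- sz[order(names(sz))]
    intra <- setNames(choose(sz, 2), paste0("intra:", names(sz)))
    inter <- numeric(0)
    if (length(sz) >= 2L) {
      cmb <- combn(names(sz), 2L)
      inter <- setNames(sz[cmb[1L, ]] * sz[cmb[2L, ]],
                        paste0("inter:", cmb[1L, ], "|", cmb[2L, ]))
    }
    list(sizes = sz, intra = intra, inter = inter,
         n_intra = sum(intra), n_inter = sum(inter))
  })
  if (!is.null(inter_totals)) {
    stopifnot(all(names(inter_totals) %in% names(pan)))
    for (p in names(inter_totals)) pan[[p]]$inter_denominator <- inter_totals[[p]]
  }
  for (p in names(pan))
    if (is.null(pan[[p]]$inter_denominator))
      pan[[p]]$inter_denominator <- pan[[p]]$n_inter
  structure(list(panels = pan, segments = segments),
            class = "opportunity_table")
}

#' Build an opportunity table from grouped alignments
#' @param alignments List of [grouped_alignment()]s (one per segment).
#' @return An [opportunity_table()] whose panels are the distinct
#'   `panel_id`s, group sizes counted over ingroup strains.
#' @export
opportunities_from_alignments <- function(alignments) {
  seg <- vapply(alignments, function(a) a$segment_id, character(1))
  panel <- vapply(alignments, function(a) a$panel_id, character(1))
  panels <- list()
  for (a in alignments) {
    ing <- ingroup_strains(a)
    sizes <- table(a$groups[ing])
    sizes <- setNames(as.integer(sizes), names(sizes))
    if (!is.null(panels[[a$panel_id]])) {
      if (!identical(panels[[a$panel_id]], sizes))
        stop("segments of panel '", a$panel_id,
             "' disagree on group sizes")
    } else panels[[a$panel_id]] <- sizes
  }
  opportunity_table(panels, setNames(panel, seg))
}

#' @export
print.opportunity_table <- function(x, ...) {
  for (p in names(x$panels)) {
    pp <- x$panels[[p]]
    cat(sprintf("panel %s: %s | intra pairs %d, inter pairs %d\n", p,
                paste(sprintf("%s=%d", names(pp$sizes), pp$sizes),
                      collapse = ", "),
                as.integer(pp$n_intra), as.integer(pp$n_inter)))
  }
  cat("segments:", paste(sprintf("%s->%s", names(x$segments), x$segments),
                         collapse = ", "), "\n")
  invisible(x)
}
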
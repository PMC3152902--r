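#' Configuration for the synthetic panel generator
#'
#' The generator emulates the study design the pipeline targets: several
#' ~23 kb backbone segments sequenced in a panel of strains from a handful of
#' phylogroups, plus a deeper outgroup. Each segment evolves on a star
#' phylogeny: one random ancestral sequence, one founder per group mutated at
#' `inter_group_divergence` per site, strains mutated from their founder at
#' `intra_group_divergence` per site, and an outgroup at `outgroup_factor`
#' times the founder divergence. Conversion tracts are planted by copying the
#' donor-side sequence over a tract into the recipient, either into the
#' recipient-group founder before strains are derived (`"ancestral"` timing:
#' every descendant inherits identical tract borders, the duplicate
#' mechanism) or into named strains afterwards (`"terminal"`).
#'
#' @param groups Named integer vector of ingroup strain counts per group.
#' @param n_segments Number of segments to simulate.
#' @param segment_length Alignment columns per segment.
#' @param inter_group_divergence Per-site substitution probability on each
#'   group-founder branch.
#' @param intra_group_divergence Per-site substitution probability on each
#'   strain branch.
#' @param ts_tv_ratio Ratio of transition to transversion events among
#'   substitutions (K2P-compatible; 2 means two transitions per
#'   transversion).
#' @param planted_events List of [planted_event()]s.
#' @param outgroup_factor Outgroup branch divergence as a multiple of
#'   `inter_group_divergence`.
#' @param panel_id Panel identifier recorded on every segment.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(groups = c(A = 4L, B1 = 4L, B2 = 4L,
                                        D = 4L, E = 4L),
                             n_segments = 4L, segment_length = 23000L,
                             inter_group_divergence = 0.02,
                             intra_group_divergence = 0.002,
                             ts_tv_ratio = 2, planted_events = list(),
                             outgroup_factor = 3, panel_id = "panel1") {
  stopifnot(length(groups) >= 1L, all(groups >= 1L), !is.null(names(groups)),
            n_segments >= 1L, segment_length >= 1L,
            inter_group_divergence >= 0, inter_group_divergence < 1,
            intra_group_divergence >= 0, intra_group_divergence < 1,
            ts_tv_ratio > 0, outgroup_factor >= 0)
  for (ev in planted_events) {
    stopifnot(inherits(ev, "planted_event"))
    if (ev$segment < 1L || ev$segment > n_segments)
      stop("planted event targets segment ", ev$segment,
           " outside 1..", n_segments)
    if (ev$start < 0L || ev$end > segment_length || ev$start >= ev$end)
      stop("planted tract [", ev$start, ", ", ev$end,
           ") outside the segment")
    if (!ev$donor %in% names(groups) || !ev$recipient %in% names(groups))
      stop("planted event groups must be generator groups")
  }
  structure(list(groups = groups, n_segments = as.integer(n_segments),
                 segment_length = as.integer(segment_length),
                 inter_group_divergence = inter_group_divergence,
                 intra_group_divergence = intra_group_divergence,
                 ts_tv_ratio = ts_tv_ratio,
                 planted_events = planted_events,
                 outgroup_factor = outgroup_factor,
                 panel_id = panel_id),
            class = "generator_config")
}

#' A conversion tract to plant into a synthetic panel
#'
#' @param segment Segment index (1-based) the tract is planted in.
#' @param donor,recipient Group labels; must differ for a between-group
#'   tract.
#' @param start,end Tract interval, 0-based half-open alignment columns.
#' @param timing `"ancestral"` (copied into the recipient founder before
#'   strain derivation) or `"terminal"` (copied into named strains after).
#' @param recipients For terminal events, strain indices within the
#'   recipient group receiving the tract (default: strain 1).
#' @return Object of class `planted_event`.
#' @export
planted_event <- function(segment, donor, recipient, start, end,
                          timing = c("ancestral", "terminal"),
                          recipients = 1L) {
  timing <- match.arg(timing)
  if (donor == recipient) stop("donor and recipient group must differ")
  structure(list(segment = as.integer(segment), donor = donor,
                 recipient = recipient, start = as.integer(start),
                 end = as.integer(end), timing = timing,
                 recipients = as.integer(recipients)),
            class = "planted_event")
}

BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# per-site independent substitution with transition bias
mutate_seq <- function(x, p, kappa) {
  if (p <= 0) return(x)
  hit <- which(runif(length(x)) < p)
  if (!length(hit)) return(x)
  is_ts <- runif(length(hit)) < kappa / (kappa + 1)
  ts_i <- hit[is_ts]
  x[ts_i] <- TRANSITION[x[ts_i]]
  tv_i <- hit[!is_ts]
  if (length(tv_i)) {
    pick <- runif(length(tv_i)) < 0.5
    x[tv_i] <- vapply(seq_along(tv_i), function(k)
      TRANSVERSIONS[[x[tv_i[k]]]][if (pick[k]) 1L else 2L], character(1))
  }
  x
}

#' Generate a synthetic strain panel with planted conversions
#'
#' @param config A [generator_config()].
#' @param seed Optional RNG seed; the same seed reproduces the panel
#'   byte-for-byte.
#' @return List with `alignments` (named list of [grouped_alignment()]s,
#'   segment ids `seg1`, `seg2`, ...) and `truth` (class `synthetic_truth`):
#'   planted events with realized borders, donor strain, carrier strains and
#'   category, plus per-segment polymorphic column indices.
#' @export
generate_panel <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$segment_length
  kappa <- config$ts_tv_ratio
  strain_ids <- unlist(lapply(names(config$groups), function(g)
    paste0(g, "_", seq_len(config$groups[[g]]))))
  groups <- setNames(rep(names(config$groups), config$groups), strain_ids)
  out_id <- "OUTGROUP"
  alignments <- list()
  events <- list()
  poly_cols <- list()
  for (s in seq_len(config$n_segments)) {
    seg_id <- paste0("seg", s)
    anc <- sample(BASES, L, replace = TRUE)
    founders <- lapply(config$groups, function(n)
      mutate_seq(anc, config$inter_group_divergence, kappa))
    names(founders) <- names(config$groups)
    seg_events <- Filter(function(e) e$segment == s, config$planted_events)
    for (ev in seg_events) {
      if (ev$timing == "ancestral") {
        idx <- (ev$start + 1L):ev$end
        founders[[ev$recipient]][idx] <- founders[[ev$donor]][idx]
      }
    }
    seqs <- list()
    for (g in names(config$groups))
      for (i in seq_len(config$groups[[g]]))
        seqs[[paste0(g, "_", i)]] <-
          mutate_seq(founders[[g]], config$intra_group_divergence, kappa)
    for (ev in seg_events) {
      if (ev$timing == "terminal") {
        idx <- (ev$start + 1L):ev$end
        donor_strain <- paste0(ev$donor, "_1")
        for (r in ev$recipients) {
          rec <- paste0(ev$recipient, "_", r)
          if (!rec %in% names(seqs))
            stop("terminal event recipient ", rec, " does not exist")
          seqs[[rec]][idx] <- seqs[[donor_strain]][idx]
        }
      }
    }
    seqs[[out_id]] <- mutate_seq(
      anc, min(config$outgroup_factor * config$inter_group_divergence, 0.95),
      kappa)
    aln <- grouped_alignment(
      vapply(seqs, paste, character(1), collapse = ""),
      c(groups, setNames("O", out_id)),
      segment_id = seg_id, outgroup = out_id, panel_id = config$panel_id)
    alignments[[seg_id]] <- aln
    poly_cols[[seg_id]] <- project_polymorphic(aln)$site_columns
    for (ev in seg_events) {
      carriers <- if (ev$timing == "ancestral")
        paste0(ev$recipient, "_", seq_len(config$groups[[ev$recipient]]))
      else paste0(ev$recipient, "_", ev$recipients)
      events[[length(events) + 1L]] <- list(
        segment_id = seg_id, donor = ev$donor, recipient = ev$recipient,
        start = ev$start, end = ev$end, timing = ev$timing,
        donor_strain = paste0(ev$donor, "_1"), carriers = carriers,
        category = pair_category(ev$donor, ev$recipient))
    }
  }
  truth <- structure(list(events = events, poly_columns = poly_cols,
                          groups = groups, config = config),
                     class = "synthetic_truth")
  list(alignments = alignments, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d planted event(s), %d segment(s)\n",
              length(x$events), length(x$poly_columns)))
  invisible(x)
}

#' Oracle fragments from planted truth
#'
#' Converts the planted events of a synthetic panel into the fragment rows a
#' perfect detector would report (`p_global = 0`; score = polymorphic sites
#' spanned): one fragment per donor-strain/carrier pair, with the planted
#' borders. These exercise the tier enumeration and exchange tests
#' independently of the detector.
#'
#' @param truth A `synthetic_truth` from [generate_panel()].
#' @return A `conversion_fragments` data.frame.
#' @export
truth_to_fragments <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(truth$events)) return(empty_fragments())
  rows <- lapply(truth$events, function(ev) {
    pc <- truth$poly_columns[[ev$segment_id]]
    ps <- sum(pc < ev$start)
    pe <- sum(pc < ev$end)
    do.call(rbind, lapply(ev$carriers, function(carrier) {
      pair <- sort(c(ev$donor_strain, carrier))
      data.frame(segment_id = ev$segment_id, strain1 = pair[1],
                 strain2 = pair[2], start = ev$start, end = ev$end,
                 psite_start = ps, psite_end = pe,
                 score = pe - ps, p_global = 0,
                 category = ev$category, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conversion_fragments", "data.frame")
  out
}
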
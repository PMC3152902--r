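#' Project an alignment onto its polymorphic sites
#'
#' Conversion detection operates on polymorphic columns only: columns with at
#' least two distinct unambiguous residues (`A/C/G/T`; gaps and `N` do not
#' count as states) among the ingroup strains. The outgroup is excluded from
#' the polymorphism call.
#'
#' @param aln A [grouped_alignment()] with at least two ingroup strains.
#' @return An object of class `polymorphic_projection`: list with
#'   `segment_id`, `site_columns` (0-based alignment column indices, strictly
#'   increasing), and `site_matrix` (sites x ingroup-strains character
#'   matrix).
#' @export
project_polymorphic <- function(aln) {
  stopifnot(inherits(aln, "grouped_alignment"))
  ing <- ingroup_strains(aln)
  if (length(ing) < 2L) stop("need at least two ingroup strains")
  m <- aln_matrix(aln, ing)  # strains x columns
  n_states <- colSums(m == "A") > 0
  n_states <- n_states + (colSums(m == "C") > 0) + (colSums(m == "G") > 0) +
    (colSums(m == "T") > 0)
  keep <- which(n_states >= 2L)
  structure(
    list(segment_id = aln$segment_id,
         site_columns = keep - 1L,  # 0-based
         site_matrix = t(m[, keep, drop = FALSE])),
    class = "polymorphic_projection")
}

#' @export
print.polymorphic_projection <- function(x, ...) {
  cat(sprintf("polymorphic_projection '%s': %d sites x %d strains\n",
              x$segment_id, length(x$site_columns), ncol(x$site_matrix)))
  invisible(x)
}

#' Match/mismatch profile of a strain pair over polymorphic sites
#'
#' Sites where either strain carries a gap or `N` are skipped (removed from
#' the profile); the returned index maps lead back to the projection and to
#' alignment columns.
#'
#' @param proj A [project_polymorphic()] result.
#' @param s_i,s_j Strain ids present in the projection.
#' @return List with `match` (logical vector over retained sites), `psite`
#'   (0-based indices of retained sites in the projection), and `columns`
#'   (0-based alignment columns of retained sites).
#' @export
pair_profile <- function(proj, s_i, s_j) {
  sm <- proj$site_matrix
  if (!all(c(s_i, s_j) %in% colnames(sm)))
    stop("unknown strain in pair: ",
         paste(setdiff(c(s_i, s_j), colnames(sm)), collapse = ", "))
  a <- sm[, s_i]
  b <- sm[, s_j]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  idx <- which(ok)
  list(match = a[idx] == b[idx],
       psite = idx - 1L,
       columns = proj$site_columns[idx])
}

# per-mismatch penalty; g = 0 or no mismatches => mismatches terminate runs
mismatch_penalty <- function(k, m, g) {
  if (m == 0L || g == 0) return(k + 1L)  # effectively infinite
  as.integer(ceiling(g * k / m))
}

#' Maximal scoring fragments of a pair profile
#'
#' Scores +1 per matching site and `-B` per mismatching site with
#' `B = ceiling(g * matches / mismatches)` (mismatches terminate runs when
#' `g = 0` or the profile has no mismatch), then extracts all maximal
#' positive-scoring segments in the Ruzzo-Tompa sense: disjoint, none
#' extendable or subdividable to a higher score.
#'
#' @param profile A [pair_profile()] result, or a logical match vector.
#' @param g Mismatch-penalty scale (the detector's `gscale`); non-negative.
#' @return Data.frame with `psite_start`, `psite_end` (0-based half-open
#'   interval in the unskipped-profile index space) and integer `score`.
#' @export
max_scoring_fragments <- function(profile, g = 1) {
  match <- if (is.list(profile)) profile$match else profile
  stopifnot(is.logical(match), g >= 0)
  if (length(match) == 0L)
    return(data.frame(psite_start = integer(), psite_end = integer(),
                      score = integer()))
  k <- sum(match)
  m <- sum(!match)
  B <- mismatch_penalty(k, m, g)
  vals <- ifelse(match, 1L, -B)
  seg <- cpp_maximal_segments(as.numeric(vals))
  data.frame(psite_start = unname(seg[, "start"]),
             psite_end = unname(seg[, "end"]),
             score = unname(seg[, "score"]), row.names = NULL)
}

#' Detector configuration
#'
#' @param gscale Mismatch-penalty scale `g`; `g = 0` forbids mismatches
#'   inside fragments. Default 1, the study setting for bacterial backbone
#'   panels.
#' @param n_permutations Column-permutation replicates for significance.
#' @param alpha Family-wise significance level for reported fragments.
#' @param seed Optional RNG seed set before the permutation draw.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(gscale = 1, n_permutations = 10000,
                            alpha = 0.05, seed = NULL) {
  stopifnot(gscale >= 0, n_permutations >= 1, alpha > 0, alpha < 1)
  structure(list(gscale = gscale,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = seed),
            class = "detector_config")
}

pair_category <- function(g1, g2) {
  ifelse(g1 == g2, paste0("intra:", g1),
         paste0("inter:", pmin(g1, g2), "|", pmax(g1, g2)))
}

empty_fragments <- function() {
  structure(
    data.frame(segment_id = character(), strain1 = character(),
               strain2 = character(), start = integer(), end = integer(),
               psite_start = integer(), psite_end = integer(),
               score = integer(), p_global = numeric(),
               category = character(), stringsAsFactors = FALSE),
    class = c("conversion_fragments", "data.frame"))
}

#' Detect candidate gene-conversion fragments in a segment
#'
#' For every unordered pair of ingroup strains, finds maximal runs of
#' agreement at polymorphic sites ([max_scoring_fragments()]) and assesses
#' their significance against a shared column-permutation null: in each
#' replicate the order of polymorphic columns is shuffled once for the whole
#' site matrix (preserving within-column residues and hence the site
#' frequency spectrum) and each pair's maximum run score is recorded.
#'
#' Because the per-pair mismatch penalty adapts to the pair's own divergence,
#' raw run scores are not comparable across pairs of very different
#' divergence; the family-wise (all pairs) correction therefore uses the
#' studentized maximum (single-step max-T): every pair's null maxima are
#' centred and scaled by that pair's own permutation mean and standard
#' deviation, and a fragment's `p_global = (1 + ` number of replicates whose
#' largest studentized per-pair maximum is `>=` the fragment's studentized
#' score`) / (n_permutations + 1)`. This controls the family-wise error rate
#' over all strain pairs while retaining power for divergent pairs.
#'
#' @param aln A [grouped_alignment()] with >= 2 ingroup strains.
#' @param config A [detector_config()].
#' @return A `conversion_fragments` data.frame (0-based half-open alignment
#'   coordinates) with one row per fragment significant at `config$alpha`:
#'   columns `segment_id`, `strain1`, `strain2`, `start`, `end`,
#'   `psite_start`, `psite_end` (projection index space), `score`,
#'   `p_global`, `category`. Attribute `n_candidates` records the number of
#'   maximal fragments assessed and attribute `candidates` their full table
#'   (pair, projection interval, score, `p_global`) before the alpha gate.
#' @export
detect_fragments <- function(aln, config = detector_config()) {
  stopifnot(inherits(aln, "grouped_alignment"),
            inherits(config, "detector_config"))
  proj <- project_polymorphic(aln)
  S <- length(proj$site_columns)
  if (S == 0L) {
    message("segment '", aln$segment_id, "': no polymorphic sites; ",
            "nothing to detect")
    return(empty_fragments())
  }
  strains <- sort(ingroup_strains(aln))
  prs <- combn(strains, 2L)
  P <- ncol(prs)
  R <- config$n_permutations

  base <- c("A", "C", "G", "T")
  okmat <- matrix(proj$site_matrix %in% base, nrow = S,
                  dimnames = dimnames(proj$site_matrix))

  values <- matrix(NA_integer_, nrow = S, ncol = P)
  cand <- vector("list", P)
  for (p in seq_len(P)) {
    s1 <- prs[1L, p]; s2 <- prs[2L, p]
    ok <- okmat[, s1] & okmat[, s2]
    idx <- which(ok)
    eq <- proj$site_matrix[idx, s1] == proj$site_matrix[idx, s2]
    k <- sum(eq); m <- length(eq) - k
    B <- mismatch_penalty(k, m, config$gscale)
    v <- ifelse(eq, 1L, -B)
    values[idx, p] <- v
    if (k > 0L) {
      seg <- cpp_maximal_segments(as.numeric(v))
      if (nrow(seg)) {
        cand[[p]] <- data.frame(
          pair = p,
          site_first = unname(idx[seg[, "start"] + 1L]),  # 1-based proj index
          site_last  = unname(idx[seg[, "end"]]),
          score = unname(seg[, "score"]), row.names = NULL)
      }
    }
  }
  cand <- do.call(rbind, cand)

  if (!is.null(config$seed)) set.seed(config$seed)
  M <- cpp_perm_pair_max(values, R)  # R x P null max scores

  out <- empty_fragments()
  if (!is.null(cand) && nrow(cand)) {
    mu <- colMeans(M)
    sdv <- apply(M, 2L, stats::sd)
    sdv[!is.finite(sdv)] <- 0
    sdv <- pmax(sdv, 1e-8)
    z_null_max <- apply((M - rep(mu, each = R)) / rep(sdv, each = R), 1L, max)
    z_frag <- (cand$score - mu[cand$pair]) / sdv[cand$pair]
    p_global <- vapply(z_frag, function(z) {
      (1 + sum(z_null_max >= z)) / (R + 1)
    }, numeric(1))

    keep <- which(p_global <= config$alpha)
    if (length(keep)) {
      ki <- cand[keep, , drop = FALSE]
      s1 <- prs[1L, ki$pair]; s2 <- prs[2L, ki$pair]
      g1 <- aln$groups[s1]; g2 <- aln$groups[s2]
      out <- structure(
        data.frame(segment_id = aln$segment_id,
                   strain1 = s1, strain2 = s2,
                   start = proj$site_columns[ki$site_first],
                   end = proj$site_columns[ki$site_last] + 1L,
                   psite_start = ki$site_first - 1L,
                   psite_end = ki$site_last,
                   score = ki$score,
                   p_global = p_global[keep],
                   category = pair_category(g1, g2),
                   stringsAsFactors = FALSE, row.names = NULL),
        class = c("conversion_fragments", "data.frame"))
      out <- out[order(out$strain1, out$strain2, out$start), , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("conversion_fragments", "data.frame")
    }
  }
  attr(out, "n_candidates") <- if (is.null(cand)) 0L else nrow(cand)
  if (!is.null(cand) && nrow(cand)) {
    attr(out, "candidates") <- data.frame(
      strain1 = prs[1L, cand$pair], strain2 = prs[2L, cand$pair],
      site_first = cand$site_first, site_last = cand$site_last,
      score = cand$score, p_global = p_global,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(out, "config") <- config
  out
}

#' @export
print.conversion_fragments <- function(x, ...) {
  cat(sprintf("conversion_fragments: %d significant fragment(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Write fragments as a BED-like TSV (0-based half-open)
#' @param fragments A `conversion_fragments` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  write.table(as.data.frame(fragments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
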
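#' Expected inter-group conversion counts under proportional opportunity
#'
#' Under the null, every inter-group strain pairing of a panel is equally
#' likely to be involved in a conversion, so the expected count for a group
#' pair `c` is `E_c = sum_s T_s * n_c(s) / D_s`, where `T_s` is the observed
#' inter-group event total of segment `s`, `n_c(s)` the number of strain
#' pairings in category `c` within `s`'s panel, and `D_s` the panel's total
#' inter-group pairings (overridable, see [opportunity_table()]). Expected
#' and observed counts are summed over segments for each pair of groups.
#'
#' @param events A `tier_events` object (or a data.frame with `segment_id`,
#'   `category`, `count`); only `inter:` categories contribute.
#' @param opp An [opportunity_table()] covering every segment in `events`.
#' @param rounding `"none"` (default) or `"integer"`, which rounds each
#'   summed expectation to the nearest whole count (half away from zero), the
#'   convention used when reproducing published integer expecteds.
#' @param exclude_groups Optional character vector of group labels whose
#'   pairings are removed from both the observed totals and the weights.
#' @return Named numeric vector of expected counts per inter-group category
#'   (attributes: `observed`, `totals` per segment, `rounding`).
#' @export
expected_counts <- function(events, opp, rounding = c("none", "integer"),
                            exclude_groups = NULL) {
  rounding <- match.arg(rounding)
  xt <- exchange_setup(events, opp, exclude_groups)
  E <- xt$expected
  if (rounding == "integer") E <- round_half_away(E)
  attr(E, "observed") <- xt$observed
  attr(E, "totals") <- xt$totals
  attr(E, "rounding") <- rounding
  E
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

category_groups <- function(category) {
  strsplit(sub("^(inter|intra):", "", category), "|", fixed = TRUE)
}

drop_excluded <- function(categories, exclude_groups) {
  if (is.null(exclude_groups) || !length(exclude_groups)) return(categories)
  keep <- !vapply(category_groups(categories),
                  function(g) any(g %in% exclude_groups), logical(1))
  categories[keep]
}

# shared preparation: observed per category, per-segment totals, weights
exchange_setup <- function(events, opp, exclude_groups = NULL) {
  stopifnot(inherits(opp, "opportunity_table"))
  counts <- if (inherits(events, "tier_events")) events$counts else events
  counts <- counts[startsWith(counts$category, "inter:"), , drop = FALSE]
  keepc <- drop_excluded(unique(counts$category), exclude_groups)
  counts <- counts[counts$category %in% keepc, , drop = FALSE]
  segs <- unique(counts$segment_id)
  missing <- setdiff(segs, names(opp$segments))
  if (length(missing))
    stop("segment(s) without a panel in the opportunity table: ",
         paste(missing, collapse = ", "))
  # categories: all inter pairs over all panels, minus exclusions
  cats <- sort(unique(unlist(lapply(opp$panels, function(p) names(p$inter)))))
  cats <- drop_excluded(cats, exclude_groups)
  unknown <- setdiff(unique(counts$category), cats)
  if (length(unknown))
    stop("observed categories absent from the opportunity table: ",
         paste(unknown, collapse = ", "))
  totals <- vapply(segs, function(s)
    sum(counts$count[counts$segment_id == s]), numeric(1))
  O <- setNames(numeric(length(cats)), cats)
  for (i in seq_len(nrow(counts)))
    O[counts$category[i]] <- O[counts$category[i]] + counts$count[i]
  # per-segment weight rows
  W <- matrix(0, nrow = length(segs), ncol = length(cats),
              dimnames = list(segs, cats))
  for (s in segs) {
    p <- opp$panels[[opp$segments[[s]]]]
    n_c <- p$inter[drop_excluded(names(p$inter), exclude_groups)]
    denom <- p$inter_denominator
    if (!is.null(exclude_groups) && length(exclude_groups) &&
        denom == p$n_inter)
      denom <- sum(n_c)  # derived denominators shrink with exclusions
    if (denom <= 0) stop("panel '", opp$segments[[s]],
                         "' has zero total inter-group pairings")
    W[s, names(n_c)] <- n_c / denom
  }
  E <- setNames(as.numeric(totals %*% W), cats)
  list(observed = O, expected = E, totals = totals, weights = W, cats = cats)
}

#' Pearson chi-square score over categories
#'
#' `X^2 = sum_c (O_c - E_c)^2 / E_c`, summed over group-pair categories (a
#' stratified, CMH-like goodness-of-fit score). Categories with `E_c = 0`
#' and `O_c = 0` are skipped; categories with `E_c = 0` but `O_c > 0` cannot
#' contribute a finite term and are flagged (they are assessed only through
#' the simulation).
#'
#' @param O,E Equal-length (optionally named) numeric vectors of observed
#'   and expected counts.
#' @return The score, with attribute `flagged` naming any `E = 0, O > 0`
#'   categories.
#' @export
pearson_score <- function(O, E) {
  stopifnot(length(O) == length(E))
  if (!is.null(names(O)) && !is.null(names(E))) E <- E[names(O)]
  flagged <- which(E == 0 & O > 0)
  use <- E > 0
  x2 <- sum((O[use] - E[use])^2 / E[use])
  attr(x2, "flagged") <- if (length(flagged)) names(O)[flagged] else character()
  x2
}

#' Simulation test for non-random between-group exchange
#'
#' Tests whether observed inter-group conversion counts depart from the
#' proportional-opportunity null. The observed Pearson score
#' ([pearson_score()] of observed vs expected category counts summed over
#' segments) is compared with the same score for `n_sims` simulated count
#' sets: in each simulation the observed event total of every segment is
#' reassigned to group-pair categories by a multinomial draw with that
#' segment's opportunity weights, the draws are summed across segments, and
#' the score recomputed. The global p-value is the proportion of simulations
#' whose score is greater than or equal to the observed score. Per-category
#' one-sided tails (`p_over`, `p_under`) are the proportions of simulations
#' with a summed category count at least / at most the observed count.
#'
#' @inheritParams expected_counts
#' @param n_sims Number of simulated count sets (the study-scale default is
#'   `1e6`; smaller values are appropriate for interactive use).
#' @param seed Optional RNG seed.
#' @return Object of class `exchange_test`: list with `observed`, `expected`,
#'   `statistic`, `p_global`, `per_category` (data.frame with category,
#'   observed, expected, p_over, p_under), `n_sims`, `seed`, `flagged`.
#' @export
exchange_test <- function(events, opp, n_sims = 1e6, seed = NULL,
                          exclude_groups = NULL) {
  stopifnot(n_sims >= 1)
  n_sims <- as.integer(n_sims)
  xt <- exchange_setup(events, opp, exclude_groups)
  O <- xt$observed; E <- xt$expected
  x2 <- pearson_score(O, E)
  if (!is.null(seed)) set.seed(seed)
  K <- length(xt$cats)
  tot <- matrix(0L, nrow = K, ncol = n_sims)
  for (s in rownames(xt$weights)) {
    Ts <- xt$totals[[s]]
    if (Ts <= 0) next
    w <- xt$weights[s, ]
    tot <- tot + rmultinom(n_sims, size = Ts, prob = w)
  }
  use <- E > 0
  x2_sim <- colSums((tot[use, , drop = FALSE] - E[use])^2 / E[use])
  p_global <- mean(x2_sim >= as.numeric(x2))
  p_over <- rowMeans(tot >= O)
  p_under <- rowMeans(tot <= O)
  structure(
    list(observed = O, expected = E, statistic = as.numeric(x2),
         p_global = p_global,
         per_category = data.frame(category = xt$cats, observed = O,
                                   expected = E, p_over = p_over,
                                   p_under = p_under, row.names = NULL,
                                   stringsAsFactors = FALSE),
         n_sims = n_sims, seed = seed, flagged = attr(x2, "flagged")),
    class = "exchange_test")
}

#' @export
print.exchange_test <- function(x, digits = 4, ...) {
  cat("Between-group exchange test (proportional-opportunity null)\n")
  p_str <- if (x$p_global == 0) sprintf("< %g", 1 / x$n_sims)
           else sprintf("= %.*g", digits, x$p_global)
  cat(sprintf("  Pearson X^2 = %.*g, p %s (%d multinomial simulations)\n",
              digits, x$statistic, p_str, x$n_sims))
  if (length(x$flagged))
    cat("  flagged (zero expectation, nonzero observed):",
        paste(x$flagged, collapse = ", "), "\n")
  df <- x$per_category
  df$expected <- round(df$expected, 3)
  print.data.frame(df, ...)
  invisible(x)
}

#' Write an exchange-test result as JSON plus per-category TSV
#' @param x An [exchange_test()] result.
#' @param json_path,tsv_path Output paths (`NULL` skips).
#' @return Invisibly, the written paths.
#' @export
write_exchange_test <- function(x, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(statistic = x$statistic, p_global = x$p_global,
                    n_sims = x$n_sims, seed = x$seed,
                    observed = as.list(x$observed),
                    expected = as.list(x$expected),
                    flagged = x$flagged)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path))
    write.table(x$per_category, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(json = json_path, tsv = tsv_path))
}
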
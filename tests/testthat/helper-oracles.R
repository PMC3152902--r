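# Independent oracles and small fixture builders used across test files.

# Exhaustive O(n^2) best-interval search: maximize sum, then smallest start,
# then smallest end. Returns c(sum, start, end) with 0-based half-open
# interval, or NULL when no positive interval exists.
oracle_best_interval <- function(x, lo = 0L, hi = length(x)) {
  best <- 0L; bi <- -1L; bj <- -1L
  if (hi - lo < 1L) return(NULL)
  for (i in (lo + 1L):hi) {
    s <- 0L
    for (j in i:hi) {
      s <- s + x[j]
      if (s > best) { best <- s; bi <- i - 1L; bj <- j }
    }
  }
  if (bi < 0L) return(NULL)
  c(sum = best, start = bi, end = bj)
}

# Recursive maximal-segment decomposition built on the exhaustive search.
oracle_maximal_segments <- function(x, lo = 0L, hi = length(x)) {
  if (hi - lo < 1L) return(NULL)
  seg <- x[(lo + 1L):hi]
  b <- oracle_best_interval(seg)
  if (is.null(b)) return(NULL)
  this <- data.frame(psite_start = lo + b[["start"]], psite_end = lo + b[["end"]],
                     score = b[["sum"]])
  rbind(oracle_maximal_segments(x, lo, lo + b[["start"]]),
        this,
        oracle_maximal_segments(x, lo + b[["end"]], hi))
}

# Quick alignment builder from a vector of residue strings.
make_aln <- function(seqs, groups, segment_id = "seg1", outgroup = NULL,
                     panel_id = "panel1") {
  grouped_alignment(seqs, groups, segment_id = segment_id,
                    outgroup = outgroup, panel_id = panel_id)
}

# Random ungrouped-noise alignment (iid columns; no group structure).
random_aln <- function(n_strains, len, seed, p_gap = 0.05) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n_strains))
  seqs <- vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                 prob = c(rep((1 - p_gap) / 4, 4), p_gap)), collapse = ""),
    character(1))
  make_aln(seqs, setNames(rep("A", n_strains), ids))
}

# Random fragment table over a configurable universe of cells/borders.
random_fragments <- function(n, seed, n_segments = 3, n_borders = 4) {
  set.seed(seed)
  if (n == 0L)
    return(data.frame(segment_id = character(), strain1 = character(),
                      strain2 = character(), start = integer(),
                      end = integer(), psite_start = integer(),
                      psite_end = integer(), score = integer(),
                      p_global = numeric(), category = character(),
                      stringsAsFactors = FALSE))
  groups <- c("A", "B1", "B2", "D")
  g1 <- sample(groups, n, replace = TRUE)
  g2 <- sample(groups, n, replace = TRUE)
  starts <- sample(seq(0, 900, by = 300)[seq_len(n_borders)], n, replace = TRUE)
  data.frame(
    segment_id = paste0("seg", sample.int(n_segments, n, replace = TRUE)),
    strain1 = paste0(g1, "_1"), strain2 = paste0(g2, "_2"),
    start = starts, end = starts + sample(c(100L, 150L), n, replace = TRUE),
    psite_start = 0L, psite_end = 1L, score = 1L, p_global = 0,
    category = phylorecomb:::pair_category(g1, g2),
    stringsAsFactors = FALSE)
}

# Two-panel opportunity layout used by the simulation-test experiments.
two_panel_opportunities <- function() {
  opportunity_table(
    list(p1 = c(A = 6, B1 = 5, B2 = 4, D = 6),
         p2 = c(A = 5, B1 = 4, B2 = 6, D = 5, E = 3)),
    c(seg1 = "p1", seg2 = "p1", seg3 = "p2", seg4 = "p2"))
}

# Draw per-segment inter-group counts from the proportional null (optionally
# boosting one category), as a counts data.frame for exchange_test().
draw_null_counts <- function(opp, totals, seed, boost_category = NULL,
                             boost = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(totals), function(s) {
    p <- opp$panels[[opp$segments[[s]]]]
    w <- p$inter
    if (!is.null(boost_category)) w[boost_category] <- w[boost_category] * boost
    k <- rmultinom(1, totals[[s]], w / sum(w))[, 1]
    data.frame(segment_id = s, category = names(p$inter), count = k,
               stringsAsFactors = FALSE)
  }))
}
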
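test_that("polymorphic projection keeps exactly the multi-state columns", {
  # columns: A/A/A, A/C/A, G/G/-, T/T/T -> only column 1 is polymorphic
  a <- make_aln(c(s1 = "AAGT", s2 = "ACGT", s3 = "AA-T"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  pr <- project_polymorphic(a)
  expect_equal(pr$site_columns, 1L)
  expect_equal(unname(pr$site_matrix[1, ]), c("A", "C", "A"))

  # all identical -> empty site list
  b <- make_aln(c(s1 = "ACGT", s2 = "ACGT"), c(s1 = "A", s2 = "A"))
  expect_length(project_polymorphic(b)$site_columns, 0L)

  # outgroup is excluded from the polymorphism call
  d <- make_aln(c(s1 = "AAAA", s2 = "AAAA", og = "AGAA"),
                c(s1 = "A", s2 = "A", og = "O"), outgroup = "og")
  expect_length(project_polymorphic(d)$site_columns, 0L)
})

test_that("projection matches an independent per-column recount", {
  a <- random_aln(6, 300, seed = 5)
  pr <- project_polymorphic(a)
  m <- do.call(rbind, strsplit(unname(a$sequences), ""))
  expected <- which(apply(m, 2, function(col)
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2)) - 1L
  expect_equal(pr$site_columns, expected)
})

test_that("pair profiles classify match, mismatch and skip correctly", {
  a <- make_aln(c(s1 = "ACGT", s2 = "ACCA", s3 = "GT-A"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  pr <- project_polymorphic(a)
  expect_equal(length(pr$site_columns), 4L)

  p12 <- pair_profile(pr, "s1", "s2")
  expect_equal(p12$match, c(TRUE, TRUE, FALSE, FALSE))

  p13 <- pair_profile(pr, "s1", "s3")  # s3 has a gap at column 2
  expect_equal(length(p13$match), 3L)
  expect_equal(p13$columns, c(0L, 1L, 3L))

  ident <- pair_profile(pr, "s1", "s1")
  expect_true(all(ident$match))

  expect_error(pair_profile(pr, "s1", "zz"), "unknown strain")

  # conservation: matches + mismatches + skips = polymorphic sites
  expect_equal(length(p13$match) + (length(pr$site_columns) - length(p13$psite)),
               length(pr$site_columns))
})

test_that("maximal scoring fragments obey the forced small cases", {
  all_match <- rep(TRUE, 7)
  fr <- max_scoring_fragments(all_match, g = 1)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$score, 7L)
  expect_equal(c(fr$psite_start, fr$psite_end), c(0L, 7L))

  # g = 0: mismatches terminate fragments
  mmxmm <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  fr0 <- max_scoring_fragments(mmxmm, g = 0)
  expect_equal(nrow(fr0), 2L)
  expect_equal(fr0$score, c(2L, 2L))
  expect_equal(fr0$psite_start, c(0L, 3L))

  expect_equal(nrow(max_scoring_fragments(logical(0))), 0L)
})

test_that("maximal fragments equal the exhaustive-enumeration oracle", {
  set.seed(91)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    match <- runif(n) < 0.6
    g <- sample(c(0, 0.5, 1, 2), 1)
    got <- max_scoring_fragments(match, g)
    k <- sum(match); m <- sum(!match)
    B <- if (m == 0L || g == 0) k + 1L else as.integer(ceiling(g * k / m))
    want <- oracle_maximal_segments(ifelse(match, 1L, -B))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_equal(as.data.frame(got), want)
    }
    # maximality forces match endpoints
    if (nrow(got)) {
      expect_true(all(match[got$psite_start + 1L]))
      expect_true(all(match[got$psite_end]))
    }
  }
})

test_that("detection handles degenerate and tiny inputs", {
  b <- make_aln(c(s1 = "ACGT", s2 = "ACGT"), c(s1 = "A", s2 = "A"))
  expect_message(fr <- detect_fragments(b, detector_config(n_permutations = 5)),
                 "no polymorphic sites")
  expect_equal(nrow(fr), 0L)

  # a single permutation that ties the observed maximum gives p = 1:
  # s1/s2 agree at every polymorphic site, so every column order ties
  a <- make_aln(c(s1 = "ACGTAC", s2 = "ACGTAC", s3 = "TTACCA"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  fr1 <- detect_fragments(a, detector_config(n_permutations = 1, seed = 3))
  expect_equal(nrow(fr1), 0L)  # p = 1 cannot pass the alpha gate
  cands <- attr(fr1, "candidates")
  expect_gte(nrow(cands), 1L)
  expect_true(all(cands$p_global == 1))
})

test_that("detection is invariant to strain input order", {
  pan <- generate_panel(generator_config(
    groups = c(A = 3L, B1 = 3L), n_segments = 1L, segment_length = 3000L,
    planted_events = list(planted_event(1, "A", "B1", 500, 1500,
                                        timing = "terminal"))), seed = 21)
  a <- pan$alignments$seg1
  b <- a
  perm <- rev(seq_along(b$sequences))
  b$sequences <- b$sequences[perm]
  b$groups <- b$groups[perm]
  cfg <- detector_config(n_permutations = 150, seed = 9)
  expect_equal(as.data.frame(detect_fragments(a, cfg)),
               as.data.frame(detect_fragments(b, cfg)))
})

test_that("a planted between-group tract is recovered with matching interval", {
  pan <- generate_panel(generator_config(
    groups = c(A = 3L, B1 = 3L), n_segments = 1L, segment_length = 6000L,
    planted_events = list(planted_event(1, "A", "B1", 2000, 4000,
                                        timing = "terminal"))), seed = 33)
  fr <- detect_fragments(pan$alignments$seg1,
                         detector_config(n_permutations = 200, seed = 14))
  hit <- fr[fr$strain1 == "A_1" & fr$strain2 == "B1_1", , drop = FALSE]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$start < 4000 & hit$end > 2000))
  expect_equal(unique(hit$category), "inter:A|B1")
  expect_true(all(fr$p_global <= 0.05))
  expect_true(all(fr$start < fr$end) && all(fr$score > 0))
})

test_that("family-wise error on no-conversion panels stays near alpha", {
  n_panels <- 30
  any_hit <- logical(n_panels)
  for (i in seq_len(n_panels)) {
    pan <- generate_panel(generator_config(groups = c(A = 3L, B1 = 3L),
                                           n_segments = 1L,
                                           segment_length = 2000L),
                          seed = 400 + i)
    fr <- detect_fragments(pan$alignments$seg1,
                           detector_config(n_permutations = 200,
                                           seed = 700 + i))
    any_hit[i] <- nrow(fr) > 0
  }
  # alpha + 3 binomial sd of Monte-Carlo error
  expect_lte(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / n_panels))
})
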
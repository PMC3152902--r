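test_that("grouped_alignment validates its invariants", {
  a <- make_aln(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "ACGTACGTTT"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  expect_s3_class(a, "grouped_alignment")
  expect_equal(length(a$sequences), 3L)
  expect_equal(sort(unique(a$groups)), c("A", "B1"))
  expect_equal(alignment_length(a), 10L)

  expect_error(make_aln(c(s1 = "ACGTACGTAC", s2 = "ACGT"),
                        c(s1 = "A", s2 = "A")),
               "length mismatch.*s2")
  expect_error(make_aln(c(s1 = "ACGU"), c(s1 = "A")), "unknown residue 'U'")
  expect_error(make_aln(c(s1 = "ACGT", s2 = "ACGT"), c(s1 = "A")),
               "no group label.*s2")
  expect_error(make_aln(c(s1 = "ACGT"), c(s1 = "A"), outgroup = "zz"),
               "outgroup")
})

test_that("generator panels round-trip through FASTA and metadata files", {
  pan <- generate_panel(generator_config(groups = c(A = 2L, B1 = 3L),
                                         n_segments = 1L,
                                         segment_length = 400L),
                        seed = 11)
  a <- pan$alignments$seg1
  fa <- tempfile(fileext = ".fasta")
  md_path <- tempfile(fileext = ".tsv")
  write_grouped_alignment(a, fa)
  md <- data.frame(strain_id = names(a$sequences),
                   group = unname(a$groups),
                   panel_id = a$panel_id,
                   is_outgroup = names(a$sequences) == a$outgroup)
  write_strain_metadata(md, md_path)

  b <- read_grouped_alignment(fa, md_path, segment_id = "seg1")
  expect_identical(b$sequences[names(a$sequences)], a$sequences)
  expect_identical(b$groups[names(a$groups)], a$groups)
  expect_identical(b$outgroup, a$outgroup)

  # strain missing from FASTA is reported and dropped
  md2 <- rbind(md, data.frame(strain_id = "ghost", group = "A",
                              panel_id = a$panel_id, is_outgroup = FALSE))
  write_strain_metadata(md2, md_path)
  expect_message(d <- read_grouped_alignment(fa, md_path, "seg1"), "ghost")
  expect_false("ghost" %in% names(d$sequences))

  # strain in FASTA but not metadata is an error
  write_strain_metadata(md[-1, ], md_path)
  expect_error(read_grouped_alignment(fa, md_path, "seg1"),
               "not in metadata")
})

test_that("the bundled synthetic example segment loads cleanly", {
  fa <- system.file("extdata", "example_segment.fasta",
                    package = "phylorecomb")
  md <- system.file("extdata", "example_metadata.tsv",
                    package = "phylorecomb")
  a <- read_grouped_alignment(fa, md, segment_id = "seg1")
  expect_equal(length(a$sequences), 7L)  # 6 ingroup strains + outgroup
  expect_equal(alignment_length(a), 600L)
  expect_equal(a$outgroup, "OUTGROUP")
  expect_setequal(unique(a$groups[ingroup_strains(a)]), c("A", "B1", "B2"))
})

test_that("metadata reader enforces uniqueness and one outgroup per panel", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tgroup\tpanel_id\tis_outgroup",
               "s1\tA\tp1\tFALSE", "s1\tB1\tp1\tFALSE"), p)
  expect_error(read_strain_metadata(p), "duplicate strain_id")
  writeLines(c("strain_id\tgroup\tpanel_id\tis_outgroup",
               "s1\tA\tp1\tTRUE", "s2\tB1\tp1\tTRUE"), p)
  expect_error(read_strain_metadata(p), "more than one outgroup")
})

test_that("masking blanks both strains over the interval and only there", {
  a <- make_aln(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "TTTTTTTTTT"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  expect_identical(mask_fragments(a, data.frame()), a)

  fr <- data.frame(segment_id = "seg1", strain1 = "s1", strain2 = "s2",
                   start = 2L, end = 5L)
  m <- mask_fragments(a, fr)
  expect_equal(m$sequences[["s1"]], "AC---CGTAC")
  expect_equal(m$sequences[["s2"]], "AC---CGTAC")
  expect_equal(m$sequences[["s3"]], a$sequences[["s3"]])
  # input untouched
  expect_equal(a$sequences[["s1"]], "ACGTACGTAC")

  expect_error(mask_fragments(a, data.frame(segment_id = "seg1",
                                            strain1 = "s1", strain2 = "s2",
                                            start = 8L, end = 12L)),
               "out of range")
  expect_error(mask_fragments(a, data.frame(segment_id = "zz",
                                            strain1 = "s1", strain2 = "s2",
                                            start = 0L, end = 2L)),
               "segment_id")
})

test_that("overlapping masks union, and masking is idempotent", {
  a <- make_aln(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "TTTTTTTTTT"),
                c(s1 = "A", s2 = "A", s3 = "B1"))
  fr <- data.frame(segment_id = "seg1",
                   strain1 = c("s1", "s1"), strain2 = c("s2", "s3"),
                   start = c(2L, 4L), end = c(6L, 8L))
  m <- mask_fragments(a, fr)
  masked_cols <- which(strsplit(m$sequences[["s1"]], "")[[1]] == "-") - 1L
  expect_equal(masked_cols, sort(union(2:5, 4:7)))  # union oracle, 0-based
  m2 <- mask_fragments(m, fr)
  expect_identical(m2, m)
  expect_equal(alignment_length(m), alignment_length(a))
  expect_identical(names(m$sequences), names(a$sequences))
})
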
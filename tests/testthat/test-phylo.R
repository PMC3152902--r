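test_that("K2P distances match the closed form and the ape reference", {
  # identical sequences -> zero distance
  a <- make_aln(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "ACGTACGTAC"),
                c(s1 = "A", s2 = "A", s3 = "A"))
  expect_true(all(k2p_distances(a)$d == 0))

  # 10 transitions in 100 sites, no transversions: d = -0.5 * log(0.8)
  base <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  s2 <- base
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  s2[1:10] <- ts[s2[1:10]]
  b <- make_aln(c(x = paste(base, collapse = ""),
                  y = paste(s2, collapse = ""),
                  z = paste(base, collapse = "")),
                c(x = "A", y = "A", z = "A"))
  d <- k2p_distances(b)
  expect_equal(d$d["x", "y"], -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(round(d$d["x", "y"], 5), 0.11157)
  expect_equal(d$n_sites, 100L)

  # random alignment: agree with ape::dist.dna(K80, complete deletion)
  pan <- generate_panel(generator_config(groups = c(A = 3L, B1 = 3L),
                                         n_segments = 1L,
                                         segment_length = 2000L), seed = 2)
  aln <- pan$alignments$seg1
  ours <- k2p_distances(aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$sequences), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = FALSE))
  expect_equal(ours$d[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
               ignore_attr = TRUE)

  # complete deletion: retained column count invariant to strain order
  perm <- aln
  ord <- rev(names(perm$sequences))
  perm$sequences <- perm$sequences[ord]
  perm$groups <- perm$groups[ord]
  expect_equal(k2p_distances(perm)$n_sites, ours$n_sites)
})

test_that("saturated pairs error by default and can be capped", {
  a <- make_aln(c(x = "ACGTACGTACGT", y = "GTACGTACGTAC", z = "ACGTACGTACGT"),
                c(x = "A", y = "A", z = "A"))
  expect_error(k2p_distances(a), "saturated")
  capped <- k2p_distances(a, on_saturation = "cap", cap = 9)
  expect_equal(capped$d["x", "y"], 9)
  expect_true(capped$saturated["x", "y"])
})

test_that("NJ recovers additive toy trees and breaks ties deterministically", {
  # additive distances from a known 5-taxon tree
  tr <- ape::read.tree(text = "(((a:1,b:2):3,c:2):2,(d:1,e:1):4);")
  dm <- ape::cophenetic.phylo(tr)
  got <- nj_tree(dm, outgroup = "e")
  expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(tr)), 0,
               ignore_attr = TRUE)

  # permuted input order gives the identical tree
  ord <- c("d", "b", "e", "a", "c")
  got2 <- nj_tree(dm[ord, ord], outgroup = "e")
  expect_true(ape::all.equal.phylo(got, got2, use.edge.length = FALSE))

  # three taxa: the unique resolution
  d3 <- dm[c("a", "b", "c"), c("a", "b", "c")]
  expect_warning(t3 <- nj_tree(d3), "no outgroup")
  expect_equal(ape::Ntip(t3), 3L)
})

test_that("bootstrap supports are calibrated on clean signal", {
  # two maximally distinct, internally identical clades
  blockA <- paste(rep("A", 60), collapse = "")
  blockB <- paste(rep("C", 60), collapse = "")
  mix <- paste(rep("GT", 30), collapse = "")
  a <- make_aln(c(a1 = blockA, a2 = blockA, b1 = blockB, b2 = blockB,
                  og = mix),
                c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", og = "O"),
                outgroup = "og")
  bs <- bootstrap_support(a, n_reps = 50, seed = 3)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  expect_true(any(bs$support == 1))
  bs2 <- bootstrap_support(a, n_reps = 50, seed = 3)
  expect_identical(bs2$support, bs$support)

  # strong-signal generator panel: ingroup split has full support
  pan <- generate_panel(generator_config(groups = c(A = 3L, B1 = 3L),
                                         n_segments = 1L,
                                         segment_length = 3000L,
                                         inter_group_divergence = 0.05),
                        seed = 9)
  bsp <- bootstrap_support(pan$alignments$seg1, n_reps = 40, seed = 5)
  expect_gte(max(bsp$support), 0.95)
})

test_that("group topologies collapse, flag paraphyly, and compare", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B1", b2 = "B1", d1 = "D", d2 = "D",
              og = "O")
  t1 <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(d1,d2),og);")
  t1 <- ape::root(t1, outgroup = "og", resolve.root = TRUE)
  g1 <- group_topology(t1, groups, outgroup = "og")
  expect_false(any(g1$paraphyletic))
  expect_setequal(g1$leaves, c("A", "B1", "D"))

  # identical trees are congruent; within-group rearrangement is invisible
  t2 <- ape::read.tree(text = "(((a2,a1),(b1,b2)),(d2,d1),og);")
  t2 <- ape::root(t2, outgroup = "og", resolve.root = TRUE)
  expect_true(congruent(g1, group_topology(t2, groups, outgroup = "og")))

  # moving a group changes the topology
  t3 <- ape::read.tree(text = "(((a1,a2),(d1,d2)),(b1,b2),og);")
  t3 <- ape::root(t3, outgroup = "og", resolve.root = TRUE)
  expect_false(congruent(g1, group_topology(t3, groups, outgroup = "og")))

  # group D split into two clades -> paraphyly flags and suffixed leaves
  t4 <- ape::read.tree(text = "((d1,(a1,a2)),((b1,b2),d2),og);")
  t4 <- ape::root(t4, outgroup = "og", resolve.root = TRUE)
  g4 <- group_topology(t4, groups, outgroup = "og")
  expect_true(g4$paraphyletic[["D"]])
  expect_setequal(g4$leaves, c("A", "B1", "D.1", "D.2"))

  # mismatched group multisets are an error, not incongruence
  expect_error(congruent(g1, g4), "multisets differ")
})

test_that("congruence is an equivalence relation", {
  groups <- c(a1 = "A", a2 = "A", b1 = "B1", b2 = "B1", d1 = "D", d2 = "D")
  newicks <- c("(((a1,a2),(b1,b2)),(d1,d2));",
               "(((a2,a1),(b2,b1)),(d2,d1));",
               "(((a1,a2),(d1,d2)),(b1,b2));",
               "((a1,a2),((b1,b2),(d1,d2)));")
  tops <- lapply(newicks, function(nw)
    group_topology(ape::read.tree(text = nw), groups))
  n <- length(tops)
  rel <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) congruent(tops[[i]], tops[[j]])))
  expect_true(all(diag(rel)))            # reflexive
  expect_identical(rel, t(rel))          # symmetric
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if (rel[i, j] && rel[j, k]) expect_true(rel[i, k])  # transitive
  # and the first two really are the same topology, the third is not
  expect_true(rel[1, 2])
  expect_false(rel[1, 3])
})
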
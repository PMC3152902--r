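#' Kimura two-parameter distances under complete deletion
#'
#' Removes every alignment column containing a gap or `N` in any strain
#' (complete deletion), then computes for each strain pair the K2P distance
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' transition and transversion fractions over the retained columns.
#'
#' @param aln A [grouped_alignment()] with at least three strains.
#' @param on_saturation `"error"` (default) stops when a pair's distance is
#'   undefined (log argument <= 0); `"cap"` records `cap` instead and flags
#'   the pair.
#' @param cap Distance recorded for saturated pairs when `on_saturation =
#'   "cap"`.
#' @return Object of class `k2p_dist`: list with `d` (symmetric matrix),
#'   `n_sites` (columns retained), `saturated` (logical matrix).
#' @export
k2p_distances <- function(aln, on_saturation = c("error", "cap"), cap = 5) {
  on_saturation <- match.arg(on_saturation)
  stopifnot(inherits(aln, "grouped_alignment"),
            length(aln$sequences) >= 3L)
  m <- aln_matrix(aln)
  keep <- colSums(!matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == 0L
  if (!any(keep)) stop("no columns remain after complete deletion")
  m <- m[, keep, drop = FALSE]
  k2p_from_matrix(m, on_saturation, cap)
}

# strains x columns matrix of pure ACGT residues -> k2p_dist
k2p_from_matrix <- function(m, on_saturation = "error", cap = 5) {
  strains <- rownames(m)
  n <- length(strains)
  L <- ncol(m)
  purine <- matrix(m %in% c("A", "G"), nrow = n)
  d <- matrix(0, n, n, dimnames = list(strains, strains))
  sat <- matrix(FALSE, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- m[i, ] != m[j, ]
      ts <- diff & (purine[i, ] == purine[j, ])  # A<->G or C<->T
      P <- sum(ts) / L
      Q <- sum(diff & !ts) / L
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      if (a1 <= 0 || a2 <= 0) {
        if (on_saturation == "error")
          stop("saturated pair (", strains[i], ", ", strains[j],
               "): K2P distance undefined")
        d[i, j] <- d[j, i] <- cap
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(a1 * sqrt(a2))
      }
    }
  }
  structure(list(d = d, n_sites = L, saturated = sat), class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distances over %d complete-deletion sites (%d strains)\n",
              x$n_sites, nrow(x$d)))
  print(round(x$d, 5))
  invisible(x)
}

#' Neighbor-joining tree, rooted on the outgroup
#'
#' Canonical Saitou-Nei agglomeration; taxa are sorted lexicographically
#' before clustering so that ties break deterministically regardless of input
#' order. If an outgroup is given, the tree is rooted on the outgroup branch
#' with the root placed at that branch's midpoint; otherwise the unrooted
#' tree is returned with a warning.
#'
#' @param dm A [k2p_distances()] result, or a symmetric distance matrix with
#'   dimnames.
#' @param outgroup Optional strain id.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  d <- if (inherits(dm, "k2p_dist")) dm$d else as.matrix(dm)
  ord <- sort(rownames(d))
  tr <- ape::nj(stats::as.dist(d[ord, ord]))
  if (is.null(outgroup)) {
    warning("no outgroup given; returning unrooted tree")
    return(tr)
  }
  if (!outgroup %in% tr$tip.label)
    stop("outgroup '", outgroup, "' not among taxa")
  root_midpoint(tr, outgroup)
}

# root on the outgroup pendant edge, splitting its length evenly
root_midpoint <- function(tr, outgroup) {
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  rootnode <- ape::Ntip(tr) + 1L
  kids <- which(tr$edge[, 1L] == rootnode)
  tipno <- match(outgroup, tr$tip.label)
  og_edge <- kids[tr$edge[kids, 2L] == tipno]
  if (length(og_edge) == 1L && length(kids) == 2L) {
    tot <- sum(tr$edge.length[kids])
    tr$edge.length[kids] <- tot / 2
  }
  tr
}

#' Bootstrap support for the NJ tree
#'
#' Resamples complete-deletion columns with replacement, rebuilds the NJ tree
#' for each replicate, and reports for every internal node of the
#' point-estimate tree the fraction of replicates containing its clade
#' (rooted trees) or bipartition (unrooted).
#'
#' @param aln A [grouped_alignment()].
#' @param outgroup Optional strain id (defaults to the alignment's outgroup).
#' @param n_reps Bootstrap replicates (study-scale default 1000).
#' @param seed Optional RNG seed.
#' @param on_saturation,cap Passed to the distance computation; replicates
#'   default to capping so that resampling noise cannot abort the run.
#' @return List with `tree` (point-estimate tree, node labels = support) and
#'   `support` (numeric vector over internal nodes).
#' @export
bootstrap_support <- function(aln, outgroup = aln$outgroup, n_reps = 1000,
                              seed = NULL, on_saturation = "cap", cap = 5) {
  m <- aln_matrix(aln)
  keep <- colSums(!matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == 0L
  if (!any(keep)) stop("no columns remain after complete deletion")
  m <- m[, keep, drop = FALSE]
  build <- function(mm) {
    dm <- k2p_from_matrix(mm, on_saturation, cap)
    nj_unrooted <- ape::nj(stats::as.dist(dm$d[sort(rownames(dm$d)),
                                               sort(rownames(dm$d))]))
    if (!is.null(outgroup)) root_midpoint(nj_unrooted, outgroup) else nj_unrooted
  }
  point <- build(m)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[r]] <- build(m[, cols, drop = FALSE])
  }
  cnt <- ape::prop.clades(point, reps, rooted = !is.null(outgroup))
  cnt[is.na(cnt)] <- 0L
  support <- cnt / n_reps
  point$node.label <- format(support, trim = TRUE)
  list(tree = point, support = support)
}

#' Group-level topology of a strain tree
#'
#' Collapses every maximal monophyletic same-group clade of a rooted strain
#' tree to a single leaf carrying the group label. Groups whose members do
#' not form a single clade are flagged paraphyletic and contribute one leaf
#' per maximal clade (labels suffixed `.1`, `.2`, ... in tree order). The
#' canonical form (children sorted recursively by their canonical strings,
#' suffixes ignored) identifies the rooted group topology up to isomorphism.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param groups Named character vector mapping tip labels to group labels.
#' @param outgroup Optional tip to drop before collapsing (the root stays at
#'   its attachment point).
#' @return Object of class `group_topology`: list with `leaves` (suffixed
#'   labels, tree order), `paraphyletic` (named logical per group),
#'   `canonical` (string), `newick` (display form).
#' @export
group_topology <- function(tree, groups, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup) && outgroup %in% tree$tip.label)
    tree <- ape::drop.tip(tree, outgroup)
  miss <- setdiff(tree$tip.label, names(groups))
  if (length(miss))
    stop("no group label for tip(s): ", paste(miss, collapse = ", "))
  ntip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  leaves <- character(0)
  node_repr <- function(node) {
    # returns list(canon, display, groups)
    if (node <= ntip) {
      g <- groups[[tree$tip.label[node]]]
      return(list(canon = g, display = g, groups = g))
    }
    kids <- lapply(children[[as.character(node)]], node_repr)
    gs <- unique(unlist(lapply(kids, `[[`, "groups")))
    if (length(gs) == 1L)
      return(list(canon = gs, display = gs, groups = gs))
    canon <- paste0("(", paste(sort(vapply(kids, `[[`, character(1), "canon")),
                               collapse = ","), ")")
    disp <- paste0("(", paste(vapply(kids, `[[`, character(1), "display"),
                              collapse = ","), ")")
    list(canon = canon, display = disp, groups = gs)
  }
  root <- ntip + 1L
  res <- node_repr(root)
  # enumerate collapsed leaves in tree order for suffixing
  collect <- function(node) {
    if (node <= ntip) return(groups[[tree$tip.label[node]]])
    kids <- children[[as.character(node)]]
    gs <- unique(unlist(lapply(kids, collect_groups)))
    if (length(gs) == 1L) return(gs)
    unlist(lapply(kids, collect))
  }
  collect_groups <- function(node) {
    if (node <= ntip) return(groups[[tree$tip.label[node]]])
    unique(unlist(lapply(children[[as.character(node)]], collect_groups)))
  }
  lv <- collect(root)
  tab <- table(lv)
  paraphyletic <- setNames(as.vector(tab) > 1L, names(tab))
  suffixed <- lv
  for (g in names(tab)[tab > 1L])
    suffixed[lv == g] <- paste0(g, ".", seq_len(tab[[g]]))
  structure(list(leaves = suffixed, paraphyletic = paraphyletic,
                 canonical = res$canon,
                 newick = paste0(res$display, ";")),
            class = "group_topology")
}

#' @export
print.group_topology <- function(x, ...) {
  cat("group topology:", x$newick, "\n")
  if (any(x$paraphyletic))
    cat("  paraphyletic:",
        paste(names(x$paraphyletic)[x$paraphyletic], collapse = ", "), "\n")
  invisible(x)
}

#' Are two group topologies congruent?
#'
#' Congruence = identical rooted group-level topology after collapsing
#' within-group structure (canonical-form equality, which for matched leaf
#' multisets is equivalent to zero Robinson-Foulds distance). Trees over
#' different group multisets are an error, not incongruence.
#'
#' @param t1,t2 [group_topology()] objects (or rooted `phylo` trees, in which
#'   case `groups1`/`groups2` must map their tips to groups).
#' @param groups1,groups2 Optional tip-to-group maps when passing raw trees.
#' @return Logical.
#' @export
congruent <- function(t1, t2, groups1 = NULL, groups2 = NULL) {
  if (inherits(t1, "phylo")) t1 <- group_topology(t1, groups1)
  if (inherits(t2, "phylo")) t2 <- group_topology(t2, groups2)
  stopifnot(inherits(t1, "group_topology"), inherits(t2, "group_topology"))
  m1 <- sort(sub("\\.\\d+$", "", t1$leaves))
  m2 <- sort(sub("\\.\\d+$", "", t2$leaves))
  if (!identical(m1, m2))
    stop("group leaf multisets differ between the two topologies")
  identical(t1$canonical, t2$canonical)
}
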
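#' Prune long-branch outliers from a gene tree
#'
#' Fits a log-normal distribution by maximum likelihood to all positive
#' branch lengths of the tree (terminal and internal; zero-length branches
#' are excluded from the fit and never pruned) and removes every subtree
#' whose stem branch exceeds the upper `ppf_upper` quantile of the fit.
#' Because internal branches participate, the rule removes long terminal
#' leaves and highly diverged clades alike. The tree is flagged as discarded
#' when pruning would remove the entire eukaryotic clade (when a taxonomy is
#' supplied) or more than `max_removed_frac` (default 30%) of all leaves.
#'
#' @param tree an `ape::phylo` with branch lengths, at least 4 leaves and at
#'   least 3 positive branch lengths.
#' @param ppf_upper upper quantile of the fitted log-normal used as the
#'   pruning cutoff (default 0.995, i.e. the 0-99.5% interval).
#' @param taxonomy optional `taxonomy_table` used to detect loss of the
#'   eukaryotic clade.
#' @param max_removed_frac fraction of leaves above which the tree is
#'   discarded (default 0.3).
#' @param sd_tol if the fitted log-sd falls below this tolerance the fit is
#'   degenerate (e.g. all branch lengths equal) and nothing is pruned.
#' @return list with elements `tree` (pruned) and `report`, the latter a
#'   list with `removed_leaves`, `removed_clades` (leaf sets of pruned
#'   internal subtrees), `fitted_logmean`, `fitted_logsd`, `upper_cutoff`,
#'   `degenerate_fit`, `discarded` and `discard_reason` (one of
#'   "all-eukaryotes-removed", "over-30-percent-removed", "none").
#' @export
prune_branch_outliers <- function(tree, ppf_upper = 0.995, taxonomy = NULL,
                                  max_removed_frac = 0.3, sd_tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length(tree$tip.label) < 4L) stop("tree must have >= 4 leaves")
  bl <- tree$edge.length
  pos <- bl[bl > 0]
  if (length(pos) < 3L) stop("need at least 3 positive branch lengths")

  lx <- log(pos)
  mu <- mean(lx)
  sg <- stats::sd(lx) * sqrt((length(lx) - 1) / length(lx))  # MLE

  report <- list(removed_leaves = character(0),
                 removed_clades = list(),
                 fitted_logmean = mu, fitted_logsd = sg,
                 upper_cutoff = NA_real_, degenerate_fit = FALSE,
                 discarded = FALSE, discard_reason = "none")
  if (sg < sd_tol) {
    report$degenerate_fit <- TRUE
    return(list(tree = tree, report = report))
  }
  cutoff <- stats::qlnorm(ppf_upper, meanlog = mu, sdlog = sg)
  report$upper_cutoff <- cutoff

  ntip <- length(tree$tip.label)
  flagged <- which(bl > cutoff)
  drop <- character(0)
  for (e in flagged) {
    child <- tree$edge[e, 2]
    if (child <= ntip) {
      drop <- union(drop, tree$tip.label[child])
    } else {
      members <- tree$tip.label[unlist(phangorn::Descendants(tree, child, "tips"))]
      report$removed_clades <- c(report$removed_clades, list(members))
      drop <- union(drop, members)
    }
  }
  report$removed_leaves <- drop

  if (!is.null(taxonomy)) {
    euk <- intersect(tree$tip.label,
                     taxonomy$seq_id[taxonomy$domain == "eukaryote"])
    if (length(euk) > 0 && all(euk %in% drop)) {
      report$discarded <- TRUE
      report$discard_reason <- "all-eukaryotes-removed"
    }
  }
  if (!report$discarded && length(drop) / ntip > max_removed_frac) {
    report$discarded <- TRUE
    report$discard_reason <- "over-30-percent-removed"
  }

  if (length(drop) == 0L || ntip - length(drop) < 2L) {
    return(list(tree = tree, report = report))
  }
  list(tree = ape::drop.tip(tree, drop), report = report)
}

#' Weighted midpoint rooting
#'
#' Re-roots the tree on the edge and position at which the sums of all
#' branch lengths on the two sides of the root are as equal as possible.
#' Within the chosen edge the balance point is solved linearly and clamped
#' to the edge; whenever the balance point is interior the two side sums are
#' exactly equal. Ties between edges are broken by the first edge in the
#' tree's preorder (cladewise) edge numbering. This is a data-structure
#' root, not a phylogenetic (outgroup) root.
#'
#' @param tree an `ape::phylo` with branch lengths and >= 2 leaves.
#' @return re-rooted `ape::phylo`.
#' @export
weighted_midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  tree <- stats::reorder(tree, "cladewise")
  total <- sum(tree$edge.length)
  if (total <= 0) {
    warning("zero total branch length; tree returned unchanged")
    return(tree)
  }
  nedge <- nrow(tree$edge)
  # sum of branch lengths strictly below the child of each edge
  below <- numeric(nedge)
  po <- stats::reorder(tree, "postorder")
  sub <- numeric(max(tree$edge))  # indexed by node
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    sub[p] <- sub[p] + sub[ch] + po$edge.length[i]
  }
  below <- sub[tree$edge[, 2]]
  L <- tree$edge.length
  above <- total - L - below
  x <- (above - below + L) / 2          # measured from the child end
  x <- pmin(pmax(x, 0), L)
  diffs <- abs((below + x) - (above + (L - x)))
  best <- which.min(diffs)              # first minimum = preorder tie-break
  child <- tree$edge[best, 2]
  pos_from_parent <- L[best] - x[best]
  out <- phytools::reroot(tree, node.number = child,
                          position = pos_from_parent)
  stats::reorder(out, "cladewise")
}

#' Topological distance between two nodes
#'
#' Counts the internal bifurcations strictly between two nodes on their
#' connecting path, excluding the tree root. Multifurcating nodes count
#' once. The distance from a node to itself is 0 and sibling clades whose
#' shared parent is not the root are at distance 1.
#'
#' @param tree an `ape::phylo`.
#' @param node_a,node_b node numbers (tips or internal) or tip labels.
#' @return non-negative integer count.
#' @export
topo_distance <- function(tree, node_a, node_b) {
  resolve <- function(n) {
    if (is.character(n)) {
      i <- match(n, tree$tip.label)
      if (is.na(i)) stop("node not found: ", n)
      return(i)
    }
    n <- as.integer(n)
    if (n < 1L || n > max(tree$edge)) stop("node not found: ", n)
    n
  }
  a <- resolve(node_a); b <- resolve(node_b)
  if (a == b) return(0L)
  path <- ape::nodepath(tree, a, b)
  interior <- path[-c(1L, length(path))]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  sum(interior > ntip & interior != root)
}

#' Taxonomy-aware subsampling of tree leaves
#'
#' Reduces a tree to at most `target` leaves while approximating a maximum
#' diversity representation of its taxonomic labels. Pairs of closest leaves
#' are pruned iteratively, but only when the pair forms a label-monophyletic
#' cherry; the leaf closest to the root survives and accumulates the count
#' of leaves pruned in its favour. When no more label-monophyletic pairs
#' exist and the tree is still above target, leaves are ordered by their
#' accumulated pruned-relative counts and the lowest-count leaves (isolated
#' singleton clades first) are deleted until the target is reached.
#'
#' @param tree an `ape::phylo`.
#' @param taxonomy a `taxonomy_table` labelling every leaf.
#' @param target desired leaf count (>= 1). If `target` is not below the
#'   current leaf count the tree is returned unchanged.
#' @param within optional character vector restricting pruning (and the
#'   target count) to a subset of leaves, e.g. the prokaryotic leaves only.
#' @return list with `leaves` (retained leaf names of the whole tree),
#'   `tree` (pruned tree) and `pruned_counts` (named counts of pruned
#'   relatives per surviving leaf).
#' @export
taxonomy_aware_subsample <- function(tree, taxonomy, target, within = NULL) {
  stopifnot(target >= 1)
  lab_of <- function(tips) {
    taxonomy$class_label[match(tips, taxonomy$seq_id)]
  }
  if (is.null(within)) within <- tree$tip.label
  counts <- stats::setNames(integer(length(tree$tip.label)), tree$tip.label)

  n_within <- function(tr) sum(tr$tip.label %in% within)

  repeat {
    if (n_within(tree) <= target) break
    ntip <- length(tree$tip.label)
    parent <- tree$edge[, 1]; child <- tree$edge[, 2]
    depth <- ape::node.depth.edgelength(tree)
    tip_parent <- parent[match(seq_len(ntip), child)]
    tip_bl <- tree$edge.length[match(seq_len(ntip), child)]
    labels <- lab_of(tree$tip.label)
    # cherries: parents with exactly two tip children
    tp <- table(tip_parent)
    cherry_parents <- as.integer(names(tp)[tp == 2])
    best <- NULL
    for (p in cherry_parents) {
      pair <- which(tip_parent == p)
      if (!all(tree$tip.label[pair] %in% within)) next
      if (labels[pair[1]] != labels[pair[2]]) next
      d <- sum(tip_bl[pair])
      key <- paste(sort(tree$tip.label[pair]), collapse = "\r")
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 && key < best$key)) {
        best <- list(pair = pair, d = d, key = key)
      }
    }
    if (is.null(best)) break
    pr <- best$pair
    dp <- depth[pr]
    keep_i <- if (dp[1] < dp[2] ||
                  (dp[1] == dp[2] &&
                   tree$tip.label[pr[1]] < tree$tip.label[pr[2]])) 1L else 2L
    keeper <- tree$tip.label[pr[keep_i]]
    loser <- tree$tip.label[pr[-keep_i]]
    counts[keeper] <- counts[keeper] + counts[loser] + 1L
    counts <- counts[names(counts) != loser]
    tree <- ape::drop.tip(tree, loser)
  }

  extra <- n_within(tree) - target
  if (extra > 0) {
    cand <- intersect(tree$tip.label, within)
    ord <- order(counts[cand], cand)   # lowest pruned-count (singletons) first
    drop <- cand[ord][seq_len(extra)]
    counts <- counts[!names(counts) %in% drop]
    tree <- ape::drop.tip(tree, drop)
  }
  list(leaves = tree$tip.label, tree = tree, pruned_counts = counts)
}

#' Partition a supercluster tree into well-separated leaf groups
#'
#' Computes the all-vs-all patristic distance matrix, embeds it in two
#' dimensions, and groups the embedded leaves with single-linkage
#' agglomeration cut at a relative merge-height gap. Trees whose pairwise
#' distances are homogeneous yield a single partition (single-cluster
#' outputs are explicitly allowed); trees containing mutually distant clades
#' are split into one group per clade. Used to break overclustered gene
#' superfamilies into clades that can be analysed separately.
#'
#' @param tree an `ape::phylo` with >= 3 leaves.
#' @param min_size below this leaf count the embedding neighbourhood is
#'   unreliable and a single partition is returned (default 8).
#' @param gap_factor the top `j` merges are cut away only when the smallest
#'   of them exceeds `gap_factor` times the largest remaining merge height
#'   (default 5); the coarsest such cut is taken, so nested substructure
#'   does not fragment a clade.
#' @param max_groups upper bound on the number of groups searched
#'   (default 8).
#' @return named integer vector assigning each leaf to a group (1..k).
#' @export
partition_supercluster <- function(tree, min_size = 8L, gap_factor = 5,
                                   max_groups = 8L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("tree must have >= 3 leaves")
  single <- stats::setNames(rep(1L, n), tree$tip.label)
  if (n < min_size) return(single)
  D <- ape::cophenetic.phylo(tree)
  emb <- stats::cmdscale(D, k = 2)
  hc <- stats::hclust(stats::dist(emb), method = "single")
  h <- hc$height
  nm <- length(h)
  for (j in seq_len(min(max_groups - 1L, nm - 1L))) {
    if (h[nm - j + 1L] > gap_factor * max(h[seq_len(nm - j)])) {
      grp <- stats::cutree(hc, k = j + 1L)
      return(stats::setNames(as.integer(grp), tree$tip.label))
    }
  }
  single
}
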
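#' Soft-LCA clade score
#'
#' Score of an internal node as the "soft" last common ancestor of a taxon
#' label: the product of the clade's purity for that label and the fraction
#' of the label's leaves the clade captures,
#' `(n/clade_size) * (n/total_label)`. The score balances taxonomic purity
#' against scope and permits near-monophyletic clades; it is reported as
#' metadata but is never used as a filtering criterion (validity relies on
#' size and purity thresholds only).
#'
#' @param n_label_in_clade leaves carrying the label inside the clade.
#' @param clade_size total leaves in the clade.
#' @param total_label total leaves carrying the label in the whole tree.
#' @return fraction in (0, 1].
#' @examples
#' soft_lca_score(4, 5, 8)   # 0.4
#' @export
soft_lca_score <- function(n_label_in_clade, clade_size, total_label) {
  if (clade_size <= 0 || total_label <= 0) stop("zero denominator")
  stopifnot(n_label_in_clade >= 1,
            n_label_in_clade <= clade_size,
            n_label_in_clade <= total_label)
  (n_label_in_clade / clade_size) * (n_label_in_clade / total_label)
}

#' Detect taxon clades in a labelled gene tree
#'
#' Assigns every leaf its curated taxon label (prokaryotic leaves use their
#' class label; eukaryotic leaves are detected jointly at the domain level,
#' since a eukaryotic clade of interest spans many class labels) and, for
#' each label, scores every ancestor of each monophyletic group of that
#' label with the soft-LCA score. Per label, candidates are ranked by score
#' and accepted greedily, skipping candidates that overlap an already
#' accepted clade. A candidate is valid when it has at least `min_prok`
#' (prokaryotic) or `min_euk` (eukaryotic) leaves and label purity strictly
#' greater than `purity_min`. Labels are processed independently, so calls
#' of different labels may overlap.
#'
#' @param tree rooted `ape::phylo`; every leaf must be present in `taxonomy`.
#' @param taxonomy a `taxonomy_table`.
#' @param min_prok,min_euk minimum clade sizes (defaults 3 and 5).
#' @param purity_min strict purity threshold (default 0.8).
#' @return list of clade calls; each is a list with `node`, `label`,
#'   `domain`, `members`, `clade_size`, `n_label`, `purity`, `score`.
#' @export
detect_clades <- function(tree, taxonomy, min_prok = 3L, min_euk = 5L,
                          purity_min = 0.8) {
  stopifnot(inherits(tree, "phylo"))
  idx <- match(tree$tip.label, taxonomy$seq_id)
  if (anyNA(idx)) {
    stop("unlabeled leaves: ",
         paste(utils::head(tree$tip.label[is.na(idx)]), collapse = ", "))
  }
  domain <- taxonomy$domain[idx]
  leaf_label <- ifelse(domain == "eukaryote", "eukaryote",
                       taxonomy$class_label[idx])

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  labels <- unique(leaf_label)
  # per-node label counts and clade sizes by postorder accumulation
  po <- stats::reorder(tree, "postorder")
  cnt <- matrix(0L, ntip + nnode, length(labels),
                dimnames = list(NULL, labels))
  cnt[cbind(seq_len(ntip), match(leaf_label, labels))] <- 1L
  size <- c(rep(1L, ntip), rep(0L, nnode))
  parent_of <- integer(ntip + nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    cnt[p, ] <- cnt[p, ] + cnt[ch, ]
    size[p] <- size[p] + size[ch]
    parent_of[ch] <- p
  }
  tips_under <- function(node) {
    if (node <= ntip) tree$tip.label[node]
    else tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
  }

  calls <- list()
  for (lab in labels) {
    total <- cnt[root, lab]
    # roots of maximal pure subtrees of this label
    pure <- cnt[, lab] == size & size > 0
    group_roots <- which(pure & (parent_of == 0L | !pure[pmax(parent_of, 1L)]))
    if (pure[root]) group_roots <- root
    # candidate nodes: each group root and all its ancestors up to the tree root
    cand <- integer(0)
    for (g in group_roots) {
      node <- g
      repeat {
        cand <- c(cand, node)
        if (node == root) break
        node <- parent_of[node]
      }
    }
    cand <- unique(cand)
    cand <- cand[cand > ntip | size[cand] == 1L]  # internal nodes or singleton leaves
    n_lab <- cnt[cand, lab]
    sz <- size[cand]
    purity <- n_lab / sz
    score <- purity * (n_lab / total)
    ord <- order(-score, -sz, cand)
    dom <- if (lab == "eukaryote") "eukaryotic" else "prokaryotic"
    min_size <- if (dom == "eukaryotic") min_euk else min_prok
    taken <- character(0)
    for (j in ord) {
      if (sz[j] < min_size || purity[j] <= purity_min) next
      members <- tips_under(cand[j])
      if (any(members %in% taken)) next
      taken <- c(taken, members)
      calls[[length(calls) + 1L]] <- list(
        node = cand[j], label = lab, domain = dom, members = members,
        clade_size = as.integer(sz[j]), n_label = as.integer(n_lab[j]),
        purity = purity[j], score = score[j])
    }
  }
  calls
}

#' Assemble an EPOC from a processed tree and its clade calls
#'
#' A eukaryotic-prokaryotic orthologous cluster (EPOC) is accepted when the
#' clade calls contain between one and three valid eukaryotic clades and at
#' least one valid prokaryotic clade. Trees without any eukaryotic or any
#' prokaryotic clade are rejected, and trees with more than three eukaryotic
#' clades show high paraphyly and are likewise rejected; the reason is
#' recorded.
#'
#' @param tree processed (pruned, rooted) `ape::phylo`.
#' @param alignment the trimmed `aa_alignment` covering the tree's leaves.
#' @param calls clade calls from [detect_clades()].
#' @param taxonomy the `taxonomy_table` for the leaves.
#' @param epoc_id identifier string.
#' @param annotations character vector of functional category labels.
#' @param max_euk_clades maximum number of eukaryotic clades (default 3).
#' @return object of class `epoc`: list with `epoc_id`, `tree`, `alignment`,
#'   `taxonomy`, `euk_clades`, `prok_clades`, `annotations`, `status`
#'   ("accepted" or "rejected:<reason>").
#' @export
assemble_epoc <- function(tree, alignment, calls, taxonomy,
                          epoc_id = "epoc", annotations = character(0),
                          max_euk_clades = 3L) {
  euk <- Filter(function(cl) cl$domain == "eukaryotic", calls)
  prok <- Filter(function(cl) cl$domain == "prokaryotic", calls)
  status <- "accepted"
  if (length(euk) == 0L) {
    status <- "rejected:no-eukaryotic-clade"
  } else if (length(prok) == 0L) {
    status <- "rejected:no-prokaryotic-clade"
  } else if (length(euk) > max_euk_clades) {
    status <- "rejected:high-paraphyly"
  }
  out <- list(epoc_id = epoc_id, tree = tree, alignment = alignment,
              taxonomy = taxonomy, euk_clades = euk, prok_clades = prok,
              annotations = annotations, status = status)
  class(out) <- "epoc"
  out
}

#' @export
print.epoc <- function(x, ...) {
  cat("EPOC", x$epoc_id, "-", x$status, "\n")
  cat("  leaves:", length(x$tree$tip.label),
      "| euk clades:", length(x$euk_clades),
      "| prok clades:", length(x$prok_clades), "\n")
  if (length(x$annotations)) {
    cat("  annotations:", paste(x$annotations, collapse = ", "), "\n")
  }
  invisible(x)
}
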
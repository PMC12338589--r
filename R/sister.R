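#' Enumerate candidate prokaryotic sister clades
#'
#' Ranks the prokaryotic clade calls of an accepted EPOC by topological
#' distance from the given eukaryotic clade root (ascending) and returns the
#' first `max_candidates`. Constrained-tree evaluation scales with the
#' number of hypotheses, so only the closest clades are tested. Ties are
#' broken by larger clade size, then lexically by label.
#'
#' @param epoc an accepted [assemble_epoc()] object.
#' @param euk_clade one of `epoc$euk_clades`.
#' @param max_candidates maximum hypotheses (default 12).
#' @return list of prokaryotic clade calls, closest first.
#' @export
enumerate_hypotheses <- function(epoc, euk_clade, max_candidates = 12L) {
  if (length(epoc$prok_clades) == 0L) stop("no prokaryotic clades")
  d <- vapply(epoc$prok_clades, function(cl) {
    topo_distance(epoc$tree, euk_clade$node, cl$node)
  }, numeric(1))
  sz <- vapply(epoc$prok_clades, function(cl) cl$clade_size, numeric(1))
  lab <- vapply(epoc$prok_clades, function(cl) cl$label, character(1))
  ord <- order(d, -sz, lab)
  epoc$prok_clades[ord][seq_len(min(max_candidates, length(ord)))]
}

#' Build a constrained topology for a sister hypothesis
#'
#' Produces the tree in which the eukaryotic clade and one candidate
#' prokaryotic sister are siblings while all remaining leaves keep the
#' master tree's internal arrangement: the eukaryotic subtree is pruned and
#' regrafted onto the midpoint of the candidate's stem. Three groups are
#' thereby enforced: the eukaryotic clade, the candidate sister, and
#' everything else. The leaf set is identical to the master's.
#'
#' @param master rooted `ape::phylo`.
#' @param euk_clade,sister clade calls with disjoint member sets present in
#'   `master`.
#' @return list with `tree` (the constrained topology) and `opt_edges`
#'   (indices of edges altered by the regraft, the natural targets for
#'   branch-length re-optimization).
#' @export
build_constrained_topology <- function(master, euk_clade, sister) {
  euk <- euk_clade$members
  sis <- sister$members
  if (length(intersect(euk, sis))) stop("overlapping clades")
  stopifnot(all(euk %in% master$tip.label), all(sis %in% master$tip.label))

  ntip <- length(master$tip.label)
  euk_node <- if (length(euk) == 1L) match(euk, master$tip.label) else
    ape::getMRCA(master, euk)
  euk_sub <- if (length(euk) == 1L) {
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = euk,
                   edge.length = 0, Nnode = 1L), class = "phylo")
  } else {
    ape::extract.clade(master, euk_node)
  }
  stem_edge <- which(master$edge[, 2] == euk_node)
  stem_len <- if (length(stem_edge) == 1L) master$edge.length[stem_edge]
              else 0.1
  # former neighbourhood of the eukaryotic clade, for the healed edge
  parent_node <- if (length(stem_edge) == 1L) master$edge[stem_edge, 1] else NA
  sib_leaves <- if (!is.na(parent_node)) {
    setdiff(master$tip.label[unlist(phangorn::Descendants(master, parent_node,
                                                          "tips"))], euk)
  } else character(0)

  reduced <- ape::drop.tip(master, euk)
  where <- if (length(sis) == 1L) match(sis, reduced$tip.label) else
    ape::getMRCA(reduced, sis)
  sis_stem <- which(reduced$edge[, 2] == where)
  pos <- if (length(sis_stem) == 1L) reduced$edge.length[sis_stem] / 2 else 0
  euk_sub$root.edge <- stem_len
  out <- ape::bind.tree(reduced, euk_sub, where = where, position = pos)
  out <- stats::reorder(out, "cladewise")

  # edges altered by prune+regraft: the eukaryotic stem, the two halves of
  # the split sister stem, and the healed edge at the former position
  find_edge <- function(leafset) {
    leafset <- intersect(leafset, out$tip.label)
    if (length(leafset) == 0L) return(integer(0))
    node <- if (length(leafset) == 1L) match(leafset, out$tip.label) else
      ape::getMRCA(out, leafset)
    which(out$edge[, 2] == node)
  }
  euk_new <- find_edge(euk)
  sis_new <- find_edge(sis)
  joint_new <- find_edge(c(euk, sis))
  healed <- if (length(sib_leaves)) find_edge(sib_leaves) else integer(0)
  opt_edges <- sort(unique(c(euk_new, sis_new, joint_new, healed)))
  list(tree = out, opt_edges = opt_edges)
}

#' Per-site log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of every alignment column on a fixed tree
#' under a time-reversible amino-acid model, by the standard postorder
#' pruning recursion with per-node scaling. Gaps and non-standard residues
#' are treated as missing data (partial likelihood 1 for all states).
#' Natural-log convention.
#'
#' @param tree rooted `ape::phylo` with branch lengths; every leaf must have
#'   a row in `aln`.
#' @param aln an `aa_alignment`.
#' @param model a [subst_model()].
#' @return numeric vector of per-site log-likelihoods (nats).
#' @export
site_loglik <- function(tree, aln, model) {
  prep <- ll_prepare(tree, aln, model)
  ll_eval(prep, tree$edge.length)
}

# Precompute the postorder structure and tip partial likelihoods once so
# branch-length optimization can re-evaluate cheaply.
ll_prepare <- function(tree, aln, model) {
  m <- unclass(aln)
  missing_rows <- setdiff(tree$tip.label, rownames(m))
  if (length(missing_rows)) {
    stop("leaf without sequence: ",
         paste(utils::head(missing_rows), collapse = ", "))
  }
  nsites <- ncol(m)
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  # permutation mapping tree edge indices -> postorder edge rows
  key <- function(e) paste(e[, 1], e[, 2])
  perm <- match(key(po$edge), key(tree$edge))

  tip_partial <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    idx <- match(m[tree$tip.label[i], ], AA20)
    M <- matrix(0, 20, nsites)
    known <- which(!is.na(idx))
    M[cbind(idx[known], known)] <- 1
    M[, setdiff(seq_len(nsites), known)] <- 1   # gaps: missing data
    tip_partial[[i]] <- M
  }
  list(po_edge = po$edge, perm = perm, ntip = ntip, nnode = tree$Nnode,
       nsites = nsites, tip_partial = tip_partial, model = model,
       internal_nodes = unique(po$edge[, 1]),
       children_of = split(seq_len(nrow(po$edge)), po$edge[, 1]))
}

ll_eval <- function(prep, edge_length) {
  el <- edge_length[prep$perm]
  ntip <- prep$ntip
  model <- prep$model
  partial <- vector("list", ntip + prep$nnode)
  partial[seq_len(ntip)] <- prep$tip_partial
  logscale <- numeric(prep$nsites)
  for (p in prep$internal_nodes) {        # postorder: children before parents
    M <- NULL
    for (e in prep$children_of[[as.character(p)]]) {
      ch <- prep$po_edge[e, 2]
      P <- prob_matrix(model, el[e])
      C <- P %*% partial[[ch]]
      M <- if (is.null(M)) C else M * C
    }
    sc <- colSums(M)              # column scaling against underflow
    sc[sc <= 0] <- 1
    partial[[p]] <- M / rep(sc, each = 20)
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  log(colSums(model$bf * partial[[root]])) + logscale
}

#' Re-optimize branch lengths on a fixed topology
#'
#' Maximizes the tree log-likelihood over individual branch lengths by
#' bounded one-dimensional (Brent/golden-section) search, holding the
#' topology and all other branches fixed, cycling over the target edges for
#' a fixed number of passes. This is the fixed-topology analogue of a
#' constrained maximum-likelihood search: after a regraft only the edges the
#' regraft touched need refreshing, so those are the default targets.
#'
#' @param tree `ape::phylo`.
#' @param aln an `aa_alignment`.
#' @param model a [subst_model()].
#' @param edges integer edge indices to optimize; default all edges.
#' @param passes sweeps over the edge set (default 2).
#' @param upper upper bound for any branch length (default 10).
#' @param tol convergence tolerance of the univariate search (default 1e-4).
#' @return list with `tree` (updated branch lengths) and `loglik`.
#' @export
reopt_branches <- function(tree, aln, model, edges = NULL, passes = 2L,
                           upper = 10, tol = 1e-4) {
  if (is.null(edges)) edges <- seq_len(nrow(tree$edge))
  prep <- ll_prepare(tree, aln, model)
  el <- tree$edge.length
  for (pass in seq_len(passes)) {
    for (e in edges) {
      f <- function(x) {
        el[e] <- x
        sum(ll_eval(prep, el))
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = tol)
      el[e] <- opt$maximum
    }
  }
  tree$edge.length <- el
  list(tree = tree, loglik = sum(ll_eval(prep, el)))
}

#' Expected Likelihood Weights by RELL bootstrap
#'
#' Given per-site log-likelihoods of competing (constrained) topologies,
#' resamples site indices with replacement (`n_boot` replicates), computes
#' each hypothesis's replicate total log-likelihood, converts the totals to
#' likelihood weights `exp(LL_h - max) / sum(exp(...))`, and averages the
#' weights over replicates. The resulting Expected Likelihood Weights lie in
#' `[0, 1]` and sum to 1 over hypotheses; per-site log-likelihoods are
#' reused across replicates (no re-optimization).
#'
#' @param site_ll matrix of per-site log-likelihoods (nats), one row per
#'   hypothesis, with rownames identifying hypotheses.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return named numeric vector of ELW values, one per hypothesis.
#' @export
rell_elw <- function(site_ll, n_boot = 1000L, seed = 1L) {
  site_ll <- rbind(site_ll)
  if (nrow(site_ll) < 1L || ncol(site_ll) < 1L) {
    stop("need >= 1 hypothesis and >= 1 site")
  }
  if (!all(is.finite(site_ll))) stop("non-finite log-likelihoods")
  nsites <- ncol(site_ll)
  set.seed(seed)
  counts <- stats::rmultinom(n_boot, nsites, rep(1 / nsites, nsites))
  tot <- site_ll %*% counts
  w <- exp(sweep(tot, 2, apply(tot, 2, max)))
  w <- sweep(w, 2, colSums(w), "/")
  elw <- rowMeans(w)
  if (is.null(rownames(site_ll))) names(elw) <- paste0("h", seq_along(elw))
  elw
}

#' Score all candidate sisters of an EPOC by ELW
#'
#' For every detected eukaryotic clade of an accepted EPOC, enumerates the
#' closest prokaryotic clades, builds each constrained topology, refreshes
#' the regraft-affected branch lengths, computes per-site log-likelihoods,
#' and converts them to Expected Likelihood Weights by RELL bootstrap.
#' Candidates whose member set overlaps the eukaryotic clade (soft-LCA
#' impurities) cannot form a constraint and are skipped.
#'
#' @param epoc an accepted [assemble_epoc()] object.
#' @param model a [subst_model()] (default equal-rates).
#' @param max_candidates maximum hypotheses per eukaryotic clade (default 12).
#' @param n_boot RELL replicates (default 1000).
#' @param seed integer seed.
#' @param reopt "local" (default; regraft-affected edges), "none", or "all".
#' @param passes optimization sweeps (default 2).
#' @return data.frame of class `elw_table` with columns `epoc_id`,
#'   `euk_clade_id`, `candidate_label`, `candidate_node`, `elw`, `topo_dist`,
#'   `total_ll`. ELW sums to 1 within each (epoc_id, euk_clade_id).
#' @export
score_sisters <- function(epoc, model = subst_model("eq20"),
                          max_candidates = 12L, n_boot = 1000L, seed = 1L,
                          reopt = c("local", "none", "all"), passes = 2L) {
  reopt <- match.arg(reopt)
  if (epoc$status != "accepted") stop("EPOC not accepted: ", epoc$status)
  rows <- list()
  for (i in seq_along(epoc$euk_clades)) {
    euk <- epoc$euk_clades[[i]]
    cands <- enumerate_hypotheses(epoc, euk, max_candidates)
    keep <- vapply(cands, function(cl) {
      length(intersect(cl$members, euk$members)) == 0L
    }, logical(1))
    cands <- cands[keep]
    if (length(cands) == 0L) next
    site_ll <- matrix(NA_real_, length(cands), ncol(epoc$alignment))
    tdist <- numeric(length(cands))
    for (j in seq_along(cands)) {
      ct <- build_constrained_topology(epoc$tree, euk, cands[[j]])
      tr <- ct$tree
      if (reopt != "none") {
        edges <- if (reopt == "all") NULL else ct$opt_edges
        tr <- reopt_branches(tr, epoc$alignment, model, edges = edges,
                             passes = passes)$tree
      }
      site_ll[j, ] <- site_loglik(tr, epoc$alignment, model)
      tdist[j] <- topo_distance(epoc$tree, euk$node, cands[[j]]$node)
    }
    rownames(site_ll) <- paste0("h", seq_along(cands))
    elw <- rell_elw(site_ll, n_boot = n_boot,
                    seed = stage_seed(seed, paste0("rell_", epoc$epoc_id,
                                                   "_e", i)))
    rows[[length(rows) + 1L]] <- data.frame(
      epoc_id = epoc$epoc_id,
      euk_clade_id = paste0("e", i),
      candidate_label = vapply(cands, function(cl) cl$label, character(1)),
      candidate_node = vapply(cands, function(cl) cl$node, numeric(1)),
      elw = as.numeric(elw),
      topo_dist = tdist,
      total_ll = rowSums(site_ll),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoc_id = character(0), euk_clade_id = character(0),
               candidate_label = character(0), candidate_node = numeric(0),
               elw = numeric(0), topo_dist = numeric(0),
               total_ll = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("elw_table", "data.frame")
  out
}
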
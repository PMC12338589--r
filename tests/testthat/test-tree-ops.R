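test_that("long-branch pruning removes quantile exceedances and flags discards", {
  # zero-variance guard: all branch lengths equal -> degenerate fit, no pruning
  tr <- ape::rtree(10)
  tr$edge.length <- rep(1, nrow(tr$edge))
  res <- prune_branch_outliers(tr)
  expect_true(res$report$degenerate_fit)
  expect_length(res$report$removed_leaves, 0)
  expect_equal(ape::Ntip(res$tree), 10)

  # one enormous branch among log-normal(0,1) draws is removed; oracle
  # recomputes the MLE quantile independently and flags exceedances
  set.seed(101)
  tr <- ape::rtree(51)   # 100 edges
  tr$edge.length <- stats::rlnorm(nrow(tr$edge), 0, 1)
  victim_edge <- which(tr$edge[, 2] <= 51)[5]
  tr$edge.length[victim_edge] <- exp(10)
  res <- prune_branch_outliers(tr)
  lx <- log(tr$edge.length)
  cut_oracle <- exp(mean(lx) + sqrt(mean((lx - mean(lx))^2)) *
                      stats::qnorm(0.995))
  flagged_oracle <- tr$edge.length > cut_oracle
  expect_equal(res$report$upper_cutoff, cut_oracle, tolerance = 1e-12)
  victim <- tr$tip.label[tr$edge[victim_edge, 2]]
  expect_true(victim %in% res$report$removed_leaves)
  expect_true(flagged_oracle[victim_edge])
  expect_false(victim %in% res$tree$tip.label)

  # one inflated internal branch subtending 4 of 10 leaves: its whole clade
  # is removed, crossing the 30% discard threshold
  set.seed(7)
  tr <- ape::rtree(10)
  tr$edge.length <- stats::rlnorm(nrow(tr$edge), 0, 0.5)
  clade_sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    ch <- tr$edge[e, 2]
    if (ch <= 10) 1L else length(phangorn::Descendants(tr, ch, "tips")[[1]])
  }, integer(1))
  victim <- which(clade_sizes == 4)[1]
  tr$edge.length[victim] <- exp(10)
  res <- prune_branch_outliers(tr)
  expect_length(res$report$removed_leaves, 4)
  expect_length(res$report$removed_clades, 1)
  expect_true(res$report$discarded)
  expect_equal(res$report$discard_reason, "over-30-percent-removed")

  # losing every eukaryotic leaf discards regardless of fraction
  sim <- simulate_epoc(sim_config(seed = 2, n_euk_leaves = 5,
                                  prok_clades = c(Asgard = 20,
                                                  Cyanobacteria = 20),
                                  n_sites = 10))
  tr <- sim$tree
  stem <- which(tr$edge[, 2] == ape::getMRCA(tr, sim$truth$euk_leaves))
  tr$edge.length[stem] <- exp(10)
  res <- prune_branch_outliers(tr, taxonomy = sim$taxonomy)
  expect_equal(res$report$discard_reason, "all-eukaryotes-removed")
  expect_true(res$report$discarded)
})

test_that("weighted midpoint rooting balances the side sums", {
  # two-leaf tree with branches 3 and 1: root lands 2 from each leaf
  tr <- ape::read.tree(text = "(A:3,B:1);")
  r <- weighted_midpoint_root(tr)
  d <- ape::node.depth.edgelength(r)
  expect_equal(d[1:2], c(2, 2))

  # symmetric tree: root stays at the centre
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  expect_equal(unname(root_side_sums(weighted_midpoint_root(tr))),
               c(4, 4))

  # caterpillar: same balance as an exhaustive edge/position scan
  tr <- ape::read.tree(text = "(((((A:1,B:2):3,C:4):5,D:6):7,E:8):9,F:1);")
  r <- weighted_midpoint_root(tr)
  mine <- abs(diff(root_side_sums(r)))
  brute <- Inf
  for (e in seq_len(nrow(tr$edge))) {
    L <- tr$edge.length[e]
    for (x in seq(0, L, length.out = 2001)) {
      t2 <- phytools::reroot(tr, tr$edge[e, 2], position = L - x)
      brute <- min(brute, abs(diff(root_side_sums(t2))))
    }
  }
  expect_lte(mine, brute + 1e-9)

  # interior balance points are exact, on random trees
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(12)
    r <- weighted_midpoint_root(tr)
    ss <- root_side_sums(r)
    if (all(r$edge.length[r$edge[, 1] == ape::Ntip(r) + 1] > 1e-12)) {
      expect_lte(abs(diff(ss)), 1e-9 * sum(tr$edge.length))
    }
    expect_setequal(r$tip.label, tr$tip.label)
    expect_true(all(r$edge.length >= 0))
  }
})

test_that("topological distance counts non-root bifurcations between nodes", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  ab <- ape::getMRCA(tr, c("A", "B"))
  cd <- ape::getMRCA(tr, c("C", "D"))
  ef <- ape::getMRCA(tr, c("E", "F"))
  expect_equal(topo_distance(tr, ab, cd), 1)   # siblings, parent not root
  expect_equal(topo_distance(tr, ab, ab), 0)
  expect_equal(topo_distance(tr, ab, ef), 1)   # path crosses only the root + 1
  expect_equal(topo_distance(tr, "A", "B"), 1)
  expect_error(topo_distance(tr, "A", "nope"), "not found")

  # BFS oracle on random trees
  bfs_oracle <- function(tree, a, b) {
    ntip <- ape::Ntip(tree)
    adj <- lapply(seq_len(max(tree$edge)), function(i) integer(0))
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
      adj[[p]] <- c(adj[[p]], ch); adj[[ch]] <- c(adj[[ch]], p)
    }
    prev <- rep(NA_integer_, max(tree$edge))
    prev[a] <- a
    queue <- a
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      if (nd == b) break
      for (nb in adj[[nd]]) if (is.na(prev[nb])) {
        prev[nb] <- nd; queue <- c(queue, nb)
      }
    }
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    interior <- path[-c(1, length(path))]
    sum(interior > ntip & interior != ntip + 1L)
  }
  set.seed(20)
  tr <- ape::rtree(20)
  for (i in 1:100) {
    pair <- sample(max(tr$edge), 2)
    expect_equal(topo_distance(tr, pair[1], pair[2]),
                 bfs_oracle(tr, pair[1], pair[2]))
    expect_equal(topo_distance(tr, pair[2], pair[1]),
                 topo_distance(tr, pair[1], pair[2]))
  }
})

test_that("taxonomy-aware subsampling prunes label-monophyletic pairs first", {
  # target above current size: unchanged
  sim <- simulate_epoc(sim_config(seed = 1, n_sites = 10))
  tax <- sim$taxonomy
  res <- taxonomy_aware_subsample(sim$tree, tax, 100)
  expect_setequal(res$leaves, sim$tree$tip.label)

  # same-label cherry: survivor is the leaf closest to the root
  tr <- ape::read.tree(text = "((L1:0.1,L2:0.3):0.3,(M1:0.2,X1:0.2):0.4);")
  tax <- taxonomy_table(c("L1", "L2", "M1", "X1"), "prokaryote",
                        c("Lab", "Lab", "Mab", "Xab"), paste0("s", 1:4))
  res <- taxonomy_aware_subsample(tr, tax, 3)
  expect_setequal(res$leaves, c("L1", "M1", "X1"))
  expect_equal(res$pruned_counts[["L1"]], 1L)

  # three monophyletic labels, target = label count: one survivor per label,
  # and the greedy sequence matches an explicit re-simulation of the rule
  nwk <- paste0("(((A1:0.1,A2:0.2):0.1,A3:0.3):0.5,",
                "((B1:0.1,B2:0.15):0.2,B3:0.4):0.5,",
                "((C1:0.05,C2:0.1):0.3,C3:0.2):0.5);")
  tr <- ape::read.tree(text = nwk)
  tax <- taxonomy_table(tr$tip.label, "prokaryote",
                        sub("[0-9]$", "", tr$tip.label), tr$tip.label)
  res <- taxonomy_aware_subsample(tr, tax, 3)
  expect_length(res$leaves, 3)
  expect_setequal(sub("[0-9]$", "", res$leaves), c("A", "B", "C"))
  # every survivor accumulated its clade's two pruned relatives
  expect_true(all(res$pruned_counts[res$leaves] == 2L))
})

test_that("supercluster partitioning recovers planted clades, else one group", {
  make_planted <- function(k, n = 20, seed = 1) {
    set.seed(seed)
    cls <- lapply(seq_len(k), function(i) {
      t <- ape::rcoal(n)
      t$edge.length <- t$edge.length /
        max(ape::node.depth.edgelength(t)) * 0.1
      t$tip.label <- paste0("c", i, "_", seq_len(n))
      t
    })
    bb <- if (k == 2) "(BB1:5,BB2:5);" else "((BB1:5,BB2:5):5,BB3:5);"
    epocr:::graft_clades(ape::read.tree(text = bb), cls)
  }
  for (k in 2:3) {
    tr <- make_planted(k, seed = k)
    g <- partition_supercluster(tr)
    expect_equal(length(unique(g)), k)
    for (gg in unique(g)) {
      members <- names(g)[g == gg]
      # each group is one planted clade, hence a connected subtree
      expect_length(unique(sub("_.*", "", members)), 1)
      mrca_tips <- phangorn::Descendants(tr, ape::getMRCA(tr, members),
                                         "tips")[[1]]
      expect_setequal(tr$tip.label[mrca_tips], members)
    }
  }
  # homogeneous random trees stay in a single partition
  for (s in 1:5) {
    set.seed(s)
    tr <- ape::rtree(30)
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    expect_equal(length(unique(partition_supercluster(tr))), 1)
  }
  # below the embedding neighbourhood: single partition fallback
  small <- ape::rtree(5)
  expect_equal(unique(partition_supercluster(small)), 1L)
})
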
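# Shared fixture builders. Everything is generated in code; no data files.

# prokaryote-only taxonomy: one label per `sizes` entry, one species per seq
prok_taxonomy <- function(sizes, labels = names(sizes)) {
  ids <- unlist(lapply(seq_along(sizes), function(i) {
    paste0(labels[i], "_", seq_len(sizes[i]))
  }))
  taxonomy_table(ids, "prokaryote", sub("_[0-9]+$", "", ids), ids)
}

# taxonomy for an arbitrary set of leaf names following the simulator's
# "<Label>_<i>" convention, with eukaryote labels drawn from the default set
leaf_taxonomy <- function(tips) {
  euk_labels <- c("Metazoa", "Fungi", "Amoebozoa", "Choanoflagellata",
                  "Streptophyta", "Chlorophyta", "Stramenopiles", "Alveolata")
  lab <- sub("_[0-9]+$", "", tips)
  is_euk <- lab %in% euk_labels
  sg <- ifelse(lab %in% euk_labels[1:4], "Amorphea",
               ifelse(lab %in% euk_labels[5:8], "Diaphoretickes", NA))
  taxonomy_table(tips, ifelse(is_euk, "eukaryote", "prokaryote"),
                 lab, tips, sg)
}

# independent side-sum computation for rooting oracles: total branch length
# in each of the two subtrees hanging off the root (root edges included)
root_side_sums <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ch <- tree$edge[tree$edge[, 1] == root, 2]
  # accumulate subtree sums by breadth-first expansion from each root child
  adj <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  subtree_sum <- function(node) {
    tot <- 0
    queue <- node
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      for (e in adj[[as.character(nd)]]) {
        tot <- tot + tree$edge.length[e]
        queue <- c(queue, tree$edge[e, 2])
      }
    }
    tot
  }
  vapply(ch, function(c2) {
    subtree_sum(c2) + tree$edge.length[match(c2, tree$edge[, 2])]
  }, numeric(1))
}

# alignment with an exact number of informative columns: `n_pass` pure
# columns (> 0.15 bits) among `n_total`, the rest uniform over the 20
# residues (0 bits); 20 rows
engineered_alignment <- function(n_total = 100, n_pass = 37, seed = 5) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  pass_cols <- sort(sample(n_total, n_pass))
  m <- matrix("", nrow = 20, ncol = n_total,
              dimnames = list(paste0("s", 1:20), NULL))
  for (j in seq_len(n_total)) {
    m[, j] <- if (j %in% pass_cols) rep(sample(aa, 1), 20) else sample(aa)
  }
  list(aln = as_alignment(m), pass_cols = pass_cols)
}

# hand-built EPOC-like object sufficient for core_filter / aelw tests
stub_epoc <- function(epoc_id, annotations = "cat", n_labels = 6) {
  euk_labels <- c("Metazoa", "Fungi", "Amoebozoa", "Choanoflagellata",
                  "Streptophyta", "Chlorophyta", "Stramenopiles",
                  "Alveolata")[seq_len(n_labels)]
  ids <- paste0(epoc_id, "_e", seq_along(euk_labels))
  sg <- ifelse(euk_labels %in% c("Metazoa", "Fungi", "Amoebozoa",
                                 "Choanoflagellata"),
               "Amorphea", "Diaphoretickes")
  tax <- taxonomy_table(ids, "eukaryote", euk_labels, ids, sg)
  structure(list(epoc_id = epoc_id, taxonomy = tax,
                 euk_clades = list(list(node = NA, label = "eukaryote",
                                        domain = "eukaryotic",
                                        members = ids,
                                        clade_size = length(ids),
                                        n_label = length(ids), purity = 1,
                                        score = 1)),
                 prok_clades = list(), annotations = annotations,
                 status = "accepted"),
            class = "epoc")
}

# a processed, accepted EPOC from the simulator (rooted, clades detected)
sim_accepted_epoc <- function(seed = 3, n_sites = 300, ...) {
  sim <- simulate_epoc(sim_config(seed = seed, n_sites = n_sites, ...))
  tr <- weighted_midpoint_root(sim$tree)
  calls <- detect_clades(tr, sim$taxonomy)
  ep <- assemble_epoc(tr, sim$alignment, calls, sim$taxonomy,
                      epoc_id = paste0("sim", seed))
  list(epoc = ep, sim = sim)
}

# tree with four well-separated eukaryotic clades (high paraphyly) plus two
# prokaryotic clades, with matching taxonomy and a short alignment
paraphyletic_input <- function(seed, n_per_clade = 5) {
  set.seed(seed)
  euk_labels <- c("Metazoa", "Fungi", "Streptophyta", "Alveolata")
  parts <- character(6)
  mk <- function(prefix, n) {
    tips <- paste0(prefix, "_", seq_len(n), ":0.1")
    paste0("(", paste(tips, collapse = ","), ")")
  }
  # each eukaryotic group is separated by a prokaryotic neighbour, so four
  # eukaryotic clades are detected (high paraphyly)
  nwk <- paste0("(((", mk("Metazoa", n_per_clade), ":0.5,",
                mk("Asgard", n_per_clade), ":0.5):0.2,(",
                mk("Fungi", n_per_clade), ":0.5,",
                mk("Cyanobacteria", n_per_clade), ":0.5):0.2):0.2,((",
                mk("Streptophyta", n_per_clade), ":0.5,",
                mk("Alphaproteobacteria", n_per_clade), ":0.5):0.2,(",
                mk("Alveolata", n_per_clade), ":0.5,",
                mk("Nitrososphaeria", n_per_clade), ":0.5):0.2):0.2);")
  tree <- ape::read.tree(text = nwk)
  tax <- leaf_taxonomy(tree$tip.label)
  aln <- simulate_alignment(tree, 60, "eq20")
  list(tree = tree, alignment = aln, taxonomy = tax,
       annotations = "cat", epoc_id = paste0("para", seed))
}

# exact ELW by enumerating every site-count vector of the multinomial
# bootstrap (independent oracle for small site counts)
enumerate_elw <- function(site_ll) {
  S <- ncol(site_ll)
  H <- nrow(site_ll)
  counts <- as.matrix(expand.grid(rep(list(0:S), S)))
  counts <- counts[rowSums(counts) == S, , drop = FALSE]
  probs <- apply(counts, 1, function(k) {
    exp(lgamma(S + 1) - sum(lgamma(k + 1)) + sum(k * log(1 / S)))
  })
  elw <- numeric(H)
  for (i in seq_len(nrow(counts))) {
    tot <- as.numeric(site_ll %*% counts[i, ])
    w <- exp(tot - max(tot))
    elw <- elw + probs[i] * w / sum(w)
  }
  as.numeric(elw)
}

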
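#' Default eukaryotic class labels used by the simulator
#'
#' Eight curated class labels spanning the two deepest eukaryotic
#' supergroups, four from Amorphea and four from Diaphoretickes, so that a
#' simulated eukaryotic clade of >= 7 leaves passes the LECA scope check
#' (more than 5 distinct labels, both supergroups present).
#' @keywords internal
euk_label_set <- function() {
  data.frame(
    class_label = c("Metazoa", "Fungi", "Amoebozoa", "Choanoflagellata",
                    "Streptophyta", "Chlorophyta", "Stramenopiles",
                    "Alveolata"),
    supergroup = c(rep("Amorphea", 4), rep("Diaphoretickes", 4)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for one synthetic EPOC
#'
#' Defines the study conditions for a planted eukaryotic-prokaryotic
#' orthologous cluster: one monophyletic eukaryotic clade attached by a stem
#' of known length to a known ("true") prokaryotic sister clade, among other
#' labelled prokaryotic clades, with an alignment evolved along the tree.
#' Optional noise processes plant horizontal-transfer-like leaves (a
#' prokaryotic leaf relabelled with an off-clade label) and long-branch
#' outliers (terminal branches inflated by a known factor).
#'
#' @param seed integer seed; all draws flow from per-stage generators
#'   derived from it, so e.g. the pre-inflation tree of a run with
#'   `outlier_count = 0` is identical to the inflated run's base tree.
#' @param n_euk_leaves leaves in the eukaryotic clade (default 10).
#' @param prok_clades named integer vector: leaf count per prokaryotic
#'   class label (default three clades of 8: Asgard, Alphaproteobacteria,
#'   Cyanobacteria).
#' @param true_sister label of the planted sister clade (default "Asgard";
#'   must name an entry of `prok_clades`).
#' @param stem_length stem (FECA to LECA) length in substitutions/site
#'   (default 0.3).
#' @param euk_depth root-to-tip depth of the eukaryotic clade (default 0.3).
#' @param prok_depth root-to-tip depth of each prokaryotic clade
#'   (default `euk_depth`).
#' @param backbone_depth depth of the backbone joining the prokaryotic
#'   clades (default 0.5).
#' @param n_sites alignment columns (default 300).
#' @param substitution_model "eq20" (equal-rates, analytically tractable)
#'   or "lg" (empirical exchangeabilities).
#' @param hgt_leaf_count prokaryotic leaves to relabel with an off-clade
#'   label (default 0).
#' @param outlier_count terminal branches to inflate (default 0).
#' @param outlier_factor multiplier applied to the selected terminal
#'   branches (default 10).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_euk_leaves = 10L,
                       prok_clades = c(Asgard = 8L,
                                       Alphaproteobacteria = 8L,
                                       Cyanobacteria = 8L),
                       true_sister = "Asgard",
                       stem_length = 0.3, euk_depth = 0.3,
                       prok_depth = euk_depth, backbone_depth = 0.5,
                       n_sites = 300L,
                       substitution_model = c("eq20", "lg"),
                       hgt_leaf_count = 0L, outlier_count = 0L,
                       outlier_factor = 10) {
  substitution_model <- match.arg(substitution_model)
  if (is.null(names(prok_clades)) || any(names(prok_clades) == "")) {
    stop("prok_clades must be a named vector of leaf counts")
  }
  if (!true_sister %in% names(prok_clades)) {
    stop("true_sister must be one of the prokaryotic clade labels")
  }
  if (n_euk_leaves < 1L || any(prok_clades < 1L)) {
    stop("every declared clade needs at least one leaf")
  }
  stopifnot(stem_length >= 0, euk_depth >= 0, prok_depth >= 0,
            n_sites >= 1, hgt_leaf_count >= 0, outlier_count >= 0,
            outlier_factor > 0)
  cfg <- list(seed = as.integer(seed), n_euk_leaves = as.integer(n_euk_leaves),
              prok_clades = prok_clades, true_sister = true_sister,
              stem_length = stem_length, euk_depth = euk_depth,
              prok_depth = prok_depth, backbone_depth = backbone_depth,
              n_sites = as.integer(n_sites),
              substitution_model = substitution_model,
              hgt_leaf_count = as.integer(hgt_leaf_count),
              outlier_count = as.integer(outlier_count),
              outlier_factor = outlier_factor)
  class(cfg) <- "sim_config"
  cfg
}

#' Derive a stage-specific seed from a global seed
#'
#' Stable, order-independent seeding: each pipeline stage draws from its own
#' generator seeded by a hash of the stage name and the global seed, so that
#' adding or reordering independent stages cannot change another stage's
#' stream. Result is kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483629
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483629)
}

# replace backbone tips BB1..BBk by whole subtrees, via newick substitution
# (ape::bind.tree cannot bind into 2-tip recipients)
graft_clades <- function(backbone, clades) {
  nwk <- ape::write.tree(backbone)
  for (i in seq_along(clades)) {
    cl <- if (length(clades[[i]]$tip.label) == 1L) {
      paste0("(", clades[[i]]$tip.label, ":", clades[[i]]$edge.length, ")")
    } else {
      sub(";$", "", ape::write.tree(clades[[i]]))
    }
    nwk <- gsub(paste0("([(,])BB", i, ":"), paste0("\\1", cl, ":"), nwk)
  }
  ape::collapse.singles(ape::read.tree(text = nwk))
}

# pure-birth clade scaled to a given root-to-tip depth, tips renamed
random_clade <- function(n, depth, prefix) {
  if (n == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = paste0(prefix, "_1"),
               edge.length = depth, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::rphylo(n, birth = 1, death = 0)
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / d * depth
  tr$tip.label <- paste0(prefix, "_", seq_len(n))
  tr
}

#' Simulate one EPOC: tree, alignment, taxonomy and truth record
#'
#' Builds a gene tree containing the planted eukaryotic clade attached as
#' sister to `true_sister` via a stem of length `stem_length`, evolves an
#' alignment along it under the configured substitution model, and emits the
#' taxonomy table resolving every leaf plus a truth record for downstream
#' recovery tests. Within-clade topologies are pure-birth; the prokaryotic
#' clades hang off a pure-birth backbone. Identical configuration (same
#' seed) reproduces the output exactly.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (`ape::phylo`), `alignment` (`aa_alignment`),
#'   `taxonomy` (`taxonomy_table`) and `truth` (list: `epoc_id`,
#'   `true_sister`, `true_stem_length`, `euk_leaves`, `sister_leaves`,
#'   `injected_outlier_leaves`, `injected_hgt_leaves`).
#' @export
simulate_epoc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$prok_clades)
  labels <- names(config$prok_clades)

  ## stage: tree
  set.seed(stage_seed(config$seed, "tree"))
  clades <- lapply(seq_len(k), function(i) {
    random_clade(config$prok_clades[[i]], config$prok_depth, labels[i])
  })
  if (k == 1L) {
    tree <- clades[[1L]]
  } else {
    backbone <- ape::rphylo(k, birth = 1, death = 0)
    bd <- max(ape::node.depth.edgelength(backbone))
    backbone$edge.length <- backbone$edge.length / bd * config$backbone_depth
    backbone$tip.label <- paste0("BB", seq_len(k))
    tree <- graft_clades(backbone, clades)
  }
  euk <- random_clade(config$n_euk_leaves, config$euk_depth, "Euk")
  euk$root.edge <- config$stem_length
  # graft the eukaryotic clade onto the midpoint of the sister clade's stem
  sister_tips <- grep(paste0("^", config$true_sister, "_"), tree$tip.label,
                      value = TRUE)
  if (length(sister_tips) == 1L) {
    where <- match(sister_tips, tree$tip.label)
  } else {
    where <- ape::getMRCA(tree, sister_tips)
  }
  stem_edge <- which(tree$edge[, 2] == where)
  pos <- if (length(stem_edge) == 1L) tree$edge.length[stem_edge] / 2 else 0
  tree <- ape::bind.tree(tree, euk, where = where, position = pos)
  tree <- stats::reorder(ape::as.phylo(tree), "cladewise")

  ## stage: labels (taxonomy + optional HGT relabelling)
  set.seed(stage_seed(config$seed, "labels"))
  tips <- tree$tip.label
  is_euk <- startsWith(tips, "Euk_")
  elab <- euk_label_set()
  euk_idx <- which(is_euk)
  euk_class <- elab$class_label[(seq_along(euk_idx) - 1L) %% nrow(elab) + 1L]
  euk_sg <- elab$supergroup[match(euk_class, elab$class_label)]
  class_label <- character(length(tips))
  supergroup <- rep(NA_character_, length(tips))
  class_label[euk_idx] <- euk_class
  supergroup[euk_idx] <- euk_sg
  prok_idx <- which(!is_euk)
  class_label[prok_idx] <- sub("_[0-9]+$", "", tips[prok_idx])
  hgt_leaves <- character(0)
  if (config$hgt_leaf_count > 0L && length(prok_idx) > 1L && k > 1L) {
    pick <- sample(prok_idx, min(config$hgt_leaf_count, length(prok_idx)))
    for (i in pick) {
      off <- setdiff(labels, class_label[i])
      class_label[i] <- off[sample.int(length(off), 1L)]
    }
    hgt_leaves <- tips[pick]
  }
  taxonomy <- taxonomy_table(
    seq_id = tips,
    domain = ifelse(is_euk, "eukaryote", "prokaryote"),
    class_label = class_label,
    species_id = tips,
    supergroup = supergroup)

  ## stage: outliers (terminal-branch inflation after the base tree is fixed)
  set.seed(stage_seed(config$seed, "outliers"))
  outlier_leaves <- character(0)
  if (config$outlier_count > 0L) {
    ntip <- length(tips)
    term_edges <- which(tree$edge[, 2] <= ntip)
    pick <- sample(term_edges, min(config$outlier_count, length(term_edges)))
    tree$edge.length[pick] <- tree$edge.length[pick] * config$outlier_factor
    outlier_leaves <- tips[tree$edge[pick, 2]]
  }

  ## stage: alignment
  set.seed(stage_seed(config$seed, "alignment"))
  alignment <- simulate_alignment(tree, config$n_sites,
                                  config$substitution_model)

  truth <- list(epoc_id = paste0("sim", config$seed),
                true_sister = config$true_sister,
                true_stem_length = config$stem_length,
                euk_leaves = tips[is_euk],
                sister_leaves = sister_tips,
                injected_outlier_leaves = outlier_leaves,
                injected_hgt_leaves = hgt_leaves)
  list(tree = tree, alignment = alignment, taxonomy = taxonomy,
       truth = truth)
}

#' Evolve an amino-acid alignment along a tree
#'
#' Thin wrapper around phangorn's sequence simulator configured for the two
#' package models; no indels, no among-site rate variation.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param n_sites number of columns.
#' @param model "eq20" or "lg".
#' @return an `aa_alignment`.
#' @export
simulate_alignment <- function(tree, n_sites, model = c("eq20", "lg")) {
  model <- match.arg(model)
  if (model == "eq20") {
    dat <- phangorn::simSeq(tree, l = n_sites, type = "AA",
                            bf = rep(1 / 20, 20), Q = rep(1, 190))
  } else {
    dat <- phangorn::simSeq(tree, l = n_sites, type = "AA", model = "LG")
  }
  m <- toupper(as.character(dat))
  as_alignment(m)
}

#' Write a simulated EPOC to plain-text files
#'
#' Emits `<id>.nwk` (newick tree), `<id>.fasta` (alignment), `<id>.tax.tsv`
#' (taxonomy) and `<id>.truth.json` (truth record) under `dir`.
#'
#' @param sim a [simulate_epoc()] result.
#' @param dir output directory, created if needed.
#' @return the four file paths, invisibly.
#' @export
write_epoc_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sim$truth$epoc_id
  paths <- file.path(dir, paste0(id, c(".nwk", ".fasta", ".tax.tsv",
                                       ".truth.json")))
  ape::write.tree(sim$tree, paths[1])
  write_alignment(sim$alignment, paths[2])
  write_taxonomy(sim$taxonomy, paths[3])
  jsonlite::write_json(sim$truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate a cohort of normalized stem-length records
#'
#' Draws `n_per_group` normalized stem lengths (NSL) per group from the
#' stated distribution family and wraps them as stem records, for power and
#' calibration studies of the stem-length statistics. Supported families:
#' "lnorm" (meanlog, sdlog), "gamma" (shape, rate), "norm" (mean, sd;
#' negative draws are rejected and redrawn since NSL >= 0).
#'
#' @param n_per_group records per group.
#' @param nsl_dists named list: group -> `list(family =, params = c(...))`.
#' @param seed integer seed.
#' @return data.frame of class `stem_records` with columns `epoc_id`,
#'   `euk_clade_id`, `sister_label` (the group), `sl`, `median_bl`, `nsl`
#'   (`sl` is `nsl` scaled by a unit `median_bl`).
#' @export
simulate_stem_cohort <- function(n_per_group, nsl_dists, seed = 1L) {
  set.seed(stage_seed(seed, "stem_cohort"))
  if (n_per_group == 0L) {
    out <- data.frame(epoc_id = character(0), euk_clade_id = character(0),
                      sister_label = character(0), sl = numeric(0),
                      median_bl = numeric(0), nsl = numeric(0))
    class(out) <- c("stem_records", "data.frame")
    return(out)
  }
  draw <- function(spec, n) {
    p <- spec$params
    switch(spec$family,
           lnorm = stats::rlnorm(n, p[[1]], p[[2]]),
           gamma = stats::rgamma(n, shape = p[[1]], rate = p[[2]]),
           norm = {
             x <- stats::rnorm(n, p[[1]], p[[2]])
             while (any(x < 0)) {
               x[x < 0] <- stats::rnorm(sum(x < 0), p[[1]], p[[2]])
             }
             x
           },
           stop("unknown distribution family: ", spec$family))
  }
  rows <- lapply(names(nsl_dists), function(g) {
    nsl <- draw(nsl_dists[[g]], n_per_group)
    data.frame(epoc_id = paste0(g, "_", seq_len(n_per_group)),
               euk_clade_id = "e1", sister_label = g,
               sl = nsl, median_bl = 1, nsl = nsl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stem_records", "data.frame")
  out
}
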
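#' Pipeline configuration
#'
#' One object holding every stage threshold, with defaults reproducing the
#' reference analysis constants: subsampling caps of 30 eukaryotic and 70
#' prokaryotic sequences, 0.15-bit alignment trimming, 0.995 upper quantile
#' for long-branch pruning with the 30% discard rule, clade validity sizes
#' 3 (prokaryotic) and 5 (eukaryotic) at purity > 0.8, at most 3 eukaryotic
#' clades, 12 candidate sisters, 1000 RELL replicates, the (0.4, 0.99) core
#' ELW window, and 200 stem bootstrap replicates with the 0.3/0.35 splits.
#'
#' @param seed global integer seed; per-stage streams are derived with
#'   [stage_seed()].
#' @param euk_max,prok_max subsampling caps.
#' @param trim_bits information-content trimming threshold (bits).
#' @param ppf_upper long-branch pruning quantile.
#' @param max_removed_frac discard threshold on removed leaf fraction.
#' @param min_prok,min_euk,purity_min,max_euk_clades clade validity rules.
#' @param max_candidates,n_boot_rell,reopt,model sister-scoring options.
#' @param core core-set filter, a [core_config()].
#' @param min_epocs_category aELW flagging threshold.
#' @param n_boot_stem,split_points stem-statistics options.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, euk_max = 30L, prok_max = 70L,
                            trim_bits = 0.15, ppf_upper = 0.995,
                            max_removed_frac = 0.3,
                            min_prok = 3L, min_euk = 5L, purity_min = 0.8,
                            max_euk_clades = 3L, max_candidates = 12L,
                            n_boot_rell = 1000L,
                            reopt = c("local", "none", "all"),
                            model = c("eq20", "lg"),
                            core = core_config(),
                            min_epocs_category = 20L,
                            n_boot_stem = 200L,
                            split_points = c(0.3, 0.35)) {
  out <- list(seed = as.integer(seed), euk_max = euk_max, prok_max = prok_max,
              trim_bits = trim_bits, ppf_upper = ppf_upper,
              max_removed_frac = max_removed_frac, min_prok = min_prok,
              min_euk = min_euk, purity_min = purity_min,
              max_euk_clades = max_euk_clades,
              max_candidates = max_candidates, n_boot_rell = n_boot_rell,
              reopt = match.arg(reopt), model = match.arg(model),
              core = core, min_epocs_category = min_epocs_category,
              n_boot_stem = n_boot_stem, split_points = split_points)
  class(out) <- "pipeline_config"
  out
}

#' Run the full ancestry-inference pipeline
#'
#' Executes, per input EPOC: taxonomy-aware subsampling to the 30/70 caps,
#' information-content alignment trimming, log-normal long-branch pruning
#' (with discard rules), weighted midpoint rooting, soft-LCA clade
#' detection, EPOC assembly (with rejection rules), and constrained-topology
#' sister scoring by ELW. Afterwards: core-set filtering, aELW aggregation
#' over annotation categories, stem-length extraction for each top-ELW
#' sister, and (given at least two sufficiently large groups) the NSL
#' distribution analysis. Rejections are counted per rule in the manifest.
#' Re-running with the same inputs and config reproduces every artifact.
#'
#' @param inputs list of EPOC inputs; each element a list with `tree`
#'   (`ape::phylo`), `alignment` (`aa_alignment`), `taxonomy`
#'   (`taxonomy_table`), optional `annotations` (character) and `epoc_id`.
#'   [simulate_epoc()] outputs can be passed directly (the truth record is
#'   ignored).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for per-stage artifacts (ELW and stem
#'   TSVs, manifest JSON).
#' @return list of class `pipeline_manifest`: `seed`, `counts` (named
#'   rejection/acceptance counts), `epocs` (processed `epoc` objects),
#'   `elw` (`elw_table`), `core` (filtered table), `aelw`, `stems`
#'   (`stem_records`), `stem_analysis` (or NULL), `prune_reports`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  model <- subst_model(config$model)
  counts <- c(input = length(inputs),
              `discarded:outlier-pruning` = 0L,
              `rejected:no-eukaryotic-clade` = 0L,
              `rejected:no-prokaryotic-clade` = 0L,
              `rejected:high-paraphyly` = 0L,
              accepted = 0L)
  epocs <- list()
  prune_reports <- list()
  elw_rows <- list()
  annotations_by_id <- list()

  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    epoc_id <- if (!is.null(inp$epoc_id)) inp$epoc_id
               else if (!is.null(inp$truth)) inp$truth$epoc_id
               else paste0("epoc", i)
    ann <- if (!is.null(inp$annotations)) inp$annotations else character(0)
    annotations_by_id[[epoc_id]] <- ann
    tree <- inp$tree
    tax <- inp$taxonomy

    # subsample to the per-domain caps
    euk_leaves <- intersect(tree$tip.label,
                            tax$seq_id[tax$domain == "eukaryote"])
    prok_leaves <- setdiff(tree$tip.label, euk_leaves)
    if (length(euk_leaves) > config$euk_max) {
      tree <- taxonomy_aware_subsample(tree, tax, config$euk_max,
                                       within = euk_leaves)$tree
    }
    prok_leaves <- setdiff(tree$tip.label, euk_leaves)
    if (length(prok_leaves) > config$prok_max) {
      tree <- taxonomy_aware_subsample(tree, tax, config$prok_max,
                                       within = prok_leaves)$tree
    }
    aln <- inp$alignment[intersect(rownames(inp$alignment), tree$tip.label), ,
                         drop = FALSE]
    class(aln) <- c("aa_alignment", class(aln))
    aln <- trim_alignment(aln, config$trim_bits)

    pr <- prune_branch_outliers(tree, config$ppf_upper, taxonomy = tax,
                                max_removed_frac = config$max_removed_frac)
    prune_reports[[epoc_id]] <- pr$report
    if (pr$report$discarded) {
      counts["discarded:outlier-pruning"] <-
        counts["discarded:outlier-pruning"] + 1L
      next
    }
    tree <- weighted_midpoint_root(pr$tree)

    calls <- detect_clades(tree, tax, min_prok = config$min_prok,
                           min_euk = config$min_euk,
                           purity_min = config$purity_min)
    ep <- assemble_epoc(tree, aln, calls, tax, epoc_id = epoc_id,
                        annotations = ann,
                        max_euk_clades = config$max_euk_clades)
    epocs[[epoc_id]] <- ep
    if (ep$status != "accepted") {
      counts[ep$status] <- counts[ep$status] + 1L
      next
    }
    counts["accepted"] <- counts["accepted"] + 1L
    elw_rows[[epoc_id]] <- score_sisters(
      ep, model = model, max_candidates = config$max_candidates,
      n_boot = config$n_boot_rell,
      seed = stage_seed(config$seed, paste0("elw_", epoc_id)),
      reopt = config$reopt)
  }

  elw <- if (length(elw_rows)) do.call(rbind, elw_rows) else
    score_sisters_empty()
  rownames(elw) <- NULL
  class(elw) <- c("elw_table", "data.frame")

  core <- core_filter(elw, epocs, config$core)

  grouping <- do.call(rbind, lapply(names(annotations_by_id), function(id) {
    a <- annotations_by_id[[id]]
    if (length(a) == 0L) return(NULL)
    data.frame(epoc_id = id, category = a, stringsAsFactors = FALSE)
  }))
  aelw_tab <- if (!is.null(grouping) && nrow(core) > 0L) {
    aelw(core, grouping, config$min_epocs_category)
  } else NULL

  # stem records from the top-ELW sister of each accepted eukaryotic clade
  stems <- list()
  if (nrow(elw) > 0L) {
    keys <- unique(elw[, c("epoc_id", "euk_clade_id")])
    for (r in seq_len(nrow(keys))) {
      sub <- elw[elw$epoc_id == keys$epoc_id[r] &
                 elw$euk_clade_id == keys$euk_clade_id[r], , drop = FALSE]
      top <- sub[which.max(sub$elw), ]
      ep <- epocs[[top$epoc_id]]
      ei <- as.integer(sub("^e", "", top$euk_clade_id))
      sis <- Filter(function(cl) cl$node == top$candidate_node,
                    ep$prok_clades)[[1]]
      rec <- stem_lengths(ep$tree, ep$euk_clades[[ei]], sis, ep$taxonomy,
                          epoc_id = top$epoc_id,
                          euk_clade_id = top$euk_clade_id)
      if (!is.null(rec)) stems[[length(stems) + 1L]] <- rec
    }
  }
  stems <- if (length(stems)) do.call(rbind, stems) else NULL
  if (!is.null(stems)) class(stems) <- c("stem_records", "data.frame")

  stem_an <- NULL
  if (!is.null(stems)) {
    tab <- table(stems$sister_label)
    if (sum(tab >= 5L) >= 2L) {
      stem_an <- tryCatch(
        suppressWarnings(stem_distribution_analysis(
          stems, n_boot = config$n_boot_stem,
          seed = stage_seed(config$seed, "stem_stats"),
          split_points = config$split_points)),
        error = function(e) NULL)
    }
  }

  manifest <- list(seed = config$seed, config = config, counts = counts,
                   epocs = epocs, elw = elw, core = core, aelw = aelw_tab,
                   stems = stems, stem_analysis = stem_an,
                   prune_reports = prune_reports)
  class(manifest) <- "pipeline_manifest"
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  manifest
}

score_sisters_empty <- function() {
  out <- data.frame(epoc_id = character(0), euk_clade_id = character(0),
                    candidate_label = character(0),
                    candidate_node = numeric(0), elw = numeric(0),
                    topo_dist = numeric(0), total_ll = numeric(0))
  class(out) <- c("elw_table", "data.frame")
  out
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("ancestry-inference pipeline manifest (seed", x$seed, ")\n")
  for (nm in names(x$counts)) cat(sprintf("  %-35s %d\n", nm, x$counts[[nm]]))
  cat("  elw rows:", nrow(x$elw), "| core rows:", nrow(x$core),
      "| stem records:", if (is.null(x$stems)) 0L else nrow(x$stems), "\n")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `elw.tsv`, `core_elw.tsv`, `aelw.tsv`, `stems.tsv` and
#' `manifest.json` (seed, counts, per-EPOC status and prune reports).
#'
#' @param manifest a `pipeline_manifest`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) {
    if (!is.null(df) && nrow(df)) {
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(manifest$elw, "elw.tsv")
  wt(manifest$core, "core_elw.tsv")
  wt(manifest$aelw, "aelw.tsv")
  wt(manifest$stems, "stems.tsv")
  statuses <- lapply(manifest$epocs, function(e) e$status)
  reports <- lapply(manifest$prune_reports, function(r) {
    r[c("removed_leaves", "fitted_logmean", "fitted_logsd", "upper_cutoff",
        "degenerate_fit", "discarded", "discard_reason")]
  })
  jsonlite::write_json(
    list(seed = manifest$seed, counts = as.list(manifest$counts),
         status = statuses, prune_reports = reports),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
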
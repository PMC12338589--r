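#' Core-set filtering configuration
#'
#' Thresholds defining the reliable "core" subset of sister-clade calls:
#' only ELW values strictly inside `(elw_min, elw_max)` are considered
#' reliable. Near-certain assignments (ELW >= 0.99) are disproportionately
#' eukaryote-like candidates branching from within the eukaryotic clade
#' itself, i.e. likely late horizontal transfer, and are excluded -- except
#' that ELW values of 1 are admitted for EPOCs carrying a configured
#' annotation (by default the oxidative-phosphorylation pathway, where such
#' values are expected for genuine mitochondrial ancestry). EPOCs must be
#' annotated, and their eukaryotic clades must pass the LECA scope check.
#'
#' @param elw_min,elw_max exclusive ELW window (defaults 0.4 and 0.99).
#' @param min_euk_labels strict minimum distinct eukaryotic labels
#'   (default 5).
#' @param require_supergroups require both Amorphea and Diaphoretickes
#'   (default TRUE).
#' @param oxphos_exception admit ELW = 1 for `exception_labels` (default
#'   TRUE).
#' @param exception_labels annotation labels granting the exception
#'   (default "map00190").
#' @return list of class `core_config`.
#' @export
core_config <- function(elw_min = 0.4, elw_max = 0.99, min_euk_labels = 5L,
                        require_supergroups = TRUE, oxphos_exception = TRUE,
                        exception_labels = "map00190") {
  stopifnot(elw_min >= 0, elw_min < elw_max, elw_max <= 1)
  out <- list(elw_min = elw_min, elw_max = elw_max,
              min_euk_labels = as.integer(min_euk_labels),
              require_supergroups = require_supergroups,
              oxphos_exception = oxphos_exception,
              exception_labels = exception_labels)
  class(out) <- "core_config"
  out
}

#' Filter an ELW table to the reliable core set
#'
#' @param elw an `elw_table` from [score_sisters()].
#' @param epocs named list of `epoc` objects (names = epoc ids) supplying
#'   annotations, taxonomy and eukaryotic clade membership.
#' @param cfg a [core_config()].
#' @return filtered `elw_table` (subset of the input rows).
#' @export
core_filter <- function(elw, epocs, cfg = core_config()) {
  if (nrow(elw) == 0L) return(elw)
  if (is.null(names(epocs))) {
    names(epocs) <- vapply(epocs, function(e) e$epoc_id, character(1))
  }
  keep <- logical(nrow(elw))
  scope_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(elw))) {
    ep <- epocs[[elw$epoc_id[r]]]
    if (is.null(ep) || length(ep$annotations) == 0L) next
    key <- paste0(elw$epoc_id[r], "/", elw$euk_clade_id[r])
    if (is.null(scope_cache[[key]])) {
      i <- as.integer(sub("^e", "", elw$euk_clade_id[r]))
      members <- ep$euk_clades[[i]]$members
      tax <- ep$taxonomy
      labs <- tax$class_label[match(members, tax$seq_id)]
      labs <- labs[tax$domain[match(members, tax$seq_id)] == "eukaryote"]
      ok <- if (cfg$require_supergroups) {
        check_leca_scope(labs, tax, cfg$min_euk_labels)
      } else {
        length(unique(labs)) > cfg$min_euk_labels
      }
      scope_cache[[key]] <- ok
    }
    if (!scope_cache[[key]]) next
    v <- elw$elw[r]
    in_window <- v > cfg$elw_min && v < cfg$elw_max
    exception <- cfg$oxphos_exception && v >= 1 - 1e-9 &&
      any(ep$annotations %in% cfg$exception_labels)
    keep[r] <- in_window || exception
  }
  out <- elw[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("elw_table", "data.frame")
  out
}

#' Average ELW per functional category and candidate taxon
#'
#' Averages ELW scores across EPOCs sharing a functional category (e.g. a
#' KEGG pathway), per candidate prokaryotic taxon. Categories supported by
#' fewer than `min_epocs` EPOCs are flagged as below threshold.
#'
#' @param core a (core-filtered) `elw_table`.
#' @param grouping data.frame with columns `epoc_id`, `category`; an EPOC
#'   may belong to several categories.
#' @param min_epocs flagging threshold on the number of distinct EPOCs per
#'   category (default 20).
#' @return data.frame with columns `category`, `taxon`, `aelw`, `n_epocs`,
#'   `below_min`.
#' @export
aelw <- function(core, grouping, min_epocs = 20L) {
  empty <- data.frame(category = character(0), taxon = character(0),
                      aelw = numeric(0), n_epocs = integer(0),
                      below_min = logical(0))
  if (nrow(core) == 0L) return(empty)
  mg <- merge(core, grouping, by = "epoc_id")
  if (nrow(mg) == 0L) return(empty)
  agg <- stats::aggregate(elw ~ category + candidate_label, data = mg, FUN = mean)
  nep <- stats::aggregate(epoc_id ~ category, data = mg,
                          FUN = function(x) length(unique(x)))
  out <- data.frame(category = agg$category, taxon = agg$candidate_label,
                    aelw = agg$elw,
                    n_epocs = nep$epoc_id[match(agg$category, nep$category)],
                    stringsAsFactors = FALSE)
  out$below_min <- out$n_epocs < min_epocs
  out[order(out$category, -out$aelw), , drop = FALSE]
}

#' Stem length and normalized stem length of a eukaryotic clade
#'
#' The stem length (SL) is the branch-length distance from the node joining
#' the eukaryotic clade with its inferred prokaryotic sister (the first
#' eukaryotic common ancestor, FECA) to the eukaryotic clade root (the last
#' eukaryotic common ancestor, LECA). To compare stems across gene families
#' with different evolutionary rates, SL is normalized by the median
#' LECA-to-leaf path length over the clade's eukaryotic leaves (NSL =
#' SL / median BL).
#'
#' @param tree rooted `ape::phylo` (the tree the clades were called on).
#' @param euk_clade,sister disjoint clade calls; `sister` should be the
#'   top-ELW candidate.
#' @param taxonomy `taxonomy_table` used to restrict the branch-length
#'   median to eukaryotic leaves.
#' @param epoc_id,euk_clade_id identifiers copied into the record.
#' @return one-row data.frame of class `stem_records` (columns `epoc_id`,
#'   `euk_clade_id`, `sister_label`, `sl`, `median_bl`, `nsl`), or `NULL`
#'   with a warning when the median eukaryotic branch length is zero.
#' @export
stem_lengths <- function(tree, euk_clade, sister, taxonomy,
                         epoc_id = "epoc", euk_clade_id = "e1") {
  if (length(intersect(euk_clade$members, sister$members))) {
    stop("clades must be disjoint")
  }
  depth <- ape::node.depth.edgelength(tree)
  leca <- if (length(euk_clade$members) == 1L) {
    match(euk_clade$members, tree$tip.label)
  } else {
    ape::getMRCA(tree, euk_clade$members)
  }
  feca <- ape::getMRCA(tree, c(euk_clade$members, sister$members))
  sl <- depth[leca] - depth[feca]
  euk_leaves <- euk_clade$members[
    taxonomy$domain[match(euk_clade$members, taxonomy$seq_id)] == "eukaryote"]
  bl <- depth[match(euk_leaves, tree$tip.label)] - depth[leca]
  med <- stats::median(bl)
  if (!is.finite(med) || med <= 0) {
    warning("zero median eukaryotic branch length; record rejected")
    return(NULL)
  }
  out <- data.frame(epoc_id = epoc_id, euk_clade_id = euk_clade_id,
                    sister_label = sister$label, sl = sl, median_bl = med,
                    nsl = sl / med, stringsAsFactors = FALSE)
  class(out) <- c("stem_records", "data.frame")
  out
}

#' Distributional analysis of normalized stem lengths
#'
#' Compares NSL distributions between groups of EPOCs that share an
#' inferred ancestor taxon. Per group: a kernel density estimate of the NSL
#' distribution (Scott's bandwidth), 5th/25th/50th/75th/95th percentiles,
#' the empirical CDF on a common grid, and `n_boot` bootstrap-resampled CDF
#' replicates. Per grid point, the focal group is compared with each
#' reference group twice: `p_mw`, a two-sided Mann-Whitney U test between
#' the two groups' bootstrap CDF-value distributions, and `p_boot`, a paired
#' bootstrap test of the CDF difference (the fraction of replicates on each
#' side of zero, doubled). The Mann-Whitney variant treats bootstrap
#' replicates as independent samples and is strongly anticonservative under
#' the null, so `p_boot` is the procedure's calibrated p-value; `p_mw` is
#' retained for comparability with likelihood-weight analyses that plot it.
#' Additionally, for each split point the groups' raw NSL values below and
#' above the split are compared by two-sided Mann-Whitney tests.
#'
#' @param records a `stem_records` data.frame.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer seed (bootstrap replicates are reproducible).
#' @param split_points NSL thresholds for the below/above comparisons
#'   (default `c(0.3, 0.35)`).
#' @param grid_points grid size spanning `[0, 99th percentile]` of the
#'   pooled NSL values (default 200).
#' @param min_group groups with fewer records are excluded with a warning
#'   (default 5).
#' @param focal focal group label (default: the group with most records).
#' @return list of class `stem_analysis`: `grid`, `groups` (per group:
#'   `nsl`, `kde`, `percentiles`, `cdf`, `boot_cdf`), `comparisons` (per
#'   reference group: `p_mw`, `p_boot` along the grid and a `splits`
#'   data.frame), `focal`, `n_boot`, `seed`.
#' @export
stem_distribution_analysis <- function(records, n_boot = 200L, seed = 1L,
                                       split_points = c(0.3, 0.35),
                                       grid_points = 200L, min_group = 5L,
                                       focal = NULL) {
  by_group <- split(records$nsl, records$sister_label)
  small <- names(by_group)[lengths(by_group) < min_group]
  if (length(small)) {
    warning("groups excluded (fewer than ", min_group, " records): ",
            paste(small, collapse = ", "))
    by_group <- by_group[lengths(by_group) >= min_group]
  }
  if (length(by_group) < 2L) stop("need >= 2 groups with >= ", min_group,
                                  " records each")
  by_group <- by_group[order(names(by_group))]
  pooled <- unlist(by_group, use.names = FALSE)
  grid <- seq(0, stats::quantile(pooled, 0.99, names = FALSE),
              length.out = grid_points)
  if (is.null(focal)) {
    focal <- names(by_group)[which.max(lengths(by_group))]
  }
  stopifnot(focal %in% names(by_group))

  set.seed(stage_seed(seed, "stem_boot"))
  groups <- lapply(names(by_group), function(g) {
    x <- by_group[[g]]
    boot <- vapply(seq_len(n_boot), function(b) {
      stats::ecdf(sample(x, replace = TRUE))(grid)
    }, numeric(length(grid)))
    list(nsl = x,
         kde = stats::density(x, bw = "nrd"),
         percentiles = stats::quantile(x, c(.05, .25, .5, .75, .95)),
         cdf = stats::ecdf(x)(grid),
         boot_cdf = boot)   # grid x n_boot
  })
  names(groups) <- names(by_group)

  refs <- setdiff(names(by_group), focal)
  comparisons <- lapply(refs, function(g) {
    Fx <- groups[[focal]]$boot_cdf
    Fy <- groups[[g]]$boot_cdf
    p_mw <- vapply(seq_along(grid), function(i) {
      if (stats::sd(Fx[i, ]) == 0 && stats::sd(Fy[i, ]) == 0) return(1)
      suppressWarnings(stats::wilcox.test(Fx[i, ], Fy[i, ],
                                          exact = FALSE)$p.value)
    }, numeric(1))
    d <- Fx - Fy
    p_boot <- apply(d, 1, function(di) {
      min(1, 2 * (1 + min(sum(di <= 0), sum(di >= 0))) / (n_boot + 1))
    })
    x <- groups[[focal]]$nsl
    y <- groups[[g]]$nsl
    splits <- do.call(rbind, lapply(split_points, function(sp) {
      p_lo <- if (sum(x < sp) >= 2 && sum(y < sp) >= 2) {
        suppressWarnings(stats::wilcox.test(x[x < sp], y[y < sp],
                                            exact = FALSE)$p.value)
      } else NA_real_
      p_hi <- if (sum(x >= sp) >= 2 && sum(y >= sp) >= 2) {
        suppressWarnings(stats::wilcox.test(x[x >= sp], y[y >= sp],
                                            exact = FALSE)$p.value)
      } else NA_real_
      data.frame(split = sp, p_below = p_lo, p_above = p_hi)
    }))
    list(reference = g, p_mw = p_mw, p_boot = p_boot, splits = splits)
  })
  names(comparisons) <- refs

  out <- list(grid = grid, groups = groups, comparisons = comparisons,
              focal = focal, n_boot = n_boot, seed = seed)
  class(out) <- "stem_analysis"
  out
}
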
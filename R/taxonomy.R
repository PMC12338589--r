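#' Construct a taxonomy table
#'
#' A taxonomy table maps every sequence id to its domain (eukaryote or
#' prokaryote), a curated class-level label (e.g. "Asgard",
#' "Alphaproteobacteria", "Metazoa"), a species id (the lowest-rank taxonomic
#' identifier; the table is authoritative, no external taxonomy is resolved)
#' and, for eukaryotes only, a supergroup membership used for scope checks of
#' the last eukaryotic common ancestor (LECA): "Amorphea", "Diaphoretickes" or
#' "other".
#'
#' @param seq_id character vector of unique sequence ids.
#' @param domain character vector, each "eukaryote" or "prokaryote".
#' @param class_label character vector of curated class labels.
#' @param species_id character vector of species identifiers.
#' @param supergroup character vector or NA; only meaningful for eukaryotes.
#'   Unknown or missing values are stored as "other" for eukaryotes and NA
#'   for prokaryotes.
#' @return A `data.frame` of class `taxonomy_table` with one row per sequence.
#' @examples
#' tax <- taxonomy_table(c("e1", "p1"), c("eukaryote", "prokaryote"),
#'                       c("Metazoa", "Asgard"), c("sp1", "sp2"),
#'                       c("Amorphea", NA))
#' @export
taxonomy_table <- function(seq_id, domain, class_label, species_id,
                           supergroup = NA_character_) {
  if (length(seq_id) == 0L) stop("empty taxonomy")
  if (anyDuplicated(seq_id)) stop("duplicated sequence ids in taxonomy")
  domain <- match.arg(domain, c("eukaryote", "prokaryote"),
                      several.ok = TRUE)
  n <- length(seq_id)
  supergroup <- rep_len(as.character(supergroup), n)
  is_euk <- domain == "eukaryote"
  supergroup[is_euk & (is.na(supergroup) |
                       !supergroup %in% c("Amorphea", "Diaphoretickes"))] <- "other"
  supergroup[!is_euk] <- NA_character_
  out <- data.frame(seq_id = as.character(seq_id),
                    domain = rep_len(domain, n),
                    class_label = rep_len(as.character(class_label), n),
                    species_id = rep_len(as.character(species_id), n),
                    supergroup = supergroup,
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Read / write a taxonomy table as TSV
#'
#' Tab-separated, header row, UTF-8; columns `seq_id, domain, class_label,
#' species_id, supergroup`.
#'
#' @param path file path.
#' @return `read_taxonomy` returns a `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("seq_id", "domain", "class_label", "species_id", "supergroup")
  if (!all(need %in% names(x))) {
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  }
  sg <- x$supergroup
  sg[sg == ""] <- NA_character_
  taxonomy_table(x$seq_id, x$domain, x$class_label, x$species_id, sg)
}

#' @rdname read_taxonomy
#' @param taxonomy a `taxonomy_table`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(as.data.frame(taxonomy), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a cluster-membership table
#'
#' @param cluster_id character vector, one entry per member row.
#' @param seq_id character vector parallel to `cluster_id`.
#' @return A `data.frame` of class `cluster_table` with columns
#'   `cluster_id, seq_id`.
#' @export
cluster_table <- function(cluster_id, seq_id) {
  if (length(cluster_id) != length(seq_id)) {
    stop("cluster_id and seq_id must have equal length")
  }
  out <- data.frame(cluster_id = as.character(cluster_id),
                    seq_id = as.character(seq_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' @rdname cluster_table
#' @param path file path of a TSV with columns `cluster_id, seq_id`.
#' @export
read_clusters <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cluster_table(x$cluster_id, x$seq_id)
}

#' Soft-core pangenome filter
#'
#' Retains the gene clusters that are widespread within their taxonomic
#' group, the "soft-core" pangenome. A cluster is kept when its members cover
#' at least `prok_frac` of the distinct species of its (prokaryotic) group,
#' or at least `euk_frac` for eukaryotic groups. Coverage is counted over
#' distinct `species_id` values; the group of a cluster is the class label
#' shared by all its members. Restricting the data to soft-core families
#' guards downstream ancestry inference against lineage-specific horizontal
#' transfer.
#'
#' By default both domains are filtered on the species fraction. Set
#' `euk_mode = "sequences"` to count eukaryotic coverage as the fraction of
#' the group's sequences instead.
#'
#' @param clusters a `cluster_table`.
#' @param taxonomy a `taxonomy_table` resolving every member sequence.
#' @param prok_frac fraction in (0, 1], default 0.5.
#' @param euk_frac fraction in (0, 1], default 0.2.
#' @param euk_mode "species" (default) or "sequences".
#' @return A `cluster_table` containing the retained clusters (subset of the
#'   input, order preserved).
#' @examples
#' tax <- taxonomy_table(paste0("s", 1:10), rep("prokaryote", 10),
#'                       rep("Asgard", 10), paste0("sp", 1:10))
#' cl <- cluster_table(rep("c1", 5), paste0("s", 1:5))
#' nrow(softcore_filter(cl, tax))   # kept: 5/10 species = 50%
#' @export
softcore_filter <- function(clusters, taxonomy, prok_frac = 0.5,
                            euk_frac = 0.2,
                            euk_mode = c("species", "sequences")) {
  euk_mode <- match.arg(euk_mode)
  stopifnot(prok_frac > 0, prok_frac <= 1, euk_frac > 0, euk_frac <= 1)
  if (nrow(taxonomy) == 0L) stop("empty taxonomy")
  unknown <- setdiff(clusters$seq_id, taxonomy$seq_id)
  if (length(unknown)) {
    stop("sequence ids not in taxonomy: ", paste(utils::head(unknown), collapse = ", "))
  }
  idx <- match(clusters$seq_id, taxonomy$seq_id)
  member_label <- taxonomy$class_label[idx]
  member_species <- taxonomy$species_id[idx]
  member_domain <- taxonomy$domain[idx]

  # group totals over the whole taxonomy
  n_species_by_label <- tapply(taxonomy$species_id, taxonomy$class_label,
                               function(s) length(unique(s)))
  n_seqs_by_label <- table(taxonomy$class_label)

  keep_cluster <- function(rows) {
    labs <- unique(member_label[rows])
    if (length(labs) != 1L) {
      stop("cluster members span multiple taxonomic groups: ",
           paste(labs, collapse = ", "))
    }
    dom <- member_domain[rows][1L]
    if (dom == "eukaryote" && euk_mode == "sequences") {
      frac <- length(rows) / as.numeric(n_seqs_by_label[labs])
      frac >= euk_frac
    } else {
      thr <- if (dom == "eukaryote") euk_frac else prok_frac
      cov <- length(unique(member_species[rows])) /
        as.numeric(n_species_by_label[labs])
      cov >= thr
    }
  }

  rows_by_cluster <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  if (any(lengths(rows_by_cluster) == 0L)) stop("empty cluster")
  kept_ids <- names(rows_by_cluster)[vapply(rows_by_cluster, keep_cluster,
                                            logical(1))]
  out <- clusters[clusters$cluster_id %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' LECA-scope check for a eukaryotic clade
#'
#' A eukaryotic clade is considered to trace back to the LECA when it spans
#' strictly more than `min_labels` distinct class labels and contains at
#' least one member from each of the two deepest eukaryotic supergroups,
#' Amorphea and Diaphoretickes.
#'
#' @param labels character vector (multiset) of eukaryotic class labels of
#'   the clade's members.
#' @param taxonomy a `taxonomy_table` used to map labels to supergroups.
#' @param min_labels strict lower bound on the distinct label count
#'   (default 5, i.e. "more than 5").
#' @return logical scalar; `FALSE` on empty input.
#' @export
check_leca_scope <- function(labels, taxonomy, min_labels = 5L) {
  if (length(labels) == 0L) return(FALSE)
  euk <- taxonomy[taxonomy$domain == "eukaryote", , drop = FALSE]
  sg_by_label <- tapply(euk$supergroup, euk$class_label,
                        function(s) unique(s))
  sg <- unlist(sg_by_label[unique(labels)], use.names = FALSE)
  length(unique(labels)) > min_labels &&
    "Amorphea" %in% sg && "Diaphoretickes" %in% sg
}
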
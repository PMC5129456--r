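# Ortholog filtering for de novo transcriptome assemblies: classify
# same-taxon contig pairs as paralogous, then reduce multi-taxon peptide
# clusterings to a set of robust orthogroups.

#' Pick the representative contig of an assembly component
#'
#' Within a component (all contigs derived from one de Bruijn graph, i.e.
#' putative isoforms and close paralogs of one locus), the representative
#' is the contig with the longest predicted ORF.  Ties are broken by
#' total contig length, then by lexicographically smallest contig id, so
#' the choice is deterministic.
#'
#' @param contigs Data frame with columns \code{contig_id},
#'   \code{component_id}, \code{sequence_length}, \code{orf_start},
#'   \code{orf_end} (0-based half-open ORF coordinates).
#' @return The \code{contig_id} of the representative.
#' @export
select_component_representative <- function(contigs) {
  if (is.null(contigs) || nrow(contigs) == 0L) stop("empty component")
  if (length(unique(contigs$component_id)) != 1L)
    stop("contigs from more than one component")
  orf_len <- contigs$orf_end - contigs$orf_start
  if (any(orf_len <= 0 | contigs$orf_start < 0 |
          contigs$orf_end > contigs$sequence_length))
    stop("invalid ORF coordinates")
  o <- order(-orf_len, -contigs$sequence_length, contigs$contig_id)
  contigs$contig_id[o[1]]
}

#' Classify an aligned contig pair as compatible or paralogous
#'
#' Given a pairwise alignment of two same-taxon contigs, decides whether
#' they are variants of one locus (alleles/isoforms) or products of a gene
#' duplication.  A sliding-window identity profile over the comparable
#' (both-ungapped) columns locates low-identity tracts.  Tracts touching
#' an alignment terminus are treated as structural variation (e.g.
#' alternative UTRs or incomplete assembly) and excluded from the mean
#' identity; an internal low-identity tract of at least
#' \code{min_internal_tract} columns indicates alternate use of duplicated
#' exons and forces the verdict \code{"paralog_subgene"} regardless of the
#' mean.  Otherwise a mean identity below \code{identity_threshold} gives
#' \code{"paralog"}, and \code{"compatible"} else.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (character
#'   strings or character vectors), gaps as \code{"-"}.
#' @param identity_threshold Mean-identity cutoff (default 0.98).
#' @param window Sliding-window width in comparable columns.
#' @param low_identity_cutoff Within-window identity below which a window
#'   is flagged low.
#' @param min_internal_tract Minimum internal tract length (comparable
#'   columns) that forces \code{"paralog_subgene"}.
#' @param terminal_window Tracts starting or ending within this many
#'   columns of an alignment end count as terminal.
#' @return List with \code{verdict} (\code{"compatible"},
#'   \code{"paralog"} or \code{"paralog_subgene"}), \code{mean_identity},
#'   \code{excluded_terminal_columns} and \code{flagged_internal_tracts}
#'   (two-column matrix of start/end positions in comparable-column
#'   coordinates).
#' @export
classify_pair <- function(seq_a, seq_b, identity_threshold = 0.98,
                          window = 100, low_identity_cutoff = 0.85,
                          min_internal_tract = 60, terminal_window = 50) {
  a <- .split_chars(seq_a)
  b <- .split_chars(seq_b)
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) stop("alignment has no comparable columns")
  match_vec <- (toupper(a) == toupper(b))[comparable]
  L <- length(match_vec)

  w <- min(window, L)
  # windowed identity via cumulative sums; window i covers [i, i + w - 1]
  cs <- c(0, cumsum(match_vec))
  wid <- (cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]) / w
  low_win <- which(wid < low_identity_cutoff)
  # columns covered by any low window
  low_col <- rep(FALSE, L)
  for (i in low_win) low_col[i:(i + w - 1)] <- TRUE

  tracts <- .runs(low_col)
  terminal <- excluded <- rep(FALSE, L)
  internal_tracts <- NULL
  if (nrow(tracts)) {
    is_term <- tracts[, 1] <= terminal_window | tracts[, 2] > L - terminal_window
    for (r in which(is_term)) excluded[tracts[r, 1]:tracts[r, 2]] <- TRUE
    keep <- !is_term & (tracts[, 2] - tracts[, 1] + 1L) >= min_internal_tract
    internal_tracts <- tracts[keep, , drop = FALSE]
  }
  use <- !excluded
  mean_identity <- if (any(use)) mean(match_vec[use]) else NA_real_
  verdict <- if (!is.null(internal_tracts) && nrow(internal_tracts) > 0)
    "paralog_subgene"
  else if (is.na(mean_identity) || mean_identity < identity_threshold)
    "paralog"
  else "compatible"
  list(verdict = verdict, mean_identity = mean_identity,
       excluded_terminal_columns = sum(excluded),
       flagged_internal_tracts = if (is.null(internal_tracts))
         matrix(integer(0), 0, 2) else internal_tracts)
}

.split_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Filter peptide clusters into candidate orthogroups
#'
#' Annotates every cluster of a cross-taxon peptide clustering with the
#' filtering criteria it violates: (1) it contains both members of a
#' known within-taxon paralog pair, (2) it is missing one of the required
#' taxa, (3) it contains more than \code{backbone_limit} contigs of the
#' outgroup backbone proteome.  All criteria are evaluated for every
#' cluster (no short-circuiting), so per-criterion exclusion counts can be
#' reported.
#'
#' @param clusters A cluster set as returned by
#'   \code{\link{read_groups_file}}: list with elements \code{inflation}
#'   and \code{clusters} (named list of data frames with columns
#'   \code{taxon}, \code{contig_id}).
#' @param paralog_pairs Data frame with columns \code{taxon},
#'   \code{contig_a}, \code{contig_b} listing within-taxon paralog pairs.
#' @param required_taxa Character vector of taxa that must each
#'   contribute at least one contig.
#' @param backbone_taxon Name of the outgroup backbone taxon.
#' @param backbone_limit Maximum number of backbone contigs allowed.
#' @return Data frame with one row per cluster: \code{cluster_id},
#'   logical columns \code{has_paralog_pair}, \code{missing_taxon},
#'   \code{excess_backbone}, \code{retained}, and a comma-separated
#'   \code{exclusion_reasons} string.
#' @export
filter_clusters <- function(clusters, paralog_pairs, required_taxa,
                            backbone_taxon, backbone_limit = 3) {
  stopifnot(length(required_taxa) >= 1L, backbone_limit >= 0)
  cl <- clusters$clusters
  if (length(cl) == 0L)
    return(data.frame(cluster_id = character(0), has_paralog_pair = logical(0),
                      missing_taxon = logical(0), excess_backbone = logical(0),
                      retained = logical(0), exclusion_reasons = character(0)))
  pp_keys <- character(0)
  if (!is.null(paralog_pairs) && nrow(paralog_pairs) > 0) {
    lo <- pmin(paralog_pairs$contig_a, paralog_pairs$contig_b)
    hi <- pmax(paralog_pairs$contig_a, paralog_pairs$contig_b)
    pp_keys <- paste(paralog_pairs$taxon, lo, hi)
  }
  rows <- lapply(names(cl), function(id) {
    members <- cl[[id]]
    has_pp <- FALSE
    if (length(pp_keys)) {
      for (tx in unique(members$taxon)) {
        ctg <- sort(members$contig_id[members$taxon == tx])
        if (length(ctg) >= 2L) {
          cmb <- utils::combn(ctg, 2L)
          if (any(paste(tx, cmb[1, ], cmb[2, ]) %in% pp_keys)) {
            has_pp <- TRUE
            break
          }
        }
      }
    }
    missing <- !all(required_taxa %in% members$taxon)
    excess <- sum(members$taxon == backbone_taxon) > backbone_limit
    reasons <- c("has_paralog_pair", "missing_taxon",
                 "excess_backbone")[c(has_pp, missing, excess)]
    data.frame(cluster_id = id, has_paralog_pair = has_pp,
               missing_taxon = missing, excess_backbone = excess,
               retained = length(reasons) == 0L,
               exclusion_reasons = paste(reasons, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Identify orthogroups robust to the clustering inflation value
#'
#' A surviving cluster is robust when its non-backbone membership is
#' reproduced exactly as a cluster in every alternate clustering (the
#' clusterings obtained at other inflation values).  Backbone (outgroup
#' proteome) contigs are ignored in the comparison because their
#' attachment is volatile under inflation changes.  A contig that is
#' present in the primary clustering but absent from an alternate counts
#' as a membership change, i.e. the cluster is not robust.
#'
#' @param survivors Character vector of cluster ids that passed
#'   \code{\link{filter_clusters}}.
#' @param primary The primary cluster set.
#' @param alternates Non-empty list of alternate cluster sets.
#' @param backbone_taxon Backbone taxon to ignore in the comparison.
#' @return Character vector, the subset of \code{survivors} that is
#'   robust.
#' @export
robust_orthogroups <- function(survivors, primary, alternates,
                               backbone_taxon) {
  if (length(alternates) == 0L) stop("at least one alternate clustering needed")
  member_key <- function(members) {
    m <- members[members$taxon != backbone_taxon, , drop = FALSE]
    paste(sort(paste(m$taxon, m$contig_id, sep = "|")), collapse = " ")
  }
  alt_keys <- lapply(alternates, function(cs)
    vapply(cs$clusters, member_key, ""))
  robust <- vapply(survivors, function(id) {
    key <- member_key(primary$clusters[[id]])
    all(vapply(alt_keys, function(ak) key %in% ak, TRUE))
  }, TRUE)
  survivors[robust]
}

#' Run the full orthogroup filter
#'
#' Convenience wrapper: applies \code{\link{filter_clusters}} to the
#' primary clustering, then \code{\link{robust_orthogroups}} against the
#' alternates, and returns per-cluster decisions with the complete set of
#' exclusion reasons (including \code{not_robust}) plus per-reason counts.
#'
#' @inheritParams filter_clusters
#' @inheritParams robust_orthogroups
#' @return List with \code{decisions} (data frame) and \code{counts}
#'   (named integer vector of exclusion tallies).
#' @export
filter_orthogroups <- function(clusters, paralog_pairs, required_taxa,
                               backbone_taxon, backbone_limit = 3,
                               alternates = list()) {
  dec <- filter_clusters(clusters, paralog_pairs, required_taxa,
                         backbone_taxon, backbone_limit)
  dec$not_robust <- FALSE
  if (length(alternates) > 0 && any(dec$retained)) {
    surv <- dec$cluster_id[dec$retained]
    rob <- robust_orthogroups(surv, clusters, alternates, backbone_taxon)
    dec$not_robust <- dec$retained & !(dec$cluster_id %in% rob)
    dec$retained <- dec$retained & !dec$not_robust
    nr <- dec$not_robust
    dec$exclusion_reasons <- ifelse(
      nr, paste0(dec$exclusion_reasons,
                 ifelse(nzchar(dec$exclusion_reasons), ",", ""), "not_robust"),
      dec$exclusion_reasons)
  }
  counts <- c(has_paralog_pair = sum(dec$has_paralog_pair),
              missing_taxon = sum(dec$missing_taxon),
              excess_backbone = sum(dec$excess_backbone),
              not_robust = sum(dec$not_robust),
              excluded = sum(!dec$retained),
              retained = sum(dec$retained))
  list(decisions = dec, counts = counts)
}

#' Read an OrthoMCL-style groups file
#'
#' Parses the groups dialect \code{clusterID: taxon|contig taxon|contig
#' ...}, one cluster per line.
#'
#' @param path File path.
#' @param inflation Inflation value to record with the cluster set.
#' @return List with \code{inflation} and \code{clusters} (named list of
#'   data frames with \code{taxon}, \code{contig_id}).
#' @export
read_groups_file <- function(path, inflation = NA_real_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  clusters <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed groups line: ", ln)
    id <- trimws(parts[1])
    members <- strsplit(trimws(paste(parts[-1], collapse = ":")), "[ \t]+")[[1]]
    tc <- strsplit(members, "|", fixed = TRUE)
    bad <- lengths(tc) != 2L
    if (any(bad)) stop("malformed member in cluster ", id)
    df <- data.frame(taxon = vapply(tc, `[`, "", 1L),
                     contig_id = vapply(tc, `[`, "", 2L))
    if (anyDuplicated(paste(df$taxon, df$contig_id)))
      stop("duplicated contig in cluster ", id)
    clusters[[id]] <- df
  }
  all_members <- unlist(lapply(clusters, function(df)
    paste(df$taxon, df$contig_id)))
  if (anyDuplicated(all_members))
    stop("a contig appears in more than one cluster")
  list(inflation = inflation, clusters = clusters)
}

#' Read a paralog-pair table
#'
#' Tab-separated columns \code{taxon}, \code{contig_a}, \code{contig_b},
#' \code{verdict}; only rows with a paralog verdict are returned.
#'
#' @param path File path.
#' @return Data frame of paralog pairs.
#' @export
read_paralog_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("taxon", "contig_a", "contig_b", "verdict")
  if (!all(need %in% names(df)))
    stop("paralog pair table must have columns ", paste(need, collapse = ", "))
  df[df$verdict %in% c("paralog", "paralog_subgene"), , drop = FALSE]
}
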
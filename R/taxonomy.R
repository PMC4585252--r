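#' Read an NCBI-dialect taxonomy (nodes.dmp / names.dmp)
#'
#' Fields are separated by `\t|\t` and rows end in `\t|`. Only scientific
#' names are kept from the names file.
#'
#' @param nodes_path Path to nodes.dmp (tax_id, parent tax_id, rank, ...).
#' @param names_path Path to names.dmp (tax_id, name, unique name, class).
#' @return A `Taxonomy` data frame: tax_id, parent_id, rank, name.
#' @export
read_taxonomy <- function(nodes_path, names_path) {
  parse_dmp <- function(path) {
    ln <- readLines(path, warn = FALSE)
    ln <- sub("\t\\|$", "", ln)
    strsplit(ln, "\t|\t", fixed = TRUE)
  }
  np <- parse_dmp(nodes_path)
  nodes <- data.frame(
    tax_id = as.integer(vapply(np, `[[`, "", 1)),
    parent_id = as.integer(vapply(np, `[[`, "", 2)),
    rank = vapply(np, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$tax_id))
    stop("duplicate tax_id in nodes file")
  mp <- parse_dmp(names_path)
  cls <- vapply(mp, function(x) if (length(x) >= 4) x[[4]] else "", "")
  sci <- cls == "scientific name" | cls == ""
  nm <- data.frame(tax_id = as.integer(vapply(mp[sci], `[[`, "", 1)),
                   name = vapply(mp[sci], `[[`, "", 2),
                   stringsAsFactors = FALSE)
  nodes$name <- nm$name[match(nodes$tax_id, nm$tax_id)]
  class(nodes) <- c("Taxonomy", "data.frame")
  nodes
}

#' LCA assignment parameters
#'
#' Defaults follow common lowest-common-ancestor binning practice for
#' translated searches: minimum bit score 50, e-value ceiling 0.01,
#' a 10% window below the best bit score (interpreted multiplicatively:
#' hits with bit >= 0.9 x best are retained), and minimum support 1.
#'
#' @param min_score Minimum bit score.
#' @param max_expected Maximum e-value.
#' @param top_percent Percent window below the best bit score, in
#'   \[0, 100\].
#' @param min_support Minimum number of queries a taxon needs before its
#'   assignments are reported (taxa below this are set unassigned).
#' @return An `LcaParams` list.
#' @export
lca_params <- function(min_score = 50, max_expected = 0.01,
                       top_percent = 10, min_support = 1L) {
  stopifnot(top_percent >= 0, top_percent <= 100)
  structure(list(min_score = min_score, max_expected = max_expected,
                 top_percent = top_percent,
                 min_support = as.integer(min_support)),
            class = "LcaParams")
}

.tax_path <- function(tax_id, parent_of) {
  path <- integer(0)
  cur <- tax_id
  for (i in seq_len(length(parent_of) + 1L)) {
    path <- c(path, cur)
    nxt <- parent_of[[as.character(cur)]]
    if (is.null(nxt) || nxt == cur) break
    cur <- nxt
  }
  path
}

#' Lowest-common-ancestor taxonomic assignment
#'
#' Per query: hits below `min_score` or above `max_expected` are
#' discarded; of the rest, hits with bit score at least
#' `(1 - top_percent/100)` times the best are retained, and the lowest
#' common ancestor of their subjects' taxa is returned. Queries with no
#' retained hits are unassigned (NA). Hits with tax ids absent from the
#' taxonomy are ignored and counted. After per-query assignment, taxa
#' supported by fewer than `min_support` queries are set unassigned.
#'
#' @param hits A `SearchHit` data frame carrying a `subject_tax_id`
#'   column.
#' @param taxonomy A `Taxonomy`.
#' @param p An `LcaParams`.
#' @return Data frame (query_id, tax_id, n_hits_used) with attribute
#'   `n_unknown_taxid`.
#' @export
assign_lca <- function(hits, taxonomy, p = lca_params()) {
  stopifnot(!is.null(hits$subject_tax_id))
  parent_of <- as.list(stats::setNames(taxonomy$parent_id,
                                       as.character(taxonomy$tax_id)))
  known <- hits$subject_tax_id %in% taxonomy$tax_id
  n_unknown <- sum(!known & !is.na(hits$subject_tax_id)) +
    sum(is.na(hits$subject_tax_id))
  hits <- hits[known & !is.na(hits$subject_tax_id), , drop = FALSE]
  qids <- unique(hits$query_id)
  res <- data.frame(query_id = qids, tax_id = NA_integer_,
                    n_hits_used = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(qids)) {
    h <- hits[hits$query_id == qids[i], , drop = FALSE]
    h <- h[h$bit_score >= p$min_score & h$evalue <= p$max_expected, ,
           drop = FALSE]
    if (nrow(h) == 0) next
    best <- max(h$bit_score)
    h <- h[h$bit_score >= (1 - p$top_percent / 100) * best, , drop = FALSE]
    paths <- lapply(unique(h$subject_tax_id), .tax_path, parent_of)
    common <- Reduce(intersect, paths)
    if (length(common) == 0) next
    # deepest shared node = first element of any path that is shared
    res$tax_id[i] <- paths[[1]][match(TRUE, paths[[1]] %in% common)]
    res$n_hits_used[i] <- nrow(h)
  }
  if (p$min_support > 1L) {
    tab <- table(res$tax_id)
    weak <- as.integer(names(tab)[tab < p$min_support])
    res$tax_id[res$tax_id %in% weak] <- NA_integer_
  }
  attr(res, "n_unknown_taxid") <- n_unknown
  res
}

#' Roll assignments up to phylum level
#'
#' Each assigned query climbs its parent chain to the first node of rank
#' "phylum"; queries whose chain has no phylum node are reported as
#' "unclassified". Fractions are over assigned (non-NA) queries and sum
#' to 1.
#'
#' @param assignments Output of [assign_lca()] (or any frame with
#'   query_id and tax_id).
#' @param taxonomy A `Taxonomy`.
#' @return Data frame (phylum, n, fraction), decreasing by n.
#' @export
rollup_phylum <- function(assignments, taxonomy) {
  a <- assignments[!is.na(assignments$tax_id), , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned queries to roll up")
  parent_of <- as.list(stats::setNames(taxonomy$parent_id,
                                       as.character(taxonomy$tax_id)))
  rank_of <- stats::setNames(taxonomy$rank, as.character(taxonomy$tax_id))
  name_of <- stats::setNames(taxonomy$name, as.character(taxonomy$tax_id))
  phylum <- vapply(a$tax_id, function(t) {
    path <- .tax_path(t, parent_of)
    hit <- path[rank_of[as.character(path)] == "phylum"]
    if (length(hit)) name_of[[as.character(hit[1])]] else "unclassified"
  }, "")
  tab <- sort(table(phylum), decreasing = TRUE)
  data.frame(phylum = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(a),
             stringsAsFactors = FALSE)
}
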
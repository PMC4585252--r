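#' Fractional top-hit assignment
#'
#' For each query (within each metal, since Fe and Cu searches are
#' treated independently), the hits whose bit score rounds to the maximum
#' at `tie_decimals` decimals are retained as joint top hits, each
#' weighted 1/k where k is the number of tied hits; all other hits are
#' discarded. Weights therefore sum to exactly 1 per query and metal.
#'
#' @param hits A `SearchHit` data frame (one or many queries).
#' @param tie_decimals Decimals at which bit scores are compared for
#'   ties; 1 matches typical tabular output precision.
#' @return A `HitAssignment` data frame: query_id, label (family_sccs),
#'   metal, weight, subject_description.
#' @export
assign_top_hits <- function(hits, tie_decimals = 1L) {
  if (nrow(hits) == 0) return(.empty_assignment())
  key <- paste(hits$query_id, hits$metal, sep = "\r")
  rb <- round(hits$bit_score, tie_decimals)
  parts <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    b <- rb[idx]
    top <- idx[b == max(b)]
    data.frame(query_id = hits$query_id[top],
               label = hits$family_sccs[top],
               metal = hits$metal[top],
               weight = rep(1 / length(top), length(top)),
               subject_description = hits$subject_description[top],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

.empty_assignment <- function() {
  data.frame(query_id = character(), label = character(),
             metal = character(), weight = numeric(),
             subject_description = character(), stringsAsFactors = FALSE)
}

#' Default description rules for splitting the multidomain cupredoxins
#'
#' Ordered case-insensitive substring patterns applied to hit
#' descriptions: nitrite-reductase patterns first, then multicopper
#' oxidases. Editable configuration, not fixed behaviour.
#'
#' @return Data frame with columns `pattern` and `label`.
#' @export
cupredoxin_rules <- function() {
  data.frame(
    pattern = c("nirk", "nitrite reductase (copper",
                "copper-containing nitrite reductase",
                "multicopper oxidase", "laccase", "ceruloplasmin",
                "ascorbate oxidase", "bilirubin oxidase", "cuo", "fet3"),
    label = c(rep("nirK", 3), rep("MCO", 7)),
    stringsAsFactors = FALSE
  )
}

#' Split multidomain cupredoxin assignments into nirK and MCO
#'
#' Parts labeled `b.6.1.3` are relabeled `b.6.1.3/nirK` or `b.6.1.3/MCO`
#' by the first matching description pattern; parts matching neither
#' keep the plain `b.6.1.3` label (and are routed to "others" by
#' [cluster_minor()]). All other families pass through unchanged.
#'
#' @param assign A `HitAssignment` data frame.
#' @param rules Ordered pattern table as from [cupredoxin_rules()].
#' @param family The family to split (default `b.6.1.3`).
#' @return The relabeled assignment frame; attribute
#'   `n_missing_description` counts target parts lacking a description.
#' @export
split_cupredoxins <- function(assign, rules = cupredoxin_rules(),
                              family = "b.6.1.3") {
  tgt <- which(assign$label == family)
  n_missing <- 0L
  if (length(tgt)) {
    desc <- assign$subject_description[tgt]
    miss <- is.na(desc) | !nzchar(desc)
    n_missing <- sum(miss)
    if (n_missing > 0)
      warning(n_missing, " ", family,
              " part(s) without description routed to neither class")
    low <- tolower(ifelse(miss, "", desc))
    lab <- rep(NA_character_, length(tgt))
    for (r in seq_len(nrow(rules))) {
      hit <- is.na(lab) & grepl(tolower(rules$pattern[r]), low, fixed = TRUE)
      lab[hit] <- rules$label[r]
    }
    ok <- !is.na(lab)
    assign$label[tgt[ok]] <- paste0(family, "/", lab[ok])
  }
  attr(assign, "n_missing_description") <- n_missing
  assign
}

#' Aggregate assignment weights into family counts
#'
#' @param assign A `HitAssignment` data frame.
#' @param metal `"Fe"` or `"Cu"`; only parts of this metal are summed.
#' @return Named numeric vector of weighted counts per label.
#' @export
aggregate_weights <- function(assign, metal) {
  a <- assign[assign$metal == metal, , drop = FALSE]
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(a$weight, a$label, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Cluster minor families into "others"
#'
#' Labels contributing less than `threshold_fraction` of the total
#' weighted count are merged (summed) into an "others" row; labels at
#' exactly the threshold are retained. The unsplit remainder of the
#' multidomain cupredoxins (plain `b.6.1.3`) always merges into
#' "others", whatever its share.
#'
#' @param counts Named numeric vector of weighted counts.
#' @param threshold_fraction Minor-family threshold, default 0.04.
#' @param force_other Labels always routed to "others".
#' @return Named numeric vector with minor labels replaced by "others".
#' @export
cluster_minor <- function(counts, threshold_fraction = 0.04,
                          force_other = "b.6.1.3") {
  stopifnot(length(counts) > 0, threshold_fraction > 0,
            threshold_fraction < 1)
  total <- sum(counts)
  minor <- counts / total < threshold_fraction |
    names(counts) %in% force_other
  if (!any(minor)) return(counts)
  major <- counts[!minor]
  others_sum <- sum(counts[minor])
  if ("others" %in% names(major)) {
    major["others"] <- major["others"] + others_sum
  } else {
    major <- c(major, others = others_sum)
  }
  major
}

#' Normalize weighted family counts per 100,000 protein-coding sequences
#'
#' @param counts Named numeric vector of weighted counts.
#' @param total_protein_coding Total protein-coding sequences in the
#'   sample (the normalization denominator); must be positive and at
#'   least the summed weighted count.
#' @param sample_id Sample label.
#' @param metal `"Fe"` or `"Cu"`.
#' @return An `InventoryTable` data frame (label, weighted_count,
#'   per_100k) including a `total` row, with attributes `sample_id`,
#'   `metal`, `total_protein_coding`.
#' @export
normalize_per_100k <- function(counts, total_protein_coding,
                               sample_id = "sample", metal = "Fe") {
  if (total_protein_coding <= 0) stop("total_protein_coding must be positive")
  if (sum(counts) > total_protein_coding + 1e-9)
    stop("total_protein_coding smaller than the summed weighted counts")
  lab <- names(counts)
  out <- data.frame(label = c(lab, "total"),
                    weighted_count = c(unname(counts), sum(counts)),
                    stringsAsFactors = FALSE)
  out$per_100k <- out$weighted_count / total_protein_coding * 1e5
  attr(out, "sample_id") <- sample_id
  attr(out, "metal") <- metal
  attr(out, "total_protein_coding") <- as.integer(total_protein_coding)
  class(out) <- c("InventoryTable", "data.frame")
  out
}

#' @export
print.InventoryTable <- function(x, ...) {
  cat("InventoryTable for sample", attr(x, "sample_id"), "(",
      attr(x, "metal"), "), per",
      attr(x, "total_protein_coding"), "protein-coding sequences\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Full per-sample inventory from hits
#'
#' Convenience wrapper chaining [assign_top_hits()],
#' [split_cupredoxins()], [aggregate_weights()], [cluster_minor()] and
#' [normalize_per_100k()] for one metal.
#'
#' @inheritParams assign_top_hits
#' @inheritParams normalize_per_100k
#' @param metal `"Fe"` or `"Cu"`.
#' @param threshold_fraction Minor-family threshold.
#' @param split_rules Cupredoxin description rules (Cu only).
#' @return An `InventoryTable`.
#' @export
profile_inventory <- function(hits, metal, total_protein_coding,
                              sample_id = "sample",
                              threshold_fraction = 0.04,
                              split_rules = cupredoxin_rules(),
                              tie_decimals = 1L) {
  a <- assign_top_hits(hits, tie_decimals)
  a <- split_cupredoxins(a, split_rules)
  counts <- aggregate_weights(a, metal)
  if (length(counts) == 0) {
    return(normalize_per_100k(stats::setNames(numeric(0), character(0)),
                              total_protein_coding, sample_id, metal))
  }
  counts <- cluster_minor(counts, threshold_fraction)
  normalize_per_100k(counts, total_protein_coding, sample_id, metal)
}

#' Write an inventory table as TSV
#' @param inv An `InventoryTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inventory_tsv <- function(inv, path) {
  out <- data.frame(sample_id = attr(inv, "sample_id"),
                    metal = attr(inv, "metal"),
                    label = inv$label,
                    weighted_count = sprintf("%.6f", inv$weighted_count),
                    per_100k = sprintf("%.6f", inv$per_100k),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine per-sample inventories into a samples x labels matrix
#' @param invs List of `InventoryTable`s.
#' @param value `"per_100k"` or `"weighted_count"`.
#' @return Numeric matrix, rows = samples, columns = labels ("total"
#'   rows dropped).
#' @export
inventory_matrix <- function(invs, value = c("per_100k", "weighted_count")) {
  value <- match.arg(value)
  labs <- sort(unique(unlist(lapply(invs, function(i)
    setdiff(i$label, "total")))))
  m <- matrix(0, length(invs), length(labs),
              dimnames = list(vapply(invs, attr, "", "sample_id"), labs))
  for (i in seq_along(invs)) {
    inv <- invs[[i]]
    inv <- inv[inv$label != "total", , drop = FALSE]
    m[i, inv$label] <- inv[[value]]
  }
  m
}
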
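#' Parse a SCOPe-dialect structural-classification hierarchy
#'
#' Reads the tab-separated description ("dir.des") and classification
#' ("dir.cla") files of a SCOPe-style release together with a protein FASTA
#' of domain sequences, and assembles them into a rooted hierarchy.
#'
#' The description file has one row per node: `sunid`, level code (`cl`
#' class, `cf` fold, `sf` superfamily, `fa` family, `px` domain), `sccs`
#' dotted label, identifier, free-text description. Comment lines start
#' with `#`; trailing extra columns are tolerated. Parentage is derived
#' from the `sccs` prefix structure (family `b.6.1.3` hangs under
#' superfamily `b.6.1`, and so on); domain rows attach to the family whose
#' `sccs` they carry, with the classification file's lineage column
#' (`cl=..,cf=..,sf=..,fa=..`) taking precedence when present. A synthetic
#' root with sunid 0 is added above the classes.
#'
#' @param cla_text Character scalar (or vector of lines) with the
#'   classification table; may be a file path.
#' @param des_text Character scalar/lines with the description table; may
#'   be a file path.
#' @param fasta_text Protein FASTA text (or path) whose ids match domain
#'   identifiers.
#' @return An object of class `Hierarchy`: a list with `nodes` (data frame
#'   of sunid, level, sccs, sid, description, parent_sunid, has_seq),
#'   `sequences` (named character, one per sequence-bearing domain),
#'   `root` (sunid 0) and `missing_parents` (sunids whose parent could not
#'   be resolved).
#' @export
parse_hierarchy <- function(cla_text, des_text, fasta_text = NULL) {
  des <- .read_lines_arg(des_text)
  cla <- .read_lines_arg(cla_text)

  keep <- !grepl("^\\s*#", des) & nzchar(trimws(des))
  rows <- des[keep]
  lineno <- which(keep)
  nodes <- list()
  if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 5)) {
      bad <- which(nf < 5)[1]
      stop("malformed description row at line ", lineno[bad],
           ": expected >= 5 tab-separated fields, got ", nf[bad])
    }
    level_code <- vapply(parts, `[[`, "", 2)
    known <- c(cl = "class", cf = "fold", sf = "superfamily",
               fa = "family", px = "domain")
    if (any(!level_code %in% names(known))) {
      bad <- which(!level_code %in% names(known))[1]
      stop("malformed description row at line ", lineno[bad],
           ": unknown level code '", level_code[bad], "'")
    }
    sunid <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
    if (anyNA(sunid)) {
      bad <- which(is.na(sunid))[1]
      stop("malformed description row at line ", lineno[bad],
           ": non-integer sunid")
    }
    nodes <- data.frame(
      sunid = sunid,
      level = unname(known[level_code]),
      sccs = .norm_sccs(vapply(parts, `[[`, "", 3)),
      sid = vapply(parts, `[[`, "", 4),
      description = vapply(parts, `[[`, "", 5),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(nodes$sunid)) {
      dup <- nodes$sunid[duplicated(nodes$sunid)][1]
      stop("duplicate sunid in description file: ", dup)
    }
  } else {
    nodes <- data.frame(sunid = integer(), level = character(),
                        sccs = character(), sid = character(),
                        description = character(), stringsAsFactors = FALSE)
  }

  root <- data.frame(sunid = 0L, level = "root", sccs = "",
                     sid = "-", description = "root",
                     stringsAsFactors = FALSE)
  nodes <- rbind(root, nodes)

  # parentage from sccs structure
  parent <- rep(NA_integer_, nrow(nodes))
  sccs_of <- function(level) {
    idx <- nodes$level == level
    stats::setNames(nodes$sunid[idx], nodes$sccs[idx])
  }
  cls <- sccs_of("class"); fld <- sccs_of("fold"); sfm <- sccs_of("superfamily")
  fam <- sccs_of("family")
  parent_sccs <- sub("\\.[^.]+$", "", nodes$sccs)
  for (i in seq_len(nrow(nodes))) {
    parent[i] <- switch(nodes$level[i],
      root = NA_integer_,
      class = 0L,
      fold = unname(cls[parent_sccs[i]]),
      superfamily = unname(fld[parent_sccs[i]]),
      family = unname(sfm[parent_sccs[i]]),
      domain = unname(fam[nodes$sccs[i]])
    )
  }

  # classification rows can pin a domain to an explicit family sunid
  ckeep <- !grepl("^\\s*#", cla) & nzchar(trimws(cla))
  crows <- cla[ckeep]
  clineno <- which(ckeep)
  if (length(crows)) {
    cparts <- strsplit(crows, "\t", fixed = TRUE)
    cnf <- lengths(cparts)
    if (any(cnf < 5)) {
      bad <- which(cnf < 5)[1]
      stop("malformed classification row at line ", clineno[bad],
           ": expected >= 5 tab-separated fields, got ", cnf[bad])
    }
    csid <- vapply(cparts, `[[`, "", 1)
    clineage <- vapply(cparts, `[[`, "", 5)
    fa_sunid <- suppressWarnings(as.integer(
      sub(".*fa=([0-9]+).*", "\\1", clineage)))
    hit <- match(csid, nodes$sid)
    ok <- !is.na(hit) & !is.na(fa_sunid) & nodes$level[hit] == "domain"
    parent[hit[ok]] <- fa_sunid[ok]
  }

  missing_parents <- nodes$sunid[nodes$level != "root" &
    (is.na(parent[seq_len(nrow(nodes))]) |
       !(parent %in% nodes$sunid) & !is.na(parent))]
  nodes$parent_sunid <- parent

  seqs <- character(0)
  if (!is.null(fasta_text)) seqs <- .read_protein_fasta(fasta_text)
  nodes$has_seq <- nodes$level == "domain" & nodes$sid %in% names(seqs)
  n_noseq <- sum(nodes$level == "domain" & !nodes$has_seq)
  if (n_noseq > 0)
    warning(n_noseq, " domain node(s) without a sequence; retained and flagged")

  structure(list(nodes = nodes, sequences = seqs, root = 0L,
                 missing_parents = missing_parents),
            class = "Hierarchy")
}

#' @export
print.Hierarchy <- function(x, ...) {
  tab <- table(factor(x$nodes$level,
                      c("root", "class", "fold", "superfamily",
                        "family", "domain")))
  cat("Hierarchy:", nrow(x$nodes), "nodes (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  sequences:", length(x$sequences), "\n")
  invisible(x)
}

.norm_sccs <- function(x) {
  x[x %in% c("-", "NA")] <- ""
  x
}

.read_lines_arg <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

.read_protein_fasta <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf))
    writeLines(.read_lines_arg(x), tf)
    ss <- Biostrings::readAAStringSet(tf)
  }
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Expand seed sunids to their domain-level descendants
#'
#' Recursively traverses the hierarchy from each seed and collects the
#' identifiers of every domain-level node below it (a domain seed expands
#' to itself). The union is returned deduplicated, ordered by ascending
#' domain sunid.
#'
#' @param h A `Hierarchy`.
#' @param seeds Integer vector of sunids present in `h`.
#' @return Character vector of domain identifiers (`sid`).
#' @export
expand_sunids <- function(h, seeds) {
  stopifnot(inherits(h, "Hierarchy"))
  seeds <- as.integer(seeds)
  unknown <- setdiff(seeds, h$nodes$sunid)
  if (length(unknown))
    stop("unknown seed sunid(s): ", paste(unknown, collapse = ", "))
  kids <- split(h$nodes$sunid, h$nodes$parent_sunid)
  acc <- integer(0)
  frontier <- seeds
  while (length(frontier)) {
    acc <- c(acc, frontier)
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
  }
  acc <- unique(acc)
  idx <- h$nodes$sunid %in% acc & h$nodes$level == "domain"
  dom <- h$nodes[idx, , drop = FALSE]
  dom <- dom[order(dom$sunid), , drop = FALSE]
  dom$sid
}

#' Build the Fe/Cu metalloprotein reference set
#'
#' Expands Fe and Cu seed sunids to domain sequences, labels each entry
#' with its family `sccs` and metal, and removes whole families given as
#' exclusions (e.g. the Fe regulatory protein aconitase, family
#' `c.83.1.1`, which is excluded by default downstream to keep the
#' inventory restricted to catalytic Fe proteins). A domain reachable from
#' both an Fe and a Cu seed is kept once per metal and flagged
#' `dual_metal`.
#'
#' @param h A `Hierarchy`.
#' @param fe_seeds,cu_seeds Integer sunid vectors (either may be empty).
#' @param exclusions Character vector of family `sccs` strings to drop.
#' @return A `MetalReference`: list with `entries` (data frame of
#'   protein_id, family_sccs, metal, sequence, description, dual_metal)
#'   and `excluded_families` (data frame of sccs, reason, n_removed).
#' @export
build_metal_reference <- function(h, fe_seeds, cu_seeds,
                                  exclusions = character(0)) {
  stopifnot(inherits(h, "Hierarchy"))
  one_metal <- function(seeds, metal) {
    ids <- if (length(seeds)) expand_sunids(h, seeds) else character(0)
    idx <- match(ids, h$nodes$sid)
    data.frame(
      protein_id = ids,
      family_sccs = h$nodes$sccs[idx],
      metal = rep(metal, length(ids)),
      sequence = unname(h$sequences[ids]),
      description = h$nodes$description[idx],
      stringsAsFactors = FALSE
    )
  }
  entries <- rbind(one_metal(fe_seeds, "Fe"), one_metal(cu_seeds, "Cu"))
  entries$dual_metal <- entries$protein_id %in%
    entries$protein_id[duplicated(entries$protein_id)]

  exclusions <- unique(exclusions)
  n_rm <- vapply(exclusions, function(s) sum(entries$family_sccs == s), 0L)
  if (any(n_rm == 0)) {
    warning("exclusion(s) matched no reference entries: ",
            paste(exclusions[n_rm == 0], collapse = ", "))
  }
  entries <- entries[!entries$family_sccs %in% exclusions, , drop = FALSE]
  rownames(entries) <- NULL
  excluded <- data.frame(sccs = exclusions,
                         reason = rep("user exclusion", length(exclusions)),
                         n_removed = as.integer(n_rm),
                         stringsAsFactors = FALSE)
  structure(list(entries = entries, excluded_families = excluded),
            class = "MetalReference")
}

#' @export
print.MetalReference <- function(x, ...) {
  cat("MetalReference:", nrow(x$entries), "entries (",
      sum(x$entries$metal == "Fe"), "Fe /",
      sum(x$entries$metal == "Cu"), "Cu ),",
      length(unique(x$entries$family_sccs)), "families\n")
  if (nrow(x$excluded_families))
    cat("  excluded families:",
        paste(x$excluded_families$sccs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a metal reference as FASTA
#'
#' Header convention: `>protein_id|family_sccs|metal description`.
#'
#' @param ref A `MetalReference`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "MetalReference"))
  e <- ref$entries
  hdr <- paste0(e$protein_id, "|", e$family_sccs, "|", e$metal, " ",
                e$description)
  ss <- Biostrings::AAStringSet(e$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a metal reference back from FASTA
#'
#' Inverse of [write_reference_fasta()]; reconstructs entries from the
#' `>protein_id|family_sccs|metal description` headers.
#'
#' @param path FASTA file path.
#' @return A `MetalReference` (with empty exclusion table).
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  hdr <- names(ss)
  id_part <- sub("\\s.*$", "", hdr)
  desc <- sub("^\\S+\\s*", "", hdr)
  bits <- strsplit(id_part, "|", fixed = TRUE)
  if (any(lengths(bits) != 3))
    stop("malformed reference header(s); expected protein_id|family_sccs|metal")
  entries <- data.frame(
    protein_id = vapply(bits, `[[`, "", 1),
    family_sccs = vapply(bits, `[[`, "", 2),
    metal = vapply(bits, `[[`, "", 3),
    sequence = unname(as.character(ss)),
    description = desc,
    stringsAsFactors = FALSE
  )
  entries$dual_metal <- entries$protein_id %in%
    entries$protein_id[duplicated(entries$protein_id)]
  structure(list(entries = entries,
                 excluded_families = data.frame(sccs = character(),
                                                reason = character(),
                                                n_removed = integer(),
                                                stringsAsFactors = FALSE)),
            class = "MetalReference")
}

#' Read a seed-sunid list
#'
#' One sunid per line; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @return Integer vector of sunids.
#' @export
read_seed_list <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  as.integer(ln[nzchar(ln)])
}
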
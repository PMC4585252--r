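#' Search parameters for the translated local-alignment search
#'
#' Defaults emulate gapped BLASTX conventions: BLOSUM62, gap open 11,
#' gap extend 1, Karlin-Altschul lambda 0.267 and K 0.041, bit-score
#' cutoff 50 and e-value ceiling 0.1. The bit score of a raw alignment
#' score S is `(lambda * S - ln K) / ln 2`; the expectation is
#' `search_space * 2^-bits`, with the effective search space defaulting to
#' total reference residues times query peptide length.
#'
#' @param gap_open,gap_extend Positive affine gap penalties (a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param lambda,k Karlin-Altschul scale and constant (lambda > 0).
#' @param bit_cutoff Minimum bit score for a hit to be retained.
#' @param evalue_cutoff Maximum expectation for a hit to be retained.
#' @param search_space Effective search space (residues x residues); NULL
#'   means computed per query as total reference residues x query length.
#' @param mask_low_complexity Mask low-complexity tracts in nucleotide
#'   queries before translation (DUST-style; an approximation of a
#'   min-complexity pre-filter).
#' @return A `SearchParams` list.
#' @export
search_params <- function(gap_open = 11L, gap_extend = 1L,
                          lambda = 0.267, k = 0.041,
                          bit_cutoff = 50, evalue_cutoff = 0.1,
                          search_space = NULL,
                          mask_low_complexity = TRUE) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, k > 0, bit_cutoff >= 0)
  structure(list(substitution_matrix = "BLOSUM62",
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, k = k,
                 bit_cutoff = bit_cutoff, evalue_cutoff = evalue_cutoff,
                 search_space = search_space,
                 mask_low_complexity = mask_low_complexity),
            class = "SearchParams")
}

#' Bit score from a raw alignment score
#' @param raw_score Raw Smith-Waterman score(s).
#' @param p A `SearchParams`.
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, p = search_params()) {
  (p$lambda * raw_score - log(p$k)) / log(2)
}

# smallest integer raw score whose bit score clears the cutoff
.min_raw_for_bits <- function(p) {
  as.integer(ceiling((p$bit_cutoff * log(2) + log(p$k)) / p$lambda - 1e-9))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the forward strand from offsets 0..2; frames -1..-3
#' read the reverse complement likewise. Trailing partial codons are
#' dropped, codons containing N translate to `X`, and stop codons are
#' rendered `*` (the aligner never crosses a stop).
#'
#' @param seq A single nucleotide string over A/C/G/T/N.
#' @return Named character vector of six peptides
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
translate_six_frames <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (!nzchar(seq)) return(stats::setNames(rep("", 6), frames))
  seq <- toupper(seq)
  rev <- .revcomp_chr(seq)
  gc <- .genetic_code_vec()
  one <- function(s, off) {
    n <- nchar(s) - off
    n <- n - n %% 3
    if (n < 3) return("")
    starts <- seq.int(off + 1L, off + n, by = 3L)
    aa <- gc[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  out <- c(one(seq, 0L), one(seq, 1L), one(seq, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  stats::setNames(out, frames)
}

# standard genetic code as a codon -> amino-acid lookup; stops are '*',
# codons with N or other ambiguity fall through to NA (rendered X)
.genetic_code_env <- new.env(parent = emptyenv())
.genetic_code_vec <- function() {
  if (is.null(.genetic_code_env$gc))
    .genetic_code_env$gc <- Biostrings::GENETIC_CODE
  .genetic_code_env$gc
}

.revcomp_chr <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Optimal local alignment of two peptides
#'
#' Affine-gap Smith-Waterman under BLOSUM62 with deterministic traceback
#' (ties broken diagonal, then up, then left). Stop characters (`*`)
#' cannot appear inside an alignment.
#'
#' @param query_pep,subject Non-empty amino-acid strings.
#' @param p A `SearchParams`.
#' @return List with `raw_score`, `bit_score`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `pct_identity`, `aln_len`. A score of 0 yields
#'   zero coordinates and an empty alignment.
#' @export
align_local <- function(query_pep, subject, p = search_params()) {
  stopifnot(nzchar(query_pep), nzchar(subject))
  m <- .blosum62()
  r <- sw_align(query_pep, subject, m, rownames(m), p$gap_open, p$gap_extend)
  list(raw_score = r$score,
       bit_score = bit_score(r$score, p),
       q_start = r$q_start, q_end = r$q_end,
       s_start = r$s_start, s_end = r$s_end,
       pct_identity = if (r$aln_len > 0) 100 * r$n_ident / r$aln_len else 0,
       aln_len = r$aln_len)
}

#' DUST-style low-complexity masking
#'
#' Scores overlapping windows by triplet over-representation
#' (sum of c_t(c_t-1)/2 over triplet counts, divided by window length
#' minus 3) and replaces windows above `level` with N. A light stand-in
#' for a read-complexity pre-filter.
#'
#' @param seq Nucleotide string.
#' @param window Window size (nt).
#' @param level Masking threshold; the classic DUST cut is around 2.
#' @return Masked sequence.
#' @export
mask_low_complexity <- function(seq, window = 48L, level = 2) {
  n <- nchar(seq)
  if (n < 6) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  starts <- seq(1, max(1, n - window + 1), by = max(1, window %/% 2))
  mask <- rep(FALSE, n)
  for (s in starts) {
    e <- min(n, s + window - 1)
    w <- e - s + 1
    if (w < 6) next
    sub <- substring(seq, s, e)
    trip <- substring(sub, 1:(w - 2), 3:w)
    ct <- table(trip)
    sc <- sum(ct * (ct - 1) / 2) / (w - 3)
    if (sc > level) mask[s:e] <- TRUE
  }
  if (any(mask)) {
    chars[mask] <- "N"
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Quality-filter and merge paired reads
#'
#' Drops pairs in which either mate's mean Phred quality falls below
#' `phred_min`, then merges surviving pairs whose 3' ends overlap by at
#' least `min_overlap` bases with a mismatch fraction of at most
#' `max_mismatch_frac` (the overlap length minimising the mismatch
#' fraction is used; ties go to the longer overlap). Within the overlap
#' the higher-quality base wins and keeps its quality. Single-end input
#' (`r2 = NULL`) passes through the quality filter only.
#'
#' @param r1,r2 Read tables as returned by [read_fastq()]: data frames
#'   with `read_id`, `sequence`, `qualities` (Phred+33 string). `r2` may
#'   be NULL for single-end input.
#' @param phred_min Minimum mean Phred quality per mate.
#' @param min_overlap Minimum merge overlap in nt.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return Data frame of merged reads (`read_id`, `sequence`,
#'   `qualities`, `mate = "merged"`) with a `merge_stats` attribute
#'   (n_pairs, n_quality_fail, n_merge_fail, n_merged).
#' @export
quality_filter_merge <- function(r1, r2 = NULL, phred_min = 25,
                                 min_overlap = 10L,
                                 max_mismatch_frac = 0.25) {
  if (is.null(r2)) {
    q <- vapply(r1$qualities, .mean_phred, 0)
    out <- r1[q >= phred_min, , drop = FALSE]
    out$mate <- "unpaired"
    attr(out, "merge_stats") <- list(n_pairs = nrow(r1),
                                     n_quality_fail = sum(q < phred_min),
                                     n_merge_fail = 0L,
                                     n_merged = nrow(out),
                                     single_end = TRUE)
    message("single-end input: merging skipped")
    return(out)
  }
  if (nrow(r1) != nrow(r2) ||
      !all(.mate_stub(r1$read_id) == .mate_stub(r2$read_id)))
    stop("mate-order mismatch between r1 and r2")
  q1 <- vapply(r1$qualities, .mean_phred, 0)
  q2 <- vapply(r2$qualities, .mean_phred, 0)
  pass <- q1 >= phred_min & q2 >= phred_min
  merged <- vector("list", sum(pass))
  nfail <- 0L
  k <- 0L
  for (i in which(pass)) {
    m <- .merge_pair(r1$sequence[i], r1$qualities[i],
                     r2$sequence[i], r2$qualities[i],
                     min_overlap, max_mismatch_frac)
    if (is.null(m)) { nfail <- nfail + 1L; next }
    k <- k + 1L
    merged[[k]] <- data.frame(read_id = .mate_stub(r1$read_id[i]),
                              sequence = m$seq, qualities = m$qual,
                              mate = "merged", stringsAsFactors = FALSE)
  }
  out <- if (k) do.call(rbind, merged[seq_len(k)]) else
    data.frame(read_id = character(), sequence = character(),
               qualities = character(), mate = character(),
               stringsAsFactors = FALSE)
  attr(out, "merge_stats") <- list(n_pairs = nrow(r1),
                                   n_quality_fail = sum(!pass),
                                   n_merge_fail = nfail,
                                   n_merged = k, single_end = FALSE)
  out
}

.mean_phred <- function(qual) {
  mean(utf8ToInt(qual) - 33L)
}

.mate_stub <- function(id) sub("/[12]$", "", id)

.merge_pair <- function(s1, q1, s2, q2, min_overlap, max_mm) {
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s2)))
  rq2 <- paste(rev(strsplit(q2, "", fixed = TRUE)[[1]]), collapse = "")
  n1 <- nchar(s1); n2 <- nchar(rc2)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(rc2, "", fixed = TRUE)[[1]]
  if (min(n1, n2) < min_overlap) return(NULL)
  best <- NULL
  for (v in seq(min(n1, n2), min_overlap)) {
    a <- c1[(n1 - v + 1):n1]
    b <- c2[1:v]
    mm <- sum(a != b) / v
    if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
      best <- list(v = v, mm = mm)
      if (mm == 0) break
    }
  }
  if (is.null(best)) return(NULL)
  v <- best$v
  p1 <- utf8ToInt(q1) - 33L
  p2 <- utf8ToInt(rq2) - 33L
  ov_seq <- character(v); ov_q <- integer(v)
  for (j in seq_len(v)) {
    i1 <- n1 - v + j
    if (c1[i1] == c2[j] || p1[i1] >= p2[j]) {
      ov_seq[j] <- c1[i1]; ov_q[j] <- max(p1[i1], p2[j])
    } else {
      ov_seq[j] <- c2[j]; ov_q[j] <- p2[j]
    }
  }
  seq <- paste0(substring(s1, 1, n1 - v), paste(ov_seq, collapse = ""),
                substring(rc2, v + 1, n2))
  qual <- paste0(substring(q1, 1, n1 - v),
                 intToUtf8(ov_q + 33L),
                 substring(rq2, v + 1, n2))
  list(seq = seq, qual = qual)
}

#' Search reads against a metal reference
#'
#' For nucleotide input each read is translated in six frames (after
#' optional low-complexity masking) and every frame is aligned against
#' every reference entry; hits with bit score at or above
#' `p$bit_cutoff` and e-value at or below `p$evalue_cutoff` are kept.
#' Protein input (`type = "protein"`, genome mode) skips translation and
#' reports frame 0.
#'
#' @param reads Data frame with `read_id` and `sequence` (and optionally
#'   `qualities`); for protein mode, amino-acid sequences.
#' @param ref A `MetalReference`.
#' @param p A `SearchParams`.
#' @param type `"nucleotide"` or `"protein"`.
#' @return A `SearchHit` data frame: query_id, subject_id, family_sccs,
#'   metal, raw_score, bit_score, evalue, pct_identity, q_start, q_end,
#'   s_start, s_end, frame, subject_description.
#' @export
search_reads <- function(reads, ref, p = search_params(),
                         type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  stopifnot(inherits(ref, "MetalReference"))
  if (nrow(ref$entries) == 0) stop("reference is empty")
  if (nrow(reads) == 0) return(.empty_hits())

  if (type == "nucleotide") {
    seqs <- reads$sequence
    if (isTRUE(p$mask_low_complexity))
      seqs <- vapply(seqs, mask_low_complexity, "", USE.NAMES = FALSE)
    frames <- lapply(seqs, translate_six_frames)
    qpep <- unlist(frames, use.names = FALSE)
    qread <- rep(seq_len(nrow(reads)), each = 6)
    qframe <- rep(c(1L, 2L, 3L, -1L, -2L, -3L), nrow(reads))
    keep <- nchar(qpep) >= 5
    qpep <- qpep[keep]; qread <- qread[keep]; qframe <- qframe[keep]
  } else {
    qpep <- reads$sequence
    qread <- seq_len(nrow(reads))
    qframe <- rep(0L, nrow(reads))
  }
  if (length(qpep) == 0) return(.empty_hits())

  m <- .blosum62()
  res <- sw_search(qpep, ref$entries$sequence, m, rownames(m),
                   p$gap_open, p$gap_extend, .min_raw_for_bits(p))
  if (length(res$query_idx) == 0) return(.empty_hits())

  bits <- bit_score(res$raw_score, p)
  qi <- res$query_idx; si <- res$subject_idx
  space <- if (is.null(p$search_space)) {
    sum(nchar(ref$entries$sequence)) * nchar(qpep[qi])
  } else rep(p$search_space, length(qi))
  ev <- space * 2^(-bits)
  keep <- bits >= p$bit_cutoff & ev <= p$evalue_cutoff
  hits <- data.frame(
    query_id = reads$read_id[qread[qi]],
    subject_id = ref$entries$protein_id[si],
    family_sccs = ref$entries$family_sccs[si],
    metal = ref$entries$metal[si],
    raw_score = res$raw_score,
    bit_score = bits,
    evalue = ev,
    pct_identity = ifelse(res$aln_len > 0,
                          100 * res$n_ident / res$aln_len, 0),
    q_start = res$q_start, q_end = res$q_end,
    s_start = res$s_start, s_end = res$s_end,
    frame = qframe[qi],
    subject_description = ref$entries$description[si],
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  if (!is.null(ref$entries$tax_id))
    hits$subject_tax_id <- ref$entries$tax_id[si][keep]
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             family_sccs = character(), metal = character(),
             raw_score = integer(), bit_score = numeric(),
             evalue = numeric(), pct_identity = numeric(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(), frame = integer(),
             subject_description = character(), stringsAsFactors = FALSE)
}

#' Parse externally produced 12-column tabular hits
#'
#' Accepts the common tabular alignment dialect (query, subject,
#' pct_identity, length, mismatches, gapopens, qstart, qend, sstart,
#' send, evalue, bitscore) and joins rows to the reference by subject id
#' to recover family and metal. Rows naming unknown subjects are dropped;
#' their count is attached as attribute `n_unknown_subject`.
#'
#' @param text Tabular text, lines, or a file path.
#' @param ref A `MetalReference`.
#' @return A `SearchHit` data frame (raw_score is NA for external hits).
#' @export
parse_tabular_hits <- function(text, ref) {
  stopifnot(inherits(ref, "MetalReference"))
  ln <- .read_lines_arg(text)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (!length(ln)) {
    out <- .empty_hits(); attr(out, "n_unknown_subject") <- 0L
    return(out)
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop("tabular hit parse error at line ", bad, ": expected 12 columns, got ",
         nf[bad])
  }
  g <- function(j) vapply(parts, `[[`, "", j)
  subj <- g(2)
  idx <- match(subj, ref$entries$protein_id)
  unknown <- sum(is.na(idx))
  if (unknown > 0)
    warning(unknown, " hit row(s) with subjects absent from the reference dropped")
  keep <- !is.na(idx)
  idx <- idx[keep]
  hits <- data.frame(
    query_id = g(1)[keep],
    subject_id = subj[keep],
    family_sccs = ref$entries$family_sccs[idx],
    metal = ref$entries$metal[idx],
    raw_score = rep(NA_integer_, sum(keep)),
    bit_score = as.numeric(g(12))[keep],
    evalue = as.numeric(g(11))[keep],
    pct_identity = as.numeric(g(3))[keep],
    q_start = as.integer(g(7))[keep], q_end = as.integer(g(8))[keep],
    s_start = as.integer(g(9))[keep], s_end = as.integer(g(10))[keep],
    frame = rep(NA_integer_, sum(keep)),
    subject_description = ref$entries$description[idx],
    stringsAsFactors = FALSE
  )
  attr(hits, "n_unknown_subject") <- unknown
  hits
}

#' Write hits in the 12-column tabular dialect plus family and metal
#' @param hits A `SearchHit` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    query = hits$query_id, subject = hits$subject_id,
    pct_identity = sprintf("%.2f", hits$pct_identity),
    length = abs(hits$q_end - hits$q_start) + 1L,
    mismatches = NA_integer_, gapopens = NA_integer_,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", hits$bit_score),
    family_sccs = hits$family_sccs, metal = hits$metal,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read FASTQ into a read table
#' @param path FASTQ path (gzip transparent).
#' @return Data frame with read_id, sequence, qualities, mate.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             sequence = unname(as.character(ss)),
             qualities = unname(as.character(Biostrings::quality(ss))),
             mate = "unpaired", stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#' @param reads Data frame with read_id, sequence, qualities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qualities)
  qs <- Biostrings::QualityScaledDNAStringSet(ss, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}
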
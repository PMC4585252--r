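test_that("six-frame translation agrees with an independent codon walk", {
  expect_equal(unname(translate_six_frames("ATGGCC")["+1"]), "MA")
  # strand symmetry: frame -1 of the reverse complement = frame +1
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_equal(unname(translate_six_frames(rc)["-1"]),
                 unname(translate_six_frames(s)["+1"]))
    # oracle: seqinr's codon-table translation, frame by frame
    for (f in 0:2) {
      ours <- unname(translate_six_frames(s)[paste0("+", f + 1)])
      theirs <- paste(seqinr::translate(strsplit(s, "")[[1]], frame = f),
                      collapse = "")
      expect_equal(ours, theirs)
    }
  }
  # N-containing codons become X; empty input gives six empty frames
  expect_equal(unname(translate_six_frames("ATGNNN")["+1"]), "MX")
  expect_equal(unname(translate_six_frames("")), rep("", 6))
})

test_that("local alignment matches the full-DP oracle and its identities", {
  p <- search_params()
  mat <- blosum62_int()
  # self-alignment score is the sum of diagonal matrix values
  pep <- "HEAGAWGHEE"
  self_sum <- sum(diag(mat[strsplit(pep, "")[[1]], strsplit(pep, "")[[1]]]))
  expect_equal(align_local(pep, pep, p)$raw_score, self_sum)
  expect_equal(align_local(pep, pep, p)$pct_identity, 100)
  # all-negative substitution pair floors at zero with empty alignment
  r0 <- align_local("AAAA", "WWWW", p)
  expect_equal(r0$raw_score, 0)
  expect_equal(r0$aln_len, 0)
  # random pairs against the quadratic DP oracle
  set.seed(99)
  for (i in 1:40) {
    q <- random_peptide(sample(5:30, 1))
    s <- random_peptide(sample(5:30, 1))
    expect_equal(align_local(q, s, p)$raw_score,
                 sw_score_oracle(q, s, mat),
                 info = paste(q, s))
  }
})

test_that("bit scores are monotone in raw score and gate the search", {
  p <- search_params()
  raws <- sort(sample(1:500, 50))
  bits <- bit_score(raws, p)
  expect_true(all(diff(bits) > 0))
  # the integer raw threshold brackets the 50-bit cutoff exactly
  min_raw <- metfam:::.min_raw_for_bits(p)
  expect_lt(bit_score(min_raw - 1, p), 50)
  expect_gte(bit_score(min_raw, p), 50)
})

test_that("quality filtering and merging follow the pair contract", {
  s <- strrep("ACGT", 25)
  q30 <- strrep("?", 100) # Phred 30
  q20 <- strrep("5", 100) # Phred 20
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  # identical fully-overlapping mates at Q30 merge into one 100-nt read
  r1 <- data.frame(read_id = "p1/1", sequence = s, qualities = q30)
  r2 <- data.frame(read_id = "p1/2", sequence = rc, qualities = q30)
  m <- quality_filter_merge(r1, r2, phred_min = 25)
  expect_equal(nrow(m), 1)
  expect_equal(nchar(m$sequence), 100)
  expect_equal(m$sequence, s)
  # mean quality 20 at threshold 25 is dropped and counted
  r1b <- data.frame(read_id = "p1/1", sequence = s, qualities = q20)
  mb <- quality_filter_merge(r1b, r2, phred_min = 25)
  expect_equal(nrow(mb), 0)
  expect_equal(attr(mb, "merge_stats")$n_quality_fail, 1)
  # 10 pairs: 3 below threshold, 7 overlapping cleanly -> 7 merged
  mk <- function(n, qual) data.frame(
    read_id = paste0("p", seq_len(n), "/1"),
    sequence = rep(s, n), qualities = rep(qual, n))
  r1c <- mk(10, q30); r1c$qualities[c(2, 5, 9)] <- q20
  r2c <- mk(10, q30); r2c$sequence <- rc
  r2c$read_id <- sub("/1", "/2", r2c$read_id)
  mc <- quality_filter_merge(r1c, r2c, phred_min = 25)
  expect_equal(nrow(mc), 7)
  expect_equal(attr(mc, "merge_stats")$n_quality_fail, 3)
  # mate-order mismatch errors
  expect_error(quality_filter_merge(r1, r2[0, ]), "mate-order")
  # single-end input bypasses merging with a note
  expect_message(ms <- quality_filter_merge(r1, NULL), "single-end")
  expect_equal(nrow(ms), 1)
})

test_that("partially overlapping mates merge with quality-weighted consensus", {
  # fragment of 30 nt, mates of 20 nt -> overlap 10
  frag <- "ACGTACGTACGTACGTACGTTGCATGCATG"
  r1s <- substr(frag, 1, 20)
  r2s_fwd <- substr(frag, 11, 30)
  r2s <- paste(rev(strsplit(chartr("ACGT", "TGCA", r2s_fwd), "")[[1]]),
               collapse = "")
  r1 <- data.frame(read_id = "f/1", sequence = r1s,
                   qualities = strrep("?", 20))
  r2 <- data.frame(read_id = "f/2", sequence = r2s,
                   qualities = strrep("?", 20))
  m <- quality_filter_merge(r1, r2, phred_min = 25, min_overlap = 10)
  expect_equal(m$sequence, frag)
})

test_that("planted reads are recovered and hits obey the bit cutoff", {
  env <- make_test_reference(seed = 21)
  ref <- env$ref
  sim <- simulate_reads(ref, sim_config(seed = 21, n_reads = 40,
                                        substitution_rate = 0))
  hits <- search_reads(sim$reads, ref)
  expect_true(all(hits$bit_score >= 50))
  expect_true(all(hits$evalue <= 0.1))
  # every read recovers its source entry as (a) top hit at 100% identity
  top <- do.call(rbind, lapply(split(hits, hits$query_id), function(h)
    h[which.max(h$bit_score), ]))
  truth <- stats::setNames(sim$truth$family_sccs, sim$truth$read_id)
  expect_true(all(top$family_sccs == truth[top$query_id]))
  expect_gte(mean(top$pct_identity == 100), 0.99)
  expect_equal(sort(unique(hits$query_id)), sort(sim$truth$read_id))
})

test_that("random reads produce no hits at the 50-bit cutoff", {
  env <- make_test_reference(seed = 22)
  set.seed(22)
  rand <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    sequence = vapply(1:100, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), ""),
    stringsAsFactors = FALSE)
  hits <- search_reads(rand, env$ref)
  expect_equal(nrow(hits), 0)
})

test_that("protein-mode search equals nucleotide-mode on the same peptide", {
  env <- make_test_reference(seed = 23)
  ref <- env$ref
  sim <- simulate_reads(ref, sim_config(seed = 23, n_reads = 10,
                                        substitution_rate = 0))
  p <- search_params(mask_low_complexity = FALSE)
  nuc <- search_reads(sim$reads, ref, p, type = "nucleotide")
  prot <- search_reads(
    data.frame(read_id = sim$truth$read_id, sequence = sim$truth$peptide,
               stringsAsFactors = FALSE),
    ref, p, type = "protein")
  expect_true(all(prot$frame == 0))
  key <- function(h) paste(h$query_id, h$subject_id)
  shared <- intersect(key(nuc), key(prot))
  expect_true(length(shared) > 0)
  expect_equal(nuc$raw_score[match(shared, key(nuc))],
               prot$raw_score[match(shared, key(prot))])
})

test_that("tabular hit parsing joins, drops unknowns and checks shape", {
  env <- make_test_reference(seed = 24)
  ref <- env$ref
  known <- ref$entries$protein_id[1]
  row12 <- function(q, s) paste(q, s, "98.5", "40", "1", "0", "1", "40",
                                "5", "44", "1e-12", "75.0", sep = "\t")
  one <- parse_tabular_hits(row12("readA", known), ref)
  expect_equal(nrow(one), 1)
  expect_equal(one$family_sccs, ref$entries$family_sccs[1])
  expect_equal(one$bit_score, 75)

  expect_warning(none <- parse_tabular_hits(row12("readA", "nope"), ref),
                 "absent")
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_unknown_subject"), 1)

  # 100-row fixture with 7 unknown subjects -> 93 hits
  subj <- rep(ref$entries$protein_id, length.out = 100)
  subj[c(3, 10, 20, 40, 60, 80, 99)] <- "unknownX"
  txt <- paste(mapply(row12, sprintf("q%03d", 1:100), subj), collapse = "\n")
  expect_warning(hits <- parse_tabular_hits(txt, ref), "7")
  expect_equal(nrow(hits), 93)

  expect_error(parse_tabular_hits("a\tb\tc", ref), "12 columns")
})

test_that("hit tables round-trip through the tabular writer", {
  env <- make_test_reference(seed = 25)
  sim <- simulate_reads(env$ref, sim_config(seed = 25, n_reads = 10,
                                            substitution_rate = 0))
  hits <- search_reads(sim$reads, env$ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  back <- parse_tabular_hits(paste(
    apply(utils::read.table(path, sep = "\t")[, 1:12], 1, paste,
          collapse = "\t"), collapse = "\n"), env$ref)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$family_sccs, hits$family_sccs)
})
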
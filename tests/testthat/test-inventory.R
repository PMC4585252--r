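mk_hits <- function(query, family, bits, metal = "Cu", desc = "") {
  data.frame(query_id = query, subject_id = paste0("d", seq_along(query)),
             family_sccs = family, metal = metal, raw_score = NA_integer_,
             bit_score = bits, evalue = 1e-10, pct_identity = 100,
             q_start = 1L, q_end = 10L, s_start = 1L, s_end = 10L,
             frame = 1L, subject_description = desc,
             stringsAsFactors = FALSE)
}

test_that("top-hit weights follow the 1/k equal-bit rule", {
  # singleton
  one <- assign_top_hits(mk_hits("q1", "f", 80))
  expect_equal(one$weight, 1)
  # two tied at 75.0, third at 60.2 -> two parts at 0.5
  two <- assign_top_hits(mk_hits(rep("q1", 3), c("f", "g", "h"),
                                 c(75.0, 75.0, 60.2)))
  expect_equal(nrow(two), 2)
  expect_equal(two$weight, c(0.5, 0.5))
  expect_setequal(two$label, c("f", "g"))
  # rounded bits {80.1 x3, 79.9, 60.0} -> three parts at 1/3
  five <- assign_top_hits(mk_hits(rep("q1", 5), letters[1:5],
                                  c(80.1, 80.1, 80.1, 79.9, 60.0)))
  expect_equal(nrow(five), 3)
  expect_equal(five$weight, rep(1 / 3, 3))
  # exhaustive max-set oracle on random bit vectors
  set.seed(31)
  for (i in 1:20) {
    bits <- round(runif(7, 40, 90), 1)
    a <- assign_top_hits(mk_hits(rep("q", 7), letters[1:7], bits))
    k <- sum(round(bits, 1) == max(round(bits, 1)))
    expect_equal(nrow(a), k)
    expect_equal(sum(a$weight), 1)
    expect_setequal(a$label, letters[1:7][round(bits, 1) ==
                                            max(round(bits, 1))])
  }
  # ties are resolved per metal independently
  both <- rbind(mk_hits("q1", "f", 80, metal = "Cu"),
                mk_hits("q1", "g", 70, metal = "Fe"))
  a <- assign_top_hits(both)
  expect_equal(sum(a$weight[a$metal == "Cu"]), 1)
  expect_equal(sum(a$weight[a$metal == "Fe"]), 1)
})

test_that("cupredoxin splitting follows the ordered description rules", {
  a <- assign_top_hits(mk_hits(
    paste0("q", 1:3), rep("b.6.1.3", 3), rep(80, 3),
    desc = c("copper-containing nitrite reductase NirK",
             "multicopper oxidase CueO", "hypothetical protein")))
  s <- split_cupredoxins(a)
  expect_setequal(s$label, c("b.6.1.3/nirK", "b.6.1.3/MCO", "b.6.1.3"))
  # non-target families pass through unchanged
  b <- assign_top_hits(mk_hits("q9", "b.6.1.2", 70, desc = "plastocyanin"))
  expect_equal(split_cupredoxins(b)$label, "b.6.1.2")
  # 20 parts: 8 nirK-patterned, 9 MCO-patterned, 3 neither
  descs <- c(rep("nitrite reductase NirK-like", 8),
             c(rep("multicopper oxidase", 5), rep("laccase", 4)),
             rep("unannotated blue protein", 3))
  a20 <- assign_top_hits(mk_hits(paste0("q", 1:20), rep("b.6.1.3", 20),
                                 rep(80, 20), desc = descs))
  s20 <- split_cupredoxins(a20)
  expect_equal(as.integer(table(s20$label)[c("b.6.1.3/nirK", "b.6.1.3/MCO",
                                             "b.6.1.3")]),
               c(8L, 9L, 3L))
  # missing description warns and routes to neither
  am <- assign_top_hits(mk_hits("qx", "b.6.1.3", 80, desc = ""))
  expect_warning(sm <- split_cupredoxins(am), "without description")
  expect_equal(sm$label, "b.6.1.3")
})

test_that("aggregation conserves per-query weight exactly", {
  a4 <- assign_top_hits(mk_hits(paste0("q", 1:4), rep("f", 4), rep(80, 4)))
  expect_equal(aggregate_weights(a4, "Cu"), c(f = 4))
  asp <- assign_top_hits(mk_hits(rep(paste0("q", 1:2), each = 2),
                                 rep(c("f", "g"), 2), rep(80, 4)))
  expect_equal(aggregate_weights(asp, "Cu"), c(f = 1, g = 1))
  # 200-assignment fixture vs an independent flat summation
  set.seed(32)
  big <- do.call(rbind, lapply(1:200, function(i) {
    nf <- sample(1:4, 1)
    mk_hits(rep(paste0("q", i), nf), sample(letters[1:6], nf), rep(80, nf))
  }))
  a <- assign_top_hits(big)
  agg <- aggregate_weights(a, "Cu")
  flat <- tapply(a$weight[a$metal == "Cu"], a$label[a$metal == "Cu"], sum)
  expect_equal(agg, c(flat)[names(agg)])
  expect_equal(sum(agg), 200)
})

test_that("minor families merge into 'others' with exact conservation", {
  # boundary: exactly 4% is retained
  expect_equal(cluster_minor(c(f = 96, g = 4)), c(f = 96, g = 4))
  expect_equal(cluster_minor(c(f = 97, g = 3)), c(f = 97, others = 3))
  # unsplit b.6.1.3 remainder always merges
  expect_equal(cluster_minor(c(f = 50, b.6.1.3 = 50)),
               c(f = 50, others = 50))
  # all labels minor -> one "others" row equal to the total
  many <- stats::setNames(rep(1, 30), paste0("f", 1:30))
  expect_equal(cluster_minor(many), c(others = 30))
  # random fixtures vs brute-force filtering, totals conserved exactly
  set.seed(33)
  for (i in 1:10) {
    x <- stats::setNames(runif(12, 0, 10), paste0("f", 1:12))
    out <- cluster_minor(x, 0.04)
    keep <- x / sum(x) >= 0.04
    expect_setequal(names(out), c(names(x)[keep],
                                  if (any(!keep)) "others"))
    expect_identical(sum(out), sum(x))
  }
})

test_that("per-100k normalization is linear and homogeneous", {
  inv <- normalize_per_100k(c(f = 35), 100000)
  expect_equal(inv$per_100k[inv$label == "f"], 35)
  expect_equal(normalize_per_100k(c(f = 50), 200000)$per_100k[1], 25)
  # six labels, awkward denominator, checked by hand arithmetic
  x <- c(a = 3.5, b = 1.25, c = 10, d = 0.4, e = 7, f = 2)
  inv6 <- normalize_per_100k(x, 123456)
  expect_equal(inv6$per_100k[match(names(x), inv6$label)],
               unname(x) / 123456 * 1e5, tolerance = 1e-9)
  # totals row present and consistent
  expect_equal(inv6$weighted_count[inv6$label == "total"], sum(x))
  # homogeneity: doubling counts and denominator leaves per_100k fixed
  inv2 <- normalize_per_100k(2 * x, 2 * 123456)
  expect_equal(inv2$per_100k, inv6$per_100k)
  expect_error(normalize_per_100k(c(f = 10), 0), "positive")
  expect_error(normalize_per_100k(c(f = 10), 5), "smaller")
})

test_that("weights stay conserved through the whole inventory chain", {
  env <- make_test_reference(seed = 34)
  sim <- simulate_reads(env$ref, sim_config(seed = 34, n_reads = 150,
                                            substitution_rate = 0.01))
  hits <- search_reads(sim$reads, env$ref)
  a <- assign_top_hits(hits)
  n_q <- length(unique(paste(a$query_id, a$metal)))
  expect_equal(sum(a$weight), n_q, tolerance = 1e-9)
  s <- split_cupredoxins(a)
  expect_equal(sum(s$weight), n_q, tolerance = 1e-9)
  for (metal in c("Fe", "Cu")) {
    agg <- aggregate_weights(s, metal)
    if (length(agg) == 0) next
    cl <- cluster_minor(agg)
    expect_identical(sum(cl), sum(agg))
  }
})
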
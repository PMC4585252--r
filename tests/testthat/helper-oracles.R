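# Independent oracles used across the suite. These deliberately share no
# code with the package internals: plain-R dynamic programming, recursive
# tree walks, ancestor-set intersections and closed-form formulas.

# full quadratic affine-gap local-alignment DP, score only
sw_score_oracle <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  subsc <- function(a, b) {
    if (a == "*" || b == "*") return(-1e6)
    if (!a %in% rownames(mat)) a <- "X"
    if (!b %in% rownames(mat)) b <- "X"
    mat[a, b]
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                           E[i, j + 1] - gap_extend)
    F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                           F[i + 1, j] - gap_extend)
    H[i + 1, j + 1] <- max(0, H[i, j] + subsc(qc[i], sc[j]),
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# exhaustive recursive DFS collecting domain sids under a sunid
dfs_domains_oracle <- function(nodes, seed) {
  out <- character(0)
  walk <- function(id) {
    row <- nodes[nodes$sunid == id, , drop = FALSE]
    if (nrow(row) && row$level == "domain") out <<- c(out, row$sid)
    kids <- nodes$sunid[!is.na(nodes$parent_sunid) &
                          nodes$parent_sunid == id]
    for (k in kids) walk(k)
  }
  for (s in seed) walk(s)
  idx <- match(unique(out), nodes$sid)
  unique(out)[order(nodes$sunid[idx])]
}

# LCA by full ancestor-set intersection, deepest shared node by path depth
ancestors_oracle <- function(tax_id, taxonomy) {
  path <- integer(0)
  cur <- tax_id
  repeat {
    path <- c(path, cur)
    parent <- taxonomy$parent_id[taxonomy$tax_id == cur]
    if (length(parent) == 0 || parent == cur) break
    cur <- parent
  }
  path
}

lca_oracle <- function(tax_ids, taxonomy) {
  paths <- lapply(unique(tax_ids), ancestors_oracle, taxonomy)
  shared <- Reduce(intersect, paths)
  if (length(shared) == 0) return(NA_integer_)
  depth <- vapply(shared, function(t) length(ancestors_oracle(t, taxonomy)),
                  0L)
  shared[which.max(depth)]
}

# recursive permutation generator (distinct from the package's iterative
# matrix construction)
perms_oracle <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_oracle(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# mid-rank Pearson Spearman coefficient, written out long-hand
spearman_rho_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# total inertia of a count matrix = chi-square statistic / grand total
chisq_inertia_oracle <- function(X) {
  N <- sum(X)
  P <- X / N
  r <- rowSums(P); c <- colSums(P)
  E <- r %o% c
  sum((P - E)^2 / E)
}

# first constrained CCA eigenvalue for a single constraint, by direct
# weighted projection of the chi-square standardized matrix
cca_eig_oracle <- function(X, z) {
  P <- X / sum(X)
  r <- rowSums(P); c <- colSums(P)
  Qbar <- (P - r %o% c) / sqrt(r %o% c)
  zc <- z - sum(r * z) / sum(r)
  Y <- sqrt(r) * zc
  H <- (Y %*% t(Y)) / sum(Y * Y)
  Qfit <- H %*% Qbar
  max(svd(Qfit)$d^2)
}

# quick builder: small fixture hierarchy + reference for search tests
make_test_reference <- function(seed = 11, substitution_rate = 0,
                                n_reads = 50) {
  cfg <- sim_config(seed = seed, n_reads = n_reads,
                    substitution_rate = substitution_rate)
  fx <- make_hierarchy_fixture(cfg)
  h <- parse_hierarchy(fx$cla_text, fx$des_text, fx$fasta_text)
  ref <- build_metal_reference(
    h, fx$families$sunid[fx$families$metal == "Fe"],
    fx$families$sunid[fx$families$metal == "Cu"])
  list(cfg = cfg, fx = fx, h = h, ref = ref)
}

blosum62_int <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_peptide <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
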
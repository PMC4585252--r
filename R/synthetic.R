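#' Configuration for the synthetic-data generator
#'
#' Holds every knob for generating hierarchy fixtures, reads and
#' geochemical depth profiles. Defaults describe a small but complete
#' OMZ-like study: a handful of Fe and Cu fold families (always
#' including the multidomain cupredoxins b.6.1.3 with nirK- and
#' MCO-styled members, the aconitase family c.83.1.1 and the
#' heme-copper oxidase family f.24.1.1), merged-read-sized fragments
#' (120 nt) with a 1% substitution rate, and depth profiles in which O2
#' collapses to anoxia at the core, dissolved Fe rises sharply across
#' the oxic-anoxic transition and dissolved Cu stays within the
#' 0.9-1.6 nM band.
#'
#' @param seed Integer seed; every generator call derives all its
#'   randomness from it.
#' @param n_fe_families,n_cu_families Family counts (minimum 3 Fe /
#'   2 Cu, the mandatory families).
#' @param domains_per_family Length-2 integer range of domains per
#'   family.
#' @param protein_length Length-2 range of domain lengths (aa).
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length (nt); must fit three times into the
#'   shortest protein.
#' @param substitution_rate Per-base substitution probability in
#'   \[0, 1).
#' @param family_mixture Optional named fractions (per family sccs)
#'   summing to 1; NULL means uniform over reference families.
#' @param taxon_map Optional named integer vector mapping family sccs to
#'   tax ids; NULL uses the packaged fixture taxonomy convention
#'   (Fe families in Planctocandidatus-like taxa, Cu families in
#'   Thaumarchaeota-like taxa).
#' @param profile_noise Relative (lognormal) noise on the O2 and Fe
#'   depth curves; 0 gives the deterministic target curves.
#' @param dcu_range Band (nM) within which dissolved Cu is drawn.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_fe_families = 3L, n_cu_families = 2L,
                       domains_per_family = c(2L, 4L),
                       protein_length = c(90L, 180L),
                       n_reads = 500L, read_length = 120L,
                       substitution_rate = 0.01,
                       family_mixture = NULL, taxon_map = NULL,
                       profile_noise = 0.05, dcu_range = c(0.9, 1.6)) {
  stopifnot(n_fe_families >= 3, n_cu_families >= 2,
            length(domains_per_family) == 2,
            domains_per_family[1] >= 1,
            diff(domains_per_family) >= 0,
            protein_length[1] >= 30,
            n_reads > 0, read_length >= 30,
            substitution_rate >= 0, substitution_rate < 1,
            profile_noise >= 0, dcu_range[1] < dcu_range[2])
  if (!is.null(family_mixture)) {
    stopifnot(abs(sum(family_mixture) - 1) < 1e-9, all(family_mixture > 0))
  }
  structure(list(seed = as.integer(seed),
                 n_fe_families = as.integer(n_fe_families),
                 n_cu_families = as.integer(n_cu_families),
                 domains_per_family = as.integer(domains_per_family),
                 protein_length = as.integer(protein_length),
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 family_mixture = family_mixture,
                 taxon_map = taxon_map,
                 profile_noise = profile_noise,
                 dcu_range = dcu_range),
            class = "SimConfig")
}

# draw one integer from an inclusive range (safe when lo == hi)
.sample_range <- function(range) {
  v <- seq.int(range[1], range[2])
  if (length(v) == 1) v else sample(v, 1)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# background amino-acid frequencies (roughly Robinson-Robinson)
.aa_freq <- function() {
  c(A = 7.8, R = 5.1, N = 4.5, D = 5.4, C = 1.9, Q = 4.3, E = 6.3,
    G = 7.4, H = 2.2, I = 5.1, L = 9.1, K = 5.7, M = 2.2, F = 3.9,
    P = 5.2, S = 7.1, T = 5.8, W = 1.3, Y = 3.2, V = 6.4)
}

.random_protein <- function(len) {
  f <- .aa_freq()
  paste(sample(names(f), len, replace = TRUE, prob = f), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    f <- .aa_freq()
    for (i in hit) ch[i] <- sample(setdiff(names(f), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a parseable hierarchy fixture with known truth
#'
#' Emits SCOPe-dialect classification and description tables plus a
#' domain FASTA for a small class-to-domain tree. The mandatory
#' families b.6.1.3 (multidomain cupredoxins, with nirK-, MCO- and
#' unannotated-styled domain descriptions), b.6.1.2, c.81.1.1, c.83.1.1
#' (aconitase) and f.24.1.1 (heme-copper oxidase) are always present so
#' the description-splitting and exclusion rules can be exercised.
#' Domains within a family are mutated copies of a family ancestor
#' (about 10% substitutions), so within-family similarity is high and
#' between-family similarity is background.
#'
#' @param cfg A `SimConfig`.
#' @return List with `cla_text`, `des_text`, `fasta_text` (character
#'   scalars), `domains` (truth table: sid, sunid, family_sccs, metal,
#'   description, tax_id) and `families` (sccs, sunid, metal,
#'   n_domains).
#' @export
make_hierarchy_fixture <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  .with_seed(cfg$seed, {
    fe_sccs <- c("c.81.1.1", "c.83.1.1", "f.24.1.1")
    extra_fe <- if (cfg$n_fe_families > 3)
      sprintf("c.%d.1.1", 90 + seq_len(cfg$n_fe_families - 3)) else character(0)
    fe_sccs <- c(fe_sccs, extra_fe)
    cu_sccs <- c("b.6.1.3", "b.6.1.2")
    extra_cu <- if (cfg$n_cu_families > 2)
      sprintf("b.%d.1.1", 50 + seq_len(cfg$n_cu_families - 2)) else character(0)
    cu_sccs <- c(cu_sccs, extra_cu)

    fam_desc <- c(
      "c.81.1.1" = "aldehyde ferredoxin oxidoreductase",
      "c.83.1.1" = "aconitase iron-sulfur domain",
      "f.24.1.1" = "cytochrome c oxidase subunit I-like (heme-copper oxidase)",
      "b.6.1.3" = "multidomain cupredoxins",
      "b.6.1.2" = "plastocyanin/azurin-like"
    )
    b613_domain_desc <- c(
      "copper-containing nitrite reductase NirK",
      "multicopper oxidase CueO",
      "copper-containing nitrite reductase, NirK-type",
      "blue multidomain copper protein of unknown function"
    )

    all_sccs <- c(fe_sccs, cu_sccs)
    metal_of <- c(rep("Fe", length(fe_sccs)), rep("Cu", length(cu_sccs)))
    names(metal_of) <- all_sccs

    counter <- 10000L
    nxt <- function() { counter <<- counter + 1L; counter }
    des <- character(0)
    cla <- character(0)
    fasta <- character(0)
    node_sunid <- new.env()

    ensure <- function(sccs, level_code, desc) {
      key <- paste0(level_code, ":", sccs)
      if (!is.null(node_sunid[[key]])) return(node_sunid[[key]])
      id <- nxt()
      node_sunid[[key]] <- id
      des <<- c(des, paste(id, level_code, sccs, "-", desc, sep = "\t"))
      id
    }

    dom_rows <- list()
    fam_rows <- list()
    for (i in seq_along(all_sccs)) {
      sccs <- all_sccs[i]
      pieces <- strsplit(sccs, ".", fixed = TRUE)[[1]]
      cl_id <- ensure(pieces[1], "cl",
                      paste("class", pieces[1]))
      cf_id <- ensure(paste(pieces[1:2], collapse = "."), "cf",
                      paste("fold", paste(pieces[1:2], collapse = ".")))
      sf_id <- ensure(paste(pieces[1:3], collapse = "."), "sf",
                      paste("superfamily", paste(pieces[1:3], collapse = ".")))
      fdesc <- if (sccs %in% names(fam_desc)) fam_desc[[sccs]] else
        paste("synthetic", metal_of[[sccs]], "family", sccs)
      fa_id <- ensure(sccs, "fa", fdesc)

      n_dom <- .sample_range(cfg$domains_per_family)
      len <- .sample_range(cfg$protein_length)
      ancestor <- .random_protein(len)
      for (d in seq_len(n_dom)) {
        px_id <- nxt()
        sid <- sprintf("d%06d", px_id)
        ddesc <- if (sccs == "b.6.1.3")
          b613_domain_desc[(d - 1) %% length(b613_domain_desc) + 1]
        else paste(fdesc, "domain", d)
        des <- c(des, paste(px_id, "px", sccs, sid, ddesc, sep = "\t"))
        lineage <- sprintf("cl=%d,cf=%d,sf=%d,fa=%d,px=%d",
                           cl_id, cf_id, sf_id, fa_id, px_id)
        cla <- c(cla, paste(sid, "0xxx", sccs, px_id, lineage, sep = "\t"))
        seq <- .mutate_protein(ancestor, 0.10)
        fasta <- c(fasta, paste0(">", sid, " ", ddesc), seq)
        dom_rows[[length(dom_rows) + 1]] <- data.frame(
          sid = sid, sunid = px_id, family_sccs = sccs,
          metal = metal_of[[sccs]], description = ddesc,
          stringsAsFactors = FALSE)
      }
      fam_rows[[length(fam_rows) + 1]] <- data.frame(
        sccs = sccs, sunid = fa_id, metal = metal_of[[sccs]],
        n_domains = n_dom, stringsAsFactors = FALSE)
    }
    domains <- do.call(rbind, dom_rows)
    families <- do.call(rbind, fam_rows)

    tmap <- cfg$taxon_map
    if (is.null(tmap)) tmap <- .default_taxon_map(families)
    domains$tax_id <- unname(tmap[domains$family_sccs])

    list(cla_text = paste(c("# synthetic classification", cla),
                          collapse = "\n"),
         des_text = paste(c("# synthetic descriptions", des),
                          collapse = "\n"),
         fasta_text = paste(fasta, collapse = "\n"),
         domains = domains, families = families)
  })
}

# Fe families on the Planctomycetes side of the fixture taxonomy,
# Cu families on the Thaumarchaeota side (species-level leaves)
.default_taxon_map <- function(families) {
  fe <- families$sccs[families$metal == "Fe"]
  cu <- families$sccs[families$metal == "Cu"]
  fe_leaves <- c(2101L, 2102L, 2103L, 2104L)
  cu_leaves <- c(3101L, 3102L, 3103L, 3104L)
  stats::setNames(
    c(fe_leaves[(seq_along(fe) - 1) %% length(fe_leaves) + 1],
      cu_leaves[(seq_along(cu) - 1) %% length(cu_leaves) + 1]),
    c(fe, cu))
}

#' Write the packaged ~40-node fixture taxonomy
#'
#' A small NCBI-dialect taxonomy (root, two superkingdoms, four phyla
#' including Planctomycetes and Thaumarchaeota, and genus/species
#' leaves) used by tests and the demo pipeline. Entirely synthetic ids
#' below the phylum level.
#'
#' @return List with `nodes_text` and `names_text`.
#' @export
make_taxonomy_fixture <- function() {
  # tax_id, parent_id, rank, name
  rows <- rbind(
    c(1, 1, "no rank", "root"),
    c(2, 1, "superkingdom", "Bacteria"),
    c(2157, 1, "superkingdom", "Archaea"),
    c(1224, 2, "phylum", "Proteobacteria"),
    c(203682, 2, "phylum", "Planctomycetes"),
    c(976, 2, "phylum", "Bacteroidetes"),
    c(651137, 2157, "phylum", "Thaumarchaeota"),
    c(1236, 1224, "class", "Gammaproteobacteria"),
    c(28211, 1224, "class", "Alphaproteobacteria"),
    c(2000, 203682, "class", "Planctomycetia"),
    c(3000, 651137, "class", "Nitrososphaeria"),
    c(4000, 976, "class", "Flavobacteriia"),
    c(2010, 2000, "order", "Candidatus Brocadiales"),
    c(2020, 2000, "order", "Planctomycetales"),
    c(3010, 3000, "order", "Nitrosopumilales"),
    c(4010, 4000, "order", "Flavobacteriales"),
    c(1100, 1236, "order", "Alteromonadales"),
    c(1110, 1236, "order", "Thiotrichales"),
    c(2050, 2010, "genus", "Candidatus Scalindua"),
    c(2060, 2020, "genus", "Planctomyces"),
    c(3050, 3010, "genus", "Nitrosopumilus"),
    c(3060, 3010, "genus", "Nitrosoarchaeum"),
    c(4050, 4010, "genus", "Polaribacter"),
    c(1150, 1100, "genus", "Alteromonas"),
    c(1160, 1110, "genus", "Thiomicrospira"),
    c(28212, 28211, "order", "Rhodobacterales"),
    c(1170, 28212, "genus", "Roseobacter"),
    c(2101, 2050, "species", "Candidatus Scalindua profunda-like sp. 1"),
    c(2102, 2050, "species", "Candidatus Scalindua profunda-like sp. 2"),
    c(2103, 2060, "species", "Planctomyces sp. synth-1"),
    c(2104, 2060, "species", "Planctomyces sp. synth-2"),
    c(3101, 3050, "species", "Nitrosopumilus maritimus-like sp. 1"),
    c(3102, 3050, "species", "Nitrosopumilus maritimus-like sp. 2"),
    c(3103, 3060, "species", "Nitrosoarchaeum sp. synth-1"),
    c(3104, 3060, "species", "Nitrosoarchaeum sp. synth-2"),
    c(1151, 1150, "species", "Alteromonas sp. synth-1"),
    c(1152, 1150, "species", "Alteromonas sp. synth-2"),
    c(1161, 1160, "species", "Thiomicrospira sp. synth-1"),
    c(1171, 1170, "species", "Roseobacter sp. synth-1"),
    c(4101, 4050, "species", "Polaribacter sp. synth-1")
  )
  nodes <- apply(rows, 1, function(r)
    paste(r[1], r[2], r[3], sep = "\t|\t"))
  nodes <- paste0(nodes, "\t|")
  names_ <- apply(rows, 1, function(r)
    paste(r[1], r[4], "", "scientific name", sep = "\t|\t"))
  names_ <- paste0(names_, "\t|")
  list(nodes_text = paste(nodes, collapse = "\n"),
       names_text = paste(names_, collapse = "\n"))
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate reads from a metal reference with known truth
#'
#' Each read draws a family from the configured mixture, a domain
#' uniformly within the family, and a random in-frame window of the
#' domain; the window is back-translated with uniform synonymous codon
#' choice, point substitutions are applied at the configured rate, and
#' the read is placed on a random strand. Base qualities are constant
#' and consistent with the substitution rate
#' (Q = round(-10 log10(rate)), capped at 40).
#'
#' @param ref A `MetalReference`.
#' @param cfg A `SimConfig`; `cfg$family_mixture` must name families
#'   present in `ref` (NULL = uniform).
#' @return List with `reads` (read_id, sequence, qualities, mate),
#'   `fastq_text`, and `truth` (read_id, family_sccs, protein_id,
#'   metal, tax_id, strand, peptide).
#' @export
simulate_reads <- function(ref, cfg = sim_config()) {
  stopifnot(inherits(ref, "MetalReference"), inherits(cfg, "SimConfig"))
  ent <- ref$entries
  mix <- cfg$family_mixture
  if (is.null(mix)) {
    fams <- sort(unique(ent$family_sccs))
    mix <- stats::setNames(rep(1 / length(fams), length(fams)), fams)
  }
  missing <- setdiff(names(mix), ent$family_sccs)
  if (length(missing))
    stop("mixture famil(ies) absent from reference: ",
         paste(missing, collapse = ", "))
  aa_len <- cfg$read_length %/% 3
  min_prot <- min(nchar(ent$sequence[ent$family_sccs %in% names(mix)]))
  if (aa_len > min_prot)
    stop("read_length ", cfg$read_length,
         " exceeds 3x the shortest mixture protein (", min_prot, " aa)")
  q <- if (cfg$substitution_rate > 0)
    min(40L, as.integer(round(-10 * log10(cfg$substitution_rate)))) else 40L
  qchar <- intToUtf8(q + 33L)
  codons <- .codon_table()
  by_family <- split(seq_len(nrow(ent)), ent$family_sccs)

  .with_seed(cfg$seed + 1L, {
    fam_draw <- sample(names(mix), cfg$n_reads, replace = TRUE, prob = mix)
    out <- vector("list", cfg$n_reads)
    for (i in seq_len(cfg$n_reads)) {
      idx <- by_family[[fam_draw[i]]]
      j <- if (length(idx) == 1) idx else sample(idx, 1)
      prot <- ent$sequence[j]
      start <- sample.int(nchar(prot) - aa_len + 1L, 1)
      pep <- substring(prot, start, start + aa_len - 1L)
      aas <- strsplit(pep, "", fixed = TRUE)[[1]]
      nt <- paste(vapply(aas, function(a) {
        cs <- codons[[a]]
        if (length(cs) == 1) cs else sample(cs, 1)
      }, "", USE.NAMES = FALSE), collapse = "")
      # point substitutions
      if (cfg$substitution_rate > 0) {
        ch <- strsplit(nt, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < cfg$substitution_rate)
        for (k in hit) ch[k] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[k]), 1)
        nt <- paste(ch, collapse = "")
      }
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") nt <- .revcomp(nt)
      out[[i]] <- data.frame(
        read_id = sprintf("read%06d", i), sequence = nt,
        family_sccs = fam_draw[i], protein_id = ent$protein_id[j],
        metal = ent$metal[j],
        tax_id = if (!is.null(ent$tax_id)) ent$tax_id[j] else NA_integer_,
        strand = strand, peptide = pep, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, out)
    reads <- data.frame(read_id = truth$read_id,
                        sequence = truth$sequence,
                        qualities = strrep(qchar, nchar(truth$sequence)),
                        mate = "merged", stringsAsFactors = FALSE)
    fastq <- paste(paste0("@", reads$read_id), reads$sequence, "+",
                   reads$qualities, sep = "\n", collapse = "\n")
    list(reads = reads, fastq_text = fastq,
         truth = truth[, c("read_id", "family_sccs", "protein_id",
                           "metal", "tax_id", "strand", "peptide")])
  })
}

#' Simulate OMZ-like geochemical depth profiles
#'
#' Fifteen depths from 15 to 1000 m follow target curves in which O2
#' declines from >200 uM at the surface through an oxycline to <5 uM in
#' the 200-300 m core and partially recovers below; dissolved Fe rises
#' sharply across the oxic-anoxic transition into the 1-2 nM range;
#' dissolved Cu is drawn flat within `cfg$dcu_range`. Lognormal noise
#' of relative scale `cfg$profile_noise` perturbs O2 and Fe, clamped so
#' each depth keeps its designed oxygen-zone box; `profile_noise = 0`
#' returns the exact targets. Nutrients and temperature get plausible
#' OMZ shapes (secondary nitrite maximum, nitrate dip, thermocline).
#'
#' @param cfg A `SimConfig`.
#' @return A `GeoSamples` data frame (15 rows) with derived Fe:Cu ratio
#'   and zone labels covering all five zones.
#' @export
simulate_profiles <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  depth <- c(15, 25, 30, 55, 70, 85, 100, 125, 200, 250, 300,
             500, 700, 850, 1000)
  o2_t <- c(225, 215, 205, 150, 80, 20, 6, 3, 2, 1, 1.5, 8, 20, 35, 45)
  o2_lo <- c(202, 202, 202, 10.5, 10.5, 10.5, 0.3, 0.3, 0.2, 0.2, 0.2,
             5.2, 5.2, 5.2, 5.2)
  o2_hi <- c(400, 400, 400, 195, 195, 195, 9.5, 9.5, 4.5, 4.5, 4.5,
             48, 48, 48, 48)
  fe_t <- c(0.10, 0.12, 0.15, 0.30, 0.50, 0.80, 1.30, 1.60, 1.80, 2.00,
            1.90, 1.20, 1.00, 0.90, 0.85)
  no2_t <- c(0.05, 0.05, 0.1, 0.3, 1.0, 3.0, 5.5, 5.0, 2.0, 1.5, 1.0,
             0.2, 0.1, 0.05, 0.05)
  no3_t <- c(2, 4, 5, 15, 22, 20, 16, 18, 25, 28, 30, 35, 38, 40, 41)
  po4_t <- c(0.4, 0.5, 0.6, 1.2, 1.8, 2.2, 2.5, 2.6, 2.8, 2.9, 3.0,
             3.1, 3.1, 3.2, 3.2)
  temp_t <- 25 - 21 * (1 - exp(-depth / 250))
  .with_seed(cfg$seed + 2L, {
    n <- length(depth)
    jitter <- function(x) x * exp(stats::rnorm(n, 0, cfg$profile_noise))
    o2 <- pmin(pmax(jitter(o2_t), o2_lo), o2_hi)
    dfe <- pmax(jitter(fe_t), 0.02)
    dcu <- stats::runif(n, cfg$dcu_range[1] + 0.05 * diff(cfg$dcu_range),
                        cfg$dcu_range[2] - 0.05 * diff(cfg$dcu_range))
    df <- data.frame(
      sample_id = sprintf("s%02d", seq_len(n)),
      depth = depth, temperature = round(temp_t, 2),
      o2 = o2, no3 = pmax(jitter(no3_t), 0), no2 = pmax(jitter(no2_t), 0),
      po4 = pmax(jitter(po4_t), 0), dfe = dfe, dcu = dcu,
      stringsAsFactors = FALSE)
    geo_samples(df)
  })
}
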
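#' Run the full inventory pipeline from a single configuration
#'
#' Executes the stages simulate (read generation per sample), build_ref,
#' search, profile, taxonomy and stats (zones, Spearman screen and,
#' with at least three samples, partial CCA) in order, writing each
#' stage's outputs plus a JSON manifest of parameters, seeds, row
#' counts and file checksums under `out_dir`. Rerunning with the same
#' configuration and inputs reproduces byte-identical outputs; the
#' manifest deliberately contains no timestamps.
#'
#' The configuration (list, or path to a JSON file) must provide:
#' \describe{
#'   \item{seed}{integer master seed}
#'   \item{cla, des, fasta}{hierarchy file paths}
#'   \item{fe_seeds, cu_seeds}{seed-sunid list paths}
#'   \item{exclusions}{character vector of family sccs to exclude}
#'   \item{geochem_csv}{geochemistry CSV path}
#'   \item{tax_nodes, tax_names}{taxonomy dump paths}
#'   \item{samples}{sample ids (rows of the geochemistry table) to
#'     simulate reads for}
#'   \item{reads_per_sample}{reads per sample}
#'   \item{total_protein_coding}{named (or scalar) per-sample
#'     normalization denominators; never inferred}
#'   \item{read_length, substitution_rate, bit_cutoff, evalue_cutoff,
#'     threshold_fraction, top_percent}{optional overrides}
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param config List or JSON path.
#' @param out_dir Output directory (created; overrides `config$out_dir`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    base <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    for (f in c("cla", "des", "fasta", "fe_seeds", "cu_seeds",
                "geochem_csv", "tax_nodes", "tax_names")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        config[[f]] <- file.path(base, config[[f]])
    }
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  cfg <- config

  # fail-fast validation before any stage runs
  need <- c("seed", "cla", "des", "fasta", "fe_seeds", "cu_seeds",
            "geochem_csv", "tax_nodes", "tax_names", "samples",
            "reads_per_sample", "total_protein_coding", "out_dir")
  miss <- need[vapply(need, function(f) is.null(cfg[[f]]), TRUE)]
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  for (f in c("cla", "des", "fasta", "fe_seeds", "cu_seeds",
              "geochem_csv", "tax_nodes", "tax_names")) {
    if (!file.exists(cfg[[f]]))
      stop("config path for '", f, "' does not exist: ", cfg[[f]])
  }
  defaults <- list(read_length = 120L, substitution_rate = 0.01,
                   bit_cutoff = 50, evalue_cutoff = 0.1,
                   threshold_fraction = 0.04, top_percent = 10,
                   exclusions = "c.83.1.1")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(), files = list(),
                   parameters = cfg[c("bit_cutoff", "evalue_cutoff",
                                      "threshold_fraction", "top_percent",
                                      "read_length", "substitution_rate",
                                      "exclusions")])
  add_file <- function(path, n_rows) {
    manifest$files[[basename(path)]] <<- list(
      path = basename(path),
      md5 = unname(tools::md5sum(path)), n_rows = n_rows)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(paste("incomplete: failed in stage", name),
                 file.path(cfg$out_dir, "INCOMPLETE"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[length(manifest$stages) + 1]] <<- name
    message("[", name, "] done")
    res
  }

  geo <- geo_samples(utils::read.csv(cfg$geochem_csv,
                                     stringsAsFactors = FALSE))
  bad <- setdiff(cfg$samples, geo$sample_id)
  if (length(bad))
    stop("config samples absent from geochemistry table: ",
         paste(bad, collapse = ", "))

  # --- build_ref (needed before simulate can draw reads) -------------
  ref <- NULL
  h <- NULL
  truth_dom <- NULL
  ref <- run_stage("build_ref", function() {
    h <<- parse_hierarchy(cfg$cla, cfg$des, cfg$fasta)
    r <- build_metal_reference(h, read_seed_list(cfg$fe_seeds),
                               read_seed_list(cfg$cu_seeds),
                               cfg$exclusions)
    # attach fixture taxon ids where the description table carries them
    tm <- .default_taxon_map(data.frame(
      sccs = unique(r$entries$family_sccs),
      metal = r$entries$metal[!duplicated(r$entries$family_sccs)],
      stringsAsFactors = FALSE))
    r$entries$tax_id <- unname(tm[r$entries$family_sccs])
    fp <- file.path(cfg$out_dir, "reference.fasta")
    write_reference_fasta(r, fp)
    add_file(fp, nrow(r$entries))
    ep <- file.path(cfg$out_dir, "excluded_families.tsv")
    utils::write.table(r$excluded_families, ep, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_file(ep, nrow(r$excluded_families))
    r
  })

  # --- simulate ------------------------------------------------------
  sim_reads <- run_stage("simulate", function() {
    dir.create(file.path(cfg$out_dir, "reads"), showWarnings = FALSE)
    fams <- sort(unique(ref$entries$family_sccs))
    fe_f <- fams[fams %in%
                   ref$entries$family_sccs[ref$entries$metal == "Fe"]]
    cu_f <- setdiff(fams, fe_f)
    out <- list()
    for (i in seq_along(cfg$samples)) {
      sid <- cfg$samples[i]
      o2 <- geo$o2[geo$sample_id == sid]
      fe_share <- 0.25 + 0.5 * exp(-o2 / 20) # Fe-rich under anoxia
      mix <- c(stats::setNames(rep(fe_share / length(fe_f),
                                   length(fe_f)), fe_f),
               stats::setNames(rep((1 - fe_share) / length(cu_f),
                                   length(cu_f)), cu_f))
      scfg <- sim_config(seed = cfg$seed + i,
                         n_reads = cfg$reads_per_sample,
                         read_length = cfg$read_length,
                         substitution_rate = cfg$substitution_rate,
                         family_mixture = mix / sum(mix))
      sim <- simulate_reads(ref, scfg)
      fq <- file.path(cfg$out_dir, "reads", paste0(sid, ".fastq"))
      writeLines(sim$fastq_text, fq)
      add_file(fq, nrow(sim$reads))
      out[[sid]] <- sim
    }
    out
  })

  # --- search --------------------------------------------------------
  hits_by_sample <- run_stage("search", function() {
    p <- search_params(bit_cutoff = cfg$bit_cutoff,
                       evalue_cutoff = cfg$evalue_cutoff)
    out <- list()
    for (sid in cfg$samples) {
      hits <- search_reads(sim_reads[[sid]]$reads, ref, p)
      hp <- file.path(cfg$out_dir, paste0("hits_", sid, ".tsv"))
      write_hits_tsv(hits, hp)
      add_file(hp, nrow(hits))
      out[[sid]] <- hits
    }
    out
  })

  # --- profile -------------------------------------------------------
  invs <- run_stage("profile", function() {
    tpc <- cfg$total_protein_coding
    if (is.null(names(tpc)))
      tpc <- stats::setNames(rep_len(tpc, length(cfg$samples)),
                             cfg$samples)
    out <- list()
    for (sid in cfg$samples) for (metal in c("Fe", "Cu")) {
      inv <- profile_inventory(hits_by_sample[[sid]], metal,
                               tpc[[sid]], sample_id = sid,
                               threshold_fraction = cfg$threshold_fraction)
      ip <- file.path(cfg$out_dir,
                      paste0("inventory_", sid, "_", metal, ".tsv"))
      write_inventory_tsv(inv, ip)
      add_file(ip, nrow(inv))
      out[[paste(sid, metal)]] <- inv
    }
    mats <- lapply(c("Fe", "Cu"), function(metal) {
      m <- inventory_matrix(out[grepl(paste0(" ", metal, "$"),
                                      names(out))])
      mp <- file.path(cfg$out_dir,
                      paste0("inventory_matrix_", metal, ".csv"))
      utils::write.table(cbind(sample_id = rownames(m), round(m, 6)),
                         mp, sep = ",", quote = FALSE, row.names = FALSE)
      add_file(mp, nrow(m))
      m
    })
    names(mats) <- c("Fe", "Cu")
    list(tables = out, matrices = mats)
  })

  # --- taxonomy ------------------------------------------------------
  run_stage("taxonomy", function() {
    taxo <- read_taxonomy(cfg$tax_nodes, cfg$tax_names)
    lp <- lca_params(top_percent = cfg$top_percent)
    for (sid in cfg$samples) {
      hits <- hits_by_sample[[sid]]
      if (nrow(hits) == 0) next
      asg <- assign_lca(hits, taxo, lp)
      ap <- file.path(cfg$out_dir, paste0("lca_", sid, ".tsv"))
      utils::write.table(asg, ap, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(ap, nrow(asg))
      if (any(!is.na(asg$tax_id))) {
        ph <- rollup_phylum(asg, taxo)
        pp <- file.path(cfg$out_dir, paste0("phylum_", sid, ".csv"))
        utils::write.table(ph, pp, sep = ",", quote = FALSE,
                           row.names = FALSE)
        add_file(pp, nrow(ph))
      }
    }
    invisible(NULL)
  })

  # --- stats ---------------------------------------------------------
  run_stage("stats", function() {
    zp <- file.path(cfg$out_dir, "zones.csv")
    utils::write.table(as.data.frame(geo), zp, sep = ",", quote = FALSE,
                       row.names = FALSE)
    add_file(zp, nrow(geo))
    gsub_ <- geo[match(cfg$samples, geo$sample_id), , drop = FALSE]
    genv <- as.matrix(gsub_[, c("depth", "temperature", "o2", "no3",
                                "no2", "po4", "dfe", "dcu")])
    rownames(genv) <- gsub_$sample_id
    for (metal in c("Fe", "Cu")) {
      m <- invs$matrices[[metal]]
      if (nrow(m) < 3 || ncol(m) < 1) next
      scr <- spearman_screen(m, genv)
      sp <- file.path(cfg$out_dir,
                      paste0("correlations_", metal, ".tsv"))
      utils::write.table(
        within(scr, {
          rho <- round(rho, 10); p_value <- round(p_value, 10)
          q_value <- round(q_value, 10)
        }), sp, sep = "\t", quote = FALSE, row.names = FALSE)
      add_file(sp, nrow(scr))
    }
    comm <- cbind(invs$matrices$Fe, invs$matrices$Cu)
    colnames(comm) <- c(paste0("Fe:", colnames(invs$matrices$Fe)),
                        paste0("Cu:", colnames(invs$matrices$Cu)))
    comm <- comm[, colSums(comm) > 0, drop = FALSE]
    if (nrow(comm) >= 3) {
      cc <- partial_cca(comm, genv[, c("o2", "no3"), drop = FALSE],
                        conditions = genv[, "depth", drop = FALSE])
      cp <- file.path(cfg$out_dir, "cca_site_scores.csv")
      utils::write.table(cbind(sample_id = rownames(cc$site_scores),
                               round(as.data.frame(cc$site_scores), 8)),
                         cp, sep = ",", quote = FALSE, row.names = FALSE)
      add_file(cp, nrow(cc$site_scores))
    }
    invisible(NULL)
  })

  manifest$stages <- unlist(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
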
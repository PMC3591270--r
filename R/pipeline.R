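#' Default pipeline configuration
#'
#' Returns the configuration list for a fully synthetic end-to-end run. Every
#' threshold sits at its documented default (best-hit e-value 1e-5, DE FDR
#' 0.05, HQ mean phred 38, term FDR 0.01) and all randomness is funneled
#' through one seed per stage, derived from the top-level seed.
#'
#' @param outdir Output directory for stage results.
#' @param seed Top-level integer seed.
#' @return Nested configuration list.
#' @export
default_config <- function(outdir = tempfile("xenoexpress_run_"), seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    simulate = list(n_genes = 300, isoforms_per_gene = 1, contig_frag_rate = 0.5,
                    mutation_rate = 0.005, n_orphan_contigs = 30,
                    prop_early = 0.05, prop_late = 0.05, logfc_amplitude = 3,
                    dispersion = 0.05, decoy_rate = 0.05,
                    n_reads = 20000, p_un = 0.49, p_a_given_un = 0.23,
                    p_b_given_a_hq = 0.17, n_qpcr_genes = 8, qpcr_noise_sd = 0.3),
    map = list(evalue = 1e-5, rrna_ids = character()),
    quantify = list(read_length = 76),
    de = list(alpha = 0.05),
    enrich = list(term_fdr = 0.01, ease = FALSE),
    cluster = list(n_boot = 1000, distance = "uncentered"),
    completeness = list(hq_threshold = 38),
    qpcr = list(convention = "methods_ratio", shift = FALSE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; the result round-trips
#' losslessly through [yaml::as.yaml()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_into(default_config(), user)
  cfg$map$rrna_ids <- as.character(unlist(cfg$map$rrna_ids))
  cfg
}

validate_config <- function(config) {
  stopifnot(config$map$evalue > 0, config$map$evalue <= 1,
            config$de$alpha > 0, config$de$alpha < 1,
            config$quantify$read_length >= 1,
            config$cluster$n_boot >= 10,
            config$completeness$hq_threshold > 0)
  invisible(config)
}

stage_seed <- function(config, k) (config$seed * 101 + k) %% 2147483647

#' Run the end-to-end synthetic pipeline
#'
#' Executes the nine stages (simulate, map, quantify, de, completeness,
#' enrich, cluster, orf, qpcr) in dependency order on fully synthetic data,
#' writing each stage's outputs under `config$outdir` and a manifest JSON
#' recording every output file with its content hash and the seeds used.
#' Rerunning with the same configuration and seed is bit-identical for the
#' deterministic stages.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, paste0(...))
  manifest <- list(stages = list(), seed = config$seed)
  files_of <- function(paths) {
    lapply(paths, function(p) list(path = basename(p),
                                   md5 = unname(tools::md5sum(p))))
  }
  add_stage <- function(name, paths, seed = NULL) {
    manifest$stages[[name]] <<- list(name = name, outputs = files_of(paths),
                                     seed = seed)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## 1. simulate ------------------------------------------------------------
  sim_cfg <- config$simulate
  sim_seed <- stage_seed(config, 1)
  sim <- run_stage("simulate", {
    sim <- simulate_anchor_and_contigs(
      n_genes = sim_cfg$n_genes, isoforms_per_gene = sim_cfg$isoforms_per_gene,
      contig_frag_rate = sim_cfg$contig_frag_rate,
      mutation_rate = sim_cfg$mutation_rate,
      n_orphan_contigs = sim_cfg$n_orphan_contigs, seed = sim_seed,
      prop_early = sim_cfg$prop_early, prop_late = sim_cfg$prop_late,
      logfc_amplitude = sim_cfg$logfc_amplitude,
      dispersion = sim_cfg$dispersion)
    design <- timecourse_design(sprintf("S%02d", 0:11))
    counts <- simulate_timecourse_counts(sim$truth, design, seed = sim_seed + 1)
    blastn <- simulate_blast_hits(sim$contigs, sim$truth,
                                  decoy_rate = sim_cfg$decoy_rate,
                                  seed = sim_seed + 2, search = "nucleotide")
    blastx <- simulate_blast_hits(sim$contigs, sim$truth,
                                  decoy_rate = sim_cfg$decoy_rate,
                                  seed = sim_seed + 3, search = "protein")
    prov <- simulate_read_provenance(sim_cfg$n_reads, p_un = sim_cfg$p_un,
                                     p_a_given_un = sim_cfg$p_a_given_un,
                                     p_b_given_a_hq = sim_cfg$p_b_given_a_hq,
                                     seed = sim_seed + 4)
    qpcr_genes <- head(names(sim$truth$program)[sim$truth$program != "null"],
                       sim_cfg$n_qpcr_genes)
    ct <- simulate_qpcr(sim$truth, design, qpcr_genes,
                        noise_sd = sim_cfg$qpcr_noise_sd, seed = sim_seed + 5)
    write_fasta(sim$contigs, out("contigs.fasta"))
    write.table(sim$annotation, out("annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_design_tsv(design, out("design.tsv"))
    write_matrix_tsv(counts, out("contig_counts.tsv"), id_col = "contig_id")
    write_blast_tsv(blastn, out("blastn.tsv"))
    write_blast_tsv(blastx, out("blastx.tsv"))
    write.table(prov, out("provenance.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(ct, out("qpcr_ct.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sets <- list(early_program = names(sim$truth$program)[sim$truth$program == "early_burst"],
                 late_program = names(sim$truth$program)[sim$truth$program == "late_peak"])
    sets <- sets[lengths(sets) > 0]
    write_gmt(sets, out("programs.gmt"))
    list(sim = sim, design = design, counts = counts, blastn = blastn,
         blastx = blastx, prov = prov, ct = ct, sets = sets,
         qpcr_genes = qpcr_genes)
  })
  add_stage("simulate", list(out("contigs.fasta"), out("annotation.tsv"),
                             out("design.tsv"), out("contig_counts.tsv"),
                             out("blastn.tsv"), out("blastx.tsv"),
                             out("provenance.tsv"), out("qpcr_ct.tsv"),
                             out("programs.gmt")), sim_seed)

  ## 2. map -----------------------------------------------------------------
  map <- run_stage("map", {
    bn <- parse_blast_tabular(out("blastn.tsv"), source = "nucleotide_search")
    bx <- parse_blast_tabular(out("blastx.tsv"), source = "protein_search")
    best <- rbind(select_best_hits(bn, config$map$evalue),
                  select_best_hits(bx, config$map$evalue))
    m <- resolve_to_genes(best, sim$sim$annotation, sim$sim$protein_annotation,
                          contigs = names(sim$sim$contigs))
    m <- flag_and_remove_rrna(m, config$map$rrna_ids)
    write_map_tsv(m, out("contig_gene_map.tsv"))
    m
  })
  add_stage("map", list(out("contig_gene_map.tsv")))

  ## 3. quantify ------------------------------------------------------------
  quant <- run_stage("quantify", {
    clens <- setNames(nchar(sim$sim$contigs), names(sim$sim$contigs))
    gene_counts <- aggregate_counts(sim$counts, map)
    eff <- gene_effective_length(map, clens, config$quantify$read_length)
    gene_tpm <- compute_tpm(gene_counts, eff)
    ctg_eff <- contig_effective_length(clens, config$quantify$read_length)
    ctg_tpm <- compute_tpm(sim$counts, ctg_eff)
    write_matrix_tsv(gene_counts, out("gene_counts.tsv"), id_col = "gene_id")
    write_matrix_tsv(gene_tpm, out("gene_tpm.tsv"), id_col = "gene_id")
    write_matrix_tsv(ctg_tpm, out("contig_tpm.tsv"), id_col = "contig_id")
    list(gene_counts = gene_counts, gene_tpm = gene_tpm, eff = eff)
  })
  add_stage("quantify", list(out("gene_counts.tsv"), out("gene_tpm.tsv"),
                             out("contig_tpm.tsv")))

  ## 4. de (gene and contig level + comparison) ------------------------------
  de <- run_stage("de", {
    disp_g <- common_dispersion(quant$gene_counts, sim$design)
    de_g <- call_de_timecourse(quant$gene_counts, sim$design, disp_g$common,
                               alpha = config$de$alpha)
    disp_c <- common_dispersion(sim$counts, sim$design)
    de_c <- call_de_timecourse(sim$counts, sim$design, disp_c$common,
                               alpha = config$de$alpha)
    cmp <- compare_de_levels(de_g, de_c, map)
    write.table(de_g, out("de_gene.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(de_c, out("de_contig.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(de_union(de_g), out("de_gene_wholeTC.txt"))
    jsonlite::write_json(list(common_dispersion_gene = disp_g$common,
                              common_dispersion_contig = disp_c$common,
                              n_shared = cmp$n_shared,
                              n_gene_only = cmp$n_gene_only,
                              n_contig_only = cmp$n_contig_only),
                         out("de_comparison.json"), auto_unbox = TRUE)
    list(de_g = de_g, de_c = de_c, disp_g = disp_g)
  })
  add_stage("de", list(out("de_gene.tsv"), out("de_contig.tsv"),
                       out("de_gene_wholeTC.txt"), out("de_comparison.json")))

  ## 5. completeness ---------------------------------------------------------
  comp <- run_stage("completeness", {
    rep <- completeness_report(provenance = sim$prov,
                               hq_threshold = config$completeness$hq_threshold)
    jsonlite::write_json(rep[names(rep) != "percent"], out("completeness.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  add_stage("completeness", list(out("completeness.json")))

  ## 6. enrich ---------------------------------------------------------------
  run_stage("enrich", {
    background <- rownames(quant$gene_counts)[rowSums(quant$gene_counts) > 0]
    enr <- do.call(rbind, lapply(names(sim$sets), function(nm) {
      e <- timecourse_set_enrichment(de$de_g, sim$sets[[nm]], background)
      e$set_name <- nm
      e
    }))
    write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    suppressWarnings({
      tm <- term_enrichment_table(de$de_g, sim$sets, background,
                                  ease_adjust = config$enrich$ease,
                                  fdr_threshold = config$enrich$term_fdr)
      if (nrow(tm)) write_matrix_tsv(tm, out("term_matrix.tsv"), id_col = "term")
      else writeLines("term", out("term_matrix.tsv"))
    })
  })
  add_stage("enrich", list(out("enrichment.tsv"), out("term_matrix.tsv")))

  ## 7. cluster --------------------------------------------------------------
  clu_seed <- stage_seed(config, 7)
  run_stage("cluster", {
    du <- de_union(de$de_g)
    lfc <- matrix(de$de_g$log2_fold_change,
                  nrow = length(unique(de$de_g$gene_id)),
                  dimnames = list(unique(de$de_g$gene_id),
                                  unique(de$de_g$time_label)))
    lfc <- lfc[rownames(lfc) %in% du, , drop = FALSE]
    sup <- bootstrap_support(lfc, n_boot = config$cluster$n_boot,
                             seed = clu_seed,
                             distance = config$cluster$distance)
    write.table(as.data.frame(sup), out("edge_support.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_support_newick(sup, out("samples.nwk"))
  })
  add_stage("cluster", list(out("edge_support.tsv"), out("samples.nwk")), clu_seed)

  ## 8. orf ------------------------------------------------------------------
  orf_seed <- stage_seed(config, 8)
  run_stage("orf", {
    de_contigs <- de_union(de$de_c)
    de_contigs <- de_contigs[de_contigs %in% names(sim$sim$contigs)]
    if (length(de_contigs) == 0L) de_contigs <- names(sim$sim$contigs)
    seqs <- sim$sim$contigs[de_contigs]
    mapped <- de_contigs %in% map$entries$contig_id
    scan <- orf_scan(seqs)
    scan$has_hit <- mapped
    null <- shuffled_null(seqs, seed = orf_seed)
    scan$shuffled_fraction <- null$fraction_of_contig
    write.table(scan, out("orf.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  add_stage("orf", list(out("orf.tsv")), orf_seed)

  ## 9. qpcr -----------------------------------------------------------------
  run_stage("qpcr", {
    conc <- qpcr_concordance(quant$gene_tpm, sim$ct, sim$design,
                             convention = config$qpcr$convention,
                             shift = config$qpcr$shift)
    write.table(conc$per_gene, out("qpcr_concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  add_stage("qpcr", list(out("qpcr_concordance.tsv")))

  manifest$config <- config
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
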
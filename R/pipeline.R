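# End-to-end orchestration: simulate or load a cohort, compute every score
# and genomic feature, run all group comparisons, and emit a report bundle
# of TSV tables mirroring the analysis panels.

#' Report tables produced by [run_pipeline()]
#' @export
PIPELINE_TABLES <- c("sample_scores.tsv", "fractions.tsv", "tmb.tsv",
                     "mutation_frequency.tsv", "hla_homozygosity.tsv",
                     "neoantigen_load.tsv", "group_tests.tsv",
                     "pten_angiogenesis.tsv", "metabolic_correlations.tsv",
                     "deg_MBM_vs_PCM.tsv", "deg_MBM_vs_ECM.tsv",
                     "run_manifest.tsv")

#' Build a pipeline configuration
#'
#' Either `simulate` (a [generator_config()]) or `inputs` (named list of
#' file paths: `expression`, `manifest`, `mutations`, `hla`, `neoantigens`,
#' `signature`, optionally `genesets`) must be supplied. All thresholds
#' live here; nothing downstream hard-codes them.
#'
#' @param simulate optional [generator_config()].
#' @param inputs optional named list of input file paths.
#' @param out_dir output directory for the report bundle.
#' @param tmb_cutoff TMB-high threshold, mutations/MB.
#' @param footprint_mb sequenced footprint, MB.
#' @param tis_thresholds optional `c(t_low, t_high)` for [tis_classify()].
#' @param dysfunction_cutoff threshold for [nonfunctional_cd8_classify()].
#' @param alpha significance level for BH-adjusted comparisons.
#' @param driver_genes genes for the mutation-frequency table.
#' @param seed seed for any stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL, out_dir,
                            tmb_cutoff = 10, footprint_mb = 1.4,
                            tis_thresholds = NULL, dysfunction_cutoff = 1.0,
                            alpha = 0.05,
                            driver_genes = c("BRAF", "NRAS", "NF1", "PTEN"),
                            seed = 1) {
  if (is.null(simulate) && is.null(inputs)) {
    abort("configuration error: either a simulate block or input paths required")
  }
  structure(list(simulate = simulate, inputs = inputs, out_dir = out_dir,
                 tmb_cutoff = tmb_cutoff, footprint_mb = footprint_mb,
                 tis_thresholds = tis_thresholds,
                 dysfunction_cutoff = dysfunction_cutoff, alpha = alpha,
                 driver_genes = driver_genes, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full profiling pipeline
#'
#' Executes every stage -- cohort loading or simulation, signature scoring,
#' deconvolution, genomic features, group statistics, PTEN/angiogenesis
#' comparison, metabolic-pathway correlations, differential expression --
#' and writes the report bundle ([PIPELINE_TABLES]) under
#' `config$out_dir`. Deterministic given the seed: rerunning the same
#' config yields byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the report tables (data.frames).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("load", {
    if (!is.null(config$simulate)) {
      co <- generate_cohort(config$simulate)
      co$genesets <- builtin_genesets()
      co$signature <- default_signature_matrix(co$reference)
      co
    } else {
      inp <- config$inputs
      co <- list(expression = read_expression(inp$expression),
                 manifest = read_manifest(inp$manifest),
                 mutations = read_mutations(inp$mutations),
                 hla = read_hla(inp$hla),
                 neoantigens = read_neoantigens(inp$neoantigens),
                 signature = read_signature_matrix(inp$signature))
      co$genesets <- if (!is.null(inp$genesets)) read_gmt(inp$genesets)
                     else builtin_genesets()
      co
    }
  })
  expr <- cohort$expression
  manifest <- cohort$manifest
  message("[load] ", ncol(expr), " samples, ", nrow(expr), " genes, ",
          nrow(cohort$mutations), " mutation records")

  fractions <- stage("deconvolution", deconvolve(expr, cohort$signature))
  message("[deconvolution] ", ncol(fractions), " compartments")

  scores <- stage("signature_scores", {
    ifng <- ifng_score(expr, cohort$genesets$ifng)
    tis <- tis_classify(expr, cohort$genesets$tis,
                        thresholds = config$tis_thresholds)
    dys <- dysfunction_score(expr)
    sting <- sting_score(expr)
    cd8 <- fractions[manifest$sample_id, "T_cells_CD8"]
    nf <- nonfunctional_cd8_classify(dys[manifest$sample_id],
                                     expr["FGFBP2", manifest$sample_id],
                                     cd8, cutoff = config$dysfunction_cutoff)
    data.frame(sample_id = manifest$sample_id, group = manifest$group,
               ifng_score = ifng[manifest$sample_id],
               tis_class = as.character(tis$class[manifest$sample_id]),
               dysfunction_score = dys[manifest$sample_id],
               sting_score = sting[manifest$sample_id],
               nonfunctional_cd8 = nf$nonfunctional,
               cd8_eligible = nf$eligible,
               row.names = NULL, stringsAsFactors = FALSE)
  })

  genomics <- stage("genomic_features", {
    tmb_tab <- tmb(cohort$mutations, footprint_mb = config$footprint_mb,
                   cutoff = config$tmb_cutoff, samples = manifest$sample_id)
    path <- filter_pathogenic(cohort$mutations)
    freq <- do.call(rbind, lapply(config$driver_genes, function(g) {
      assessed <- cohort$truth$assessed[[g]]  # per-gene coverage if simulated
      do.call(rbind, lapply(intersect(COHORT_GROUPS, unique(manifest$group)),
                            function(grp) {
        mutation_frequency(path, manifest, g, grp, assessed = assessed)
      }))
    }))
    hom <- hla_homozygosity(cohort$hla, manifest = manifest)
    load <- neoantigen_load(cohort$neoantigens, samples = manifest$sample_id)
    list(tmb = tmb_tab, freq = freq, hom = hom$summary, load = load)
  })
  message("[genomic_features] ", nrow(filter_pathogenic(cohort$mutations)),
          " pathogenic records retained of ", nrow(cohort$mutations))

  group_tests <- stage("group_tests", {
    vars <- rbind(
      ifng_score = scores$ifng_score,
      dysfunction_score = scores$dysfunction_score,
      sting_score = scores$sting_score,
      tmb = genomics$tmb$tmb[match(manifest$sample_id, genomics$tmb$sample_id)],
      t(fractions[manifest$sample_id, , drop = FALSE]))
    kruskal_bh(vars, manifest$group)
  })

  ss <- stage("ssgsea", {
    sets <- cohort$genesets[intersect(c("OXPHOS", "TCA", "GLYC",
                                        "ANGIOGENESIS"),
                                      names(cohort$genesets))]
    ssgsea(expr, sets)
  })

  pten <- stage("pten_angiogenesis", {
    path <- filter_pathogenic(cohort$mutations)
    pten_mut <- unique(path$sample_id[path$gene == "PTEN"])
    do.call(rbind, lapply(intersect(COHORT_GROUPS, unique(manifest$group)),
                          function(grp) {
      ids <- manifest$sample_id[manifest$group == grp]
      ang <- ss[ids, "ANGIOGENESIS"]
      mut <- ids %in% pten_mut
      ok <- sum(mut) >= 2 && sum(!mut) >= 2
      data.frame(group = grp, n_mut = sum(mut), n_wt = sum(!mut),
                 median_mut = if (any(mut)) stats::median(ang[mut]) else NA,
                 median_wt = if (any(!mut)) stats::median(ang[!mut]) else NA,
                 p_value = if (ok) mann_whitney(ang[mut], ang[!mut])$p_value
                           else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })

  metab <- stage("metabolic_correlations", {
    pathways <- intersect(c("OXPHOS", "TCA", "GLYC"), colnames(ss))
    do.call(rbind, lapply(intersect(COHORT_GROUPS, unique(manifest$group)),
                          function(grp) {
      ids <- manifest$sample_id[manifest$group == grp]
      cm <- correlation_matrix(ss[ids, pathways, drop = FALSE],
                               fractions[ids, , drop = FALSE],
                               method = "spearman", alpha = config$alpha)
      long <- expand.grid(pathway = rownames(cm$rho),
                          cell_type = colnames(cm$rho),
                          stringsAsFactors = FALSE)
      long$group <- grp
      long$rho <- as.vector(cm$rho)
      long$p_value <- as.vector(cm$p)
      long$significant <- !as.vector(cm$mask)
      long[, c("group", "pathway", "cell_type", "rho", "p_value",
               "significant")]
    }))
  })

  degs <- stage("deg", {
    list(MBM_vs_PCM = deg(expr, manifest, "MBM", "PCM", alpha = config$alpha),
         MBM_vs_ECM = deg(expr, manifest, "MBM", "ECM", alpha = config$alpha))
  })

  tables <- list(
    "sample_scores.tsv" = scores,
    "fractions.tsv" = data.frame(sample_id = rownames(fractions), fractions,
                                 check.names = FALSE, stringsAsFactors = FALSE),
    "tmb.tsv" = genomics$tmb,
    "mutation_frequency.tsv" = genomics$freq,
    "hla_homozygosity.tsv" = genomics$hom,
    "neoantigen_load.tsv" = genomics$load,
    "group_tests.tsv" = group_tests,
    "pten_angiogenesis.tsv" = pten,
    "metabolic_correlations.tsv" = metab,
    "deg_MBM_vs_PCM.tsv" = degs$MBM_vs_PCM,
    "deg_MBM_vs_ECM.tsv" = degs$MBM_vs_ECM)

  cfg_file <- tempfile()
  hashed <- unclass(config)
  hashed$out_dir <- NULL      # the analysis is invariant to where it lands
  writeLines(deparse(hashed), cfg_file)
  manifest_tab <- data.frame(
    key = c("package_version", "seed", "config_hash", "n_samples", "n_genes",
            paste0("rows_", names(tables))),
    value = c(as.character(utils::packageVersion("tmeprofiler")),
              as.character(config$seed),
              unname(tools::md5sum(cfg_file)),
              ncol(expr), nrow(expr),
              vapply(tables, nrow, integer(1))),
    stringsAsFactors = FALSE)
  unlink(cfg_file)
  tables[["run_manifest.tsv"]] <- manifest_tab

  for (nm in names(tables)) {
    write_tsv_table(tables[[nm]], file.path(config$out_dir, nm))
  }
  message("[report] ", length(tables), " tables written to ", config$out_dir)
  invisible(tables)
}
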
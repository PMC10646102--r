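# Synthetic three-group melanoma cohort generator. Generates a fully
# labeled cohort (expression, manifest, mutations, HLA, neoantigens) with
# planted group effects -- signature shifts, immune mixing differences,
# mutation rates, TMB distributions -- so that every downstream stage of the
# pipeline can be exercised and its statistical behavior tested without
# access to protected patient data.

#' Default immune cell types for the synthetic reference
#'
#' Ten immune populations plus a malignant ("Tumor") compartment.
#' @export
CELL_TYPES <- c("B_cells", "Macrophages_M1", "Macrophages_M2", "Monocytes",
                "Neutrophils", "NK_cells", "T_cells_CD4", "T_cells_CD8",
                "Tregs", "Dendritic_cells", "Tumor")

#' Built-in gene sets used by the generator and the scoring layer
#'
#' Returns the named gene sets the generator plants effects on and the
#' scoring functions consume. The interferon-gamma (6-gene) and T
#' cell-inflamed (18-gene) memberships follow the anti-PD-1 response
#' signature literature (Ayers et al., J Clin Invest 2017); the exhaustion
#' and STING memberships are the standard checkpoint / cGAS-STING regulator
#' panels; the metabolic and angiogenesis families are compact
#' representative subsets of the corresponding KEGG / hallmark pathways,
#' intended for simulation and testing rather than as curated collections.
#'
#' @return named list of character vectors of gene symbols.
#' @export
builtin_genesets <- function() {
  list(
    ifng = c("IFNG", "STAT1", "CXCL9", "CXCL10", "IDO1", "HLA-DRA"),
    tis = c("CCL5", "CD27", "CD274", "CD276", "CD8A", "CMKLR1", "CXCL9",
            "CXCR6", "HLA-DQA1", "HLA-DRB1", "HLA-E", "IDO1", "LAG3",
            "NKG7", "PDCD1LG2", "PSMB10", "STAT1", "TIGIT"),
    exhaustion = c("HAVCR2", "LAG3", "PDCD1"),
    sting = c("TMEM173", "CGAS", "CCL5", "CXCL10", "IRF3"),
    OXPHOS = c("NDUFA1", "NDUFB5", "NDUFS2", "NDUFV1", "SDHA", "SDHB",
               "UQCRC1", "UQCRC2", "CYC1", "COX4I1", "COX5A", "COX6B1",
               "COX7A2", "ATP5F1A", "ATP5F1B", "ATP5MC1", "ATP5PB",
               "ATP5PD", "NDUFA4", "UQCRFS1"),
    TCA = c("CS", "ACO2", "IDH2", "IDH3A", "IDH3B", "OGDH", "DLST",
            "SUCLA2", "SUCLG1", "SDHC", "SDHD", "FH", "MDH1", "MDH2",
            "PDHA1", "PDHB", "DLAT", "DLD", "ACLY", "PC"),
    GLYC = c("HK1", "HK2", "GPI", "PFKL", "PFKM", "ALDOA", "ALDOC", "TPI1",
             "GAPDH", "PGK1", "PGAM1", "ENO1", "ENO2", "PKM", "LDHA",
             "LDHB", "SLC2A1", "SLC2A3", "PFKP", "ALDOB"),
    ANGIOGENESIS = c("VEGFA", "VEGFB", "VEGFC", "FLT1", "KDR", "ANGPT1",
                     "ANGPT2", "TEK", "PDGFA", "PDGFB", "FGF2", "FGFR1",
                     "HIF1A", "EPAS1", "SERPINE1", "THBS1", "CXCL8",
                     "NRP1", "TIE1", "ESM1"),
    mbm_up = c("HBB", "HBA1", "VSIG4", "PF4"),
    mbm_down = c("COL1A1", "COL1A2", "COL3A1", "CCL21")
  )
}

# single genes the pipeline references outside of any set
SPECIAL_GENES <- c("FGFBP2", "TNF", "IL12A", "IL12B", "STAT3", "AKT1",
                   "PIK3CA", "CCL2", "BRAF", "NRAS", "NF1", "PTEN")

#' Build a synthetic-cohort generator configuration
#'
#' The defaults emulate the published three-group melanoma cohort: group
#' sizes 350 PCM / 94 MBM / 870 ECM; brain metastases carry a lower
#' interferon-gamma signature, reduced STING pathway expression, enriched
#' oxidative metabolism, depleted B cells / M2 macrophages / NK cells /
#' Tregs / dendritic cells with enriched M1 macrophages, and higher
#' pathogenic PTEN mutation rates (16.3% vs 8.1% PCM and 6.0% ECM).
#' Per-gene mutation rates and per-gene assessment coverage mirror the
#' printed per-group rates and denominators; quantities the source cohort
#' does not pin down (noise level, effect sizes for qualitative findings,
#' TMB distribution parameters) are free parameters documented in the
#' methods vignette.
#'
#' @param n_per_group named integer vector of samples per group.
#' @param n_genes total genes in the expression universe (markers, named
#'   signature genes, and background filler).
#' @param markers_per_type marker genes per reference cell type.
#' @param seed master seed; all per-table child seeds derive from it.
#' @param noise_sigma sdlog of the multiplicative log-normal expression
#'   noise (natural-log scale); 0 gives noiseless convex mixtures.
#' @param dirichlet_conc named list group -> positive concentration vector
#'   over `CELL_TYPES` (immune mixing priors).
#' @param min_tumor_fraction lower clamp on the tumor compartment fraction.
#' @param signature_shift named list group -> named numeric vector of
#'   additive log2 shifts applied to built-in gene-set members.
#' @param pten_angiogenesis_shift additive log2 shift on angiogenesis genes
#'   in MBM samples carrying a pathogenic PTEN mutation.
#' @param mutation_prob named list gene -> named per-group probability of a
#'   pathogenic mutation among assessed samples.
#' @param assessed_prob named numeric vector gene -> probability a sample
#'   has assessment coverage for that gene (models per-gene denominators).
#' @param tmb_mean named per-group mean TMB in mutations/MB.
#' @param tmb_size negative-binomial size (dispersion) for TMB counts.
#' @param footprint_mb sequenced footprint in megabases.
#' @param homozygosity_prob named per-locus probability of HLA homozygosity.
#' @param ic50_log10_range range of log10(IC50 nmol/L) for neoantigens.
#' @param peptides_per_mutation mean neoantigen peptides per TMB mutation.
#' @param pdl1_prob named per-group probability of PD-L1 positivity.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_per_group = c(PCM = 350, MBM = 94, ECM = 870),
                             n_genes = 1000,
                             markers_per_type = 20,
                             seed = 1,
                             noise_sigma = 0.5,
                             dirichlet_conc = NULL,
                             min_tumor_fraction = 0.3,
                             signature_shift = list(
                               MBM = c(ifng = -1.0, tis = -0.8, sting = -0.5,
                                       exhaustion = 0.3, OXPHOS = 1.0,
                                       TCA = 0.6, GLYC = 0.5,
                                       mbm_up = 2.0, mbm_down = -1.5)),
                             pten_angiogenesis_shift = 0.75,
                             mutation_prob = list(
                               BRAF = c(PCM = 0.45, MBM = 0.478, ECM = 0.45),
                               NRAS = c(PCM = 0.20, MBM = 0.22, ECM = 0.20),
                               NF1  = c(PCM = 0.60, MBM = 0.683, ECM = 0.60),
                               PTEN = c(PCM = 0.081, MBM = 0.163, ECM = 0.060)),
                             assessed_prob = c(BRAF = 0.98, NRAS = 0.97,
                                               NF1 = 0.44, PTEN = 0.92),
                             tmb_mean = c(PCM = 11, MBM = 9, ECM = 8),
                             tmb_size = 3,
                             footprint_mb = 1.4,
                             homozygosity_prob = stats::setNames(
                               rep(0.15, length(HLA_LOCI)), HLA_LOCI),
                             ic50_log10_range = c(0, 5),
                             peptides_per_mutation = 1.5,
                             pdl1_prob = c(PCM = 0.35, MBM = 0.25, ECM = 0.30)) {
  if (is.null(dirichlet_conc)) {
    base <- stats::setNames(
      c(2, 1, 2, 1.5, 1, 1.5, 3, 3, 1.5, 1.5, 12), CELL_TYPES)
    mbm <- base
    # planted immune contexture: depleted B/M2/NK/Treg/DC, enriched M1
    mbm[c("B_cells", "Macrophages_M2", "NK_cells", "Tregs",
          "Dendritic_cells")] <- c(0.8, 0.8, 0.7, 0.6, 0.8)
    mbm["Macrophages_M1"] <- 1.6
    dirichlet_conc <- list(PCM = base, MBM = mbm, ECM = base)
  }
  cfg <- list(n_per_group = n_per_group, n_genes = n_genes,
              markers_per_type = markers_per_type, seed = seed,
              noise_sigma = noise_sigma, dirichlet_conc = dirichlet_conc,
              min_tumor_fraction = min_tumor_fraction,
              signature_shift = signature_shift,
              pten_angiogenesis_shift = pten_angiogenesis_shift,
              mutation_prob = mutation_prob, assessed_prob = assessed_prob,
              tmb_mean = tmb_mean, tmb_size = tmb_size,
              footprint_mb = footprint_mb,
              homozygosity_prob = homozygosity_prob,
              ic50_log10_range = ic50_log10_range,
              peptides_per_mutation = peptides_per_mutation,
              pdl1_prob = pdl1_prob)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (any(cfg$n_per_group < 1)) abort("configuration error: group sizes must be >= 1")
  if (is.null(names(cfg$n_per_group)) ||
      !all(names(cfg$n_per_group) %in% COHORT_GROUPS))
    abort("configuration error: n_per_group must be named with cohort groups")
  probs <- c(unlist(cfg$mutation_prob), cfg$assessed_prob,
             cfg$homozygosity_prob, cfg$pdl1_prob)
  if (any(probs < 0 | probs > 1))
    abort("configuration error: probabilities must lie in [0, 1]")
  if (any(unlist(cfg$dirichlet_conc) <= 0))
    abort("configuration error: Dirichlet concentrations must be > 0")
  if (cfg$noise_sigma < 0) abort("configuration error: noise_sigma must be >= 0")
  if (cfg$min_tumor_fraction < 0 || cfg$min_tumor_fraction >= 1)
    abort("configuration error: min_tumor_fraction must be in [0, 1)")
  if (cfg$n_genes < 10 * length(CELL_TYPES)) {
    abort("configuration error: n_genes (", cfg$n_genes,
          ") must be >= 10 x number of cell types (",
          10 * length(CELL_TYPES), ")")
  }
  cfg
}

# derive per-table child seeds so adding a table never perturbs the others
child_seeds <- function(seed, n = 8) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# the synthetic gene universe: named signature/special genes, cell-type
# marker blocks, background filler up to n_genes
gene_universe <- function(cfg) {
  specials <- unique(c(unlist(builtin_genesets(), use.names = FALSE),
                       SPECIAL_GENES))
  markers <- unlist(lapply(CELL_TYPES, function(ct) {
    sprintf("MK.%s.%02d", ct, seq_len(cfg$markers_per_type))
  }))
  need <- length(specials) + length(markers)
  if (cfg$n_genes < 10 * length(CELL_TYPES)) {
    abort("configuration error: n_genes (", cfg$n_genes,
          ") must be >= 10 x number of cell types (",
          10 * length(CELL_TYPES), ")")
  }
  if (cfg$n_genes < need) {
    abort("configuration error: n_genes (", cfg$n_genes,
          ") too small for ", need, " named + marker genes")
  }
  background <- sprintf("BG%04d", seq_len(cfg$n_genes - need))
  list(genes = c(specials, markers, background),
       markers = markers, specials = specials, background = background)
}

#' Generate synthetic cell-type reference expression profiles
#'
#' Builds a genes x cell-types matrix of mean TPM expression. Each cell
#' type owns a disjoint block of `markers_per_type` marker genes whose
#' expression sits 3 log2 units above the log-normal background; every
#' column is then TPM-normalized (sums to 1e6) so that a convex mixture of
#' columns is itself a valid TPM profile. Deterministic given the config
#' seed.
#'
#' @param config a [generator_config()].
#' @return numeric matrix, genes x cell types.
#' @export
generate_reference_profiles <- function(config) {
  config <- validate_generator_config(config)
  uni <- gene_universe(config)
  seeds <- child_seeds(config$seed)
  set.seed(seeds[1])
  n_types <- length(CELL_TYPES)
  # log-normal background on the log2 scale: location 3, scale 1.2
  base <- matrix(2^stats::rnorm(length(uni$genes) * n_types, mean = 3, sd = 1.2),
                 nrow = length(uni$genes), ncol = n_types,
                 dimnames = list(uni$genes, CELL_TYPES))
  for (i in seq_along(CELL_TYPES)) {
    mk <- sprintf("MK.%s.%02d", CELL_TYPES[i], seq_len(config$markers_per_type))
    # one baseline per marker gene so the owning type always dominates:
    # +3 log2 vs background in the owner, -2 log2 everywhere else
    b <- 2^stats::rnorm(length(mk), mean = 3, sd = 1.2)
    base[mk, ] <- b %o% rep(2^-2, n_types)
    base[mk, i] <- b * 2^3
  }
  sweep(base, 2, colSums(base), "/") * 1e6
}

# group-wise Dirichlet mixing fractions with the tumor compartment clamped
draw_fractions <- function(cfg, groups) {
  n <- length(groups)
  frac <- matrix(0, n, length(CELL_TYPES),
                 dimnames = list(NULL, CELL_TYPES))
  for (i in seq_len(n)) {
    conc <- cfg$dirichlet_conc[[groups[i]]]
    g <- stats::rgamma(length(conc), shape = conc, rate = 1)
    p <- stats::setNames(g / sum(g), names(conc))
    if (p["Tumor"] < cfg$min_tumor_fraction) {
      imm <- setdiff(CELL_TYPES, "Tumor")
      p[imm] <- p[imm] / sum(p[imm]) * (1 - cfg$min_tumor_fraction)
      p["Tumor"] <- cfg$min_tumor_fraction
    }
    frac[i, ] <- p
  }
  frac
}

#' Generate a synthetic labeled cohort
#'
#' Produces every artifact the pipeline consumes plus the ground truth used
#' by recovery tests:
#' \describe{
#'   \item{expression}{genes x samples TPM matrix: a convex mixture of the
#'     reference profiles per sample (mixing fractions Dirichlet by group,
#'     tumor fraction clamped), multiplied by log-normal noise, with the
#'     configured log2 signature shifts applied to the designated group,
#'     then re-normalized to TPM.}
#'   \item{manifest}{sample ids, groups, PD-L1 status.}
#'   \item{mutations}{pathogenic driver mutations drawn per assessed sample
#'     (Bernoulli at group rates), VUS missense filler realizing the
#'     negative-binomial TMB counts, and a few germline-flagged records.}
#'   \item{hla}{genotypes at the seven loci, homozygous at the configured
#'     per-locus rates.}
#'   \item{neoantigens}{peptides with log10-uniform IC50 values.}
#'   \item{truth}{true mixing fractions, planted shifts, mutant sets,
#'     assessed coverage, and realized TMB counts.}
#' }
#' Fully reproducible from the master seed; each table uses its own derived
#' child seed so adding one table never perturbs another.
#'
#' @param config a [generator_config()].
#' @return list with elements `expression`, `manifest`, `mutations`, `hla`,
#'   `neoantigens`, `reference`, `truth`.
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  seeds <- child_seeds(config$seed)
  reference <- generate_reference_profiles(config)
  sets <- builtin_genesets()

  groups <- rep(names(config$n_per_group), config$n_per_group)
  sample_id <- unlist(lapply(names(config$n_per_group), function(g) {
    sprintf("%s_%03d", g, seq_len(config$n_per_group[[g]]))
  }))

  # --- mixing fractions and raw mixture -------------------------------
  set.seed(seeds[2])
  fractions <- draw_fractions(config, groups)
  rownames(fractions) <- sample_id
  expr <- reference %*% t(fractions)          # genes x samples, TPM scale
  colnames(expr) <- sample_id

  # --- mutations (needed before conditional expression shifts) --------
  set.seed(seeds[4])
  drivers <- names(config$mutation_prob)
  assessed <- list()
  mut_rows <- list()
  true_mutants <- character(0)
  for (gene in drivers) {
    p_cov <- if (gene %in% names(config$assessed_prob))
      config$assessed_prob[[gene]] else 1
    cov <- stats::runif(length(sample_id)) < p_cov
    assessed[[gene]] <- sample_id[cov]
    rate <- config$mutation_prob[[gene]][groups]
    mut <- cov & (stats::runif(length(sample_id)) < rate)
    if (any(mut)) {
      mut_rows[[gene]] <- data.frame(
        sample_id = sample_id[mut], gene = gene,
        variant_class = "missense", pathogenicity = "pathogenic",
        germline_flagged = FALSE, stringsAsFactors = FALSE)
      true_mutants <- c(true_mutants, paste(sample_id[mut], gene, sep = ":"))
    }
  }
  # TMB filler: VUS missense records realizing negative-binomial counts
  uni <- gene_universe(config)
  driver_missense <- table(factor(
    unlist(lapply(mut_rows, function(d) d$sample_id)), levels = sample_id))
  target <- stats::rnbinom(length(sample_id), size = config$tmb_size,
                           mu = config$tmb_mean[groups] * config$footprint_mb)
  filler_n <- pmax(0L, as.integer(target) - as.integer(driver_missense))
  filler_n <- pmin(filler_n, length(uni$background))
  filler <- lapply(seq_along(sample_id), function(i) {
    if (filler_n[i] == 0) return(NULL)
    data.frame(sample_id = sample_id[i],
               gene = sample(uni$background, filler_n[i]),
               variant_class = "missense", pathogenicity = "VUS",
               germline_flagged = FALSE, stringsAsFactors = FALSE)
  })
  # germline-flagged missense (excluded from TMB by construction)
  germ_n <- stats::rpois(length(sample_id), 2)
  germ <- lapply(seq_along(sample_id), function(i) {
    if (germ_n[i] == 0) return(NULL)
    data.frame(sample_id = sample_id[i],
               gene = sample(uni$background, min(germ_n[i], length(uni$background))),
               variant_class = "missense", pathogenicity = "likely_benign",
               germline_flagged = TRUE, stringsAsFactors = FALSE)
  })
  mutations <- do.call(rbind, c(mut_rows, filler, germ))
  rownames(mutations) <- NULL
  tmb_count <- as.integer(driver_missense) + filler_n
  names(tmb_count) <- sample_id

  # --- planted expression effects and noise ---------------------------
  set.seed(seeds[3])
  for (g in names(config$signature_shift)) {
    for (sig in names(config$signature_shift[[g]])) {
      genes <- intersect(sets[[sig]], rownames(expr))
      cols <- groups == g
      expr[genes, cols] <- expr[genes, cols] *
        2^config$signature_shift[[g]][[sig]]
    }
  }
  if (config$pten_angiogenesis_shift != 0) {
    pten_mut <- unique(mutations$sample_id[
      mutations$gene == "PTEN" & mutations$pathogenicity == "pathogenic"])
    cols <- sample_id %in% pten_mut & groups == "MBM"
    genes <- intersect(sets$ANGIOGENESIS, rownames(expr))
    expr[genes, cols] <- expr[genes, cols] * 2^config$pten_angiogenesis_shift
  }
  if (config$noise_sigma > 0) {
    expr <- expr * exp(matrix(
      stats::rnorm(length(expr), 0, config$noise_sigma),
      nrow = nrow(expr)))
  }
  expr <- sweep(expr, 2, colSums(expr), "/") * 1e6   # back to TPM

  # --- manifest --------------------------------------------------------
  set.seed(seeds[7])
  manifest <- data.frame(
    sample_id = sample_id, group = groups,
    pdl1_positive = stats::runif(length(sample_id)) < config$pdl1_prob[groups],
    age_band = "", sex = "", stringsAsFactors = FALSE)

  # --- HLA genotypes ---------------------------------------------------
  set.seed(seeds[5])
  allele_pool <- lapply(stats::setNames(HLA_LOCI, HLA_LOCI), function(l) {
    sprintf("%s*%02d:01", sub("HLA-", "", l), 1:12)
  })
  hla <- do.call(rbind, lapply(HLA_LOCI, function(l) {
    hom <- stats::runif(length(sample_id)) < config$homozygosity_prob[[l]]
    a1 <- sample(allele_pool[[l]], length(sample_id), replace = TRUE)
    a2 <- ifelse(hom, a1, sample(allele_pool[[l]], length(sample_id),
                                 replace = TRUE))
    # re-draw accidental homozygotes among the intended heterozygotes
    clash <- !hom & a1 == a2
    while (any(clash)) {
      a2[clash] <- sample(allele_pool[[l]], sum(clash), replace = TRUE)
      clash <- !hom & a1 == a2
    }
    data.frame(sample_id = sample_id, locus = l, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  }))
  rownames(hla) <- NULL

  # --- neoantigens -----------------------------------------------------
  set.seed(seeds[6])
  npep <- stats::rpois(length(sample_id),
                       config$peptides_per_mutation * tmb_count)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  neo <- lapply(seq_along(sample_id), function(i) {
    if (npep[i] == 0) return(NULL)
    pep <- vapply(seq_len(npep[i]), function(k)
      paste(sample(aa, 9, replace = TRUE), collapse = ""), character(1))
    ic50 <- 10^stats::runif(npep[i], config$ic50_log10_range[1],
                            config$ic50_log10_range[2])
    data.frame(sample_id = sample_id[i], peptide = pep, ic50 = ic50,
               stringsAsFactors = FALSE)
  })
  neoantigens <- do.call(rbind, neo)
  rownames(neoantigens) <- NULL

  list(expression = validate_expression(expr),
       manifest = validate_manifest(manifest),
       mutations = mutations,
       hla = hla,
       neoantigens = neoantigens,
       reference = reference,
       truth = list(fractions = fractions,
                    shifts = config$signature_shift,
                    mutants = true_mutants,
                    assessed = assessed,
                    tmb_count = tmb_count))
}

#' Write a synthetic cohort to a directory as TSV artifacts
#'
#' Writes `expression.tsv`, `manifest.tsv`, `mutations.tsv`, `hla.tsv`,
#' `neoantigens.tsv`, `reference_profiles.tsv`, `genesets.gmt`, and the
#' truth tables (`truth_fractions.tsv`, `truth_tmb.tsv`). Byte-identical
#' across runs with the same config and seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_tsv_table(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_tsv_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tsv_table(cohort$hla, file.path(dir, "hla.tsv"))
  write_tsv_table(cohort$neoantigens, file.path(dir, "neoantigens.tsv"))
  ref <- data.frame(gene = rownames(cohort$reference), cohort$reference,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(ref, file.path(dir, "reference_profiles.tsv"))
  write_gmt(builtin_genesets(), file.path(dir, "genesets.gmt"))
  fr <- data.frame(sample_id = rownames(cohort$truth$fractions),
                   cohort$truth$fractions, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_table(fr, file.path(dir, "truth_fractions.tsv"))
  write_tsv_table(data.frame(sample_id = names(cohort$truth$tmb_count),
                             tmb_count = cohort$truth$tmb_count,
                             stringsAsFactors = FALSE),
                  file.path(dir, "truth_tmb.tsv"))
  invisible(dir)
}
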
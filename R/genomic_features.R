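# Genomic feature layer: pathogenicity filtering, tumor mutational burden,
# per-group pathogenic mutation frequencies, HLA homozygosity, and
# neoantigen affinity binning.

#' Keep only pathogenic and likely-pathogenic mutation records
#'
#' Variants classified benign, likely benign, or of unknown significance
#' (VUS) are excluded from mutation-frequency analyses.
#'
#' @param records mutation record data.frame (see [read_mutations()]).
#' @return the filtered data.frame (idempotent).
#' @export
filter_pathogenic <- function(records) {
  records[records$pathogenicity %in% c("pathogenic", "likely_pathogenic"), ,
          drop = FALSE]
}

#' Tumor mutational burden per sample
#'
#' Counts qualifying mutations per sample -- non-synonymous missense
#' variants not flagged as previously described germline alterations -- and
#' divides by the sequenced footprint. Samples are classified `high` when
#' TMB is greater than or equal to the cutoff (boundary is high), else
#' `low`.
#'
#' @param records mutation record data.frame.
#' @param footprint_mb sequenced footprint in megabases (default 1.4, the
#'   592-gene panel footprint).
#' @param cutoff TMB-high threshold in mutations/MB (default 10).
#' @param samples optional character vector of all profiled sample ids, so
#'   samples with zero qualifying mutations are reported; defaults to the
#'   samples present in `records`.
#' @param qualifying_classes variant classes counted (default `"missense"`;
#'   widen to include nonsense/frameshift for a broader non-synonymous
#'   definition).
#' @return data.frame with `sample_id`, `count`, `tmb`, `tmb_class`.
#' @export
tmb <- function(records, footprint_mb = 1.4, cutoff = 10, samples = NULL,
                qualifying_classes = "missense") {
  if (footprint_mb <= 0) abort("configuration error: footprint_mb must be > 0")
  keep <- records$variant_class %in% qualifying_classes &
    !records$germline_flagged
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  counts <- table(factor(records$sample_id[keep], levels = samples))
  tmb_val <- as.numeric(counts) / footprint_mb
  data.frame(sample_id = samples,
             count = as.integer(counts),
             tmb = tmb_val,
             tmb_class = ifelse(tmb_val >= cutoff, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pathogenic mutation frequency of a gene within a group
#'
#' `k` is the number of distinct assessed samples in the group with at
#' least one retained (pathogenic / likely pathogenic) record for the gene;
#' `n` is the number of assessed samples in the group. Per-gene assessment
#' coverage (panel denominators differ by gene) is an explicit optional
#' input, defaulting to every sample in the group. Percentages are rounded
#' half-up to one decimal.
#'
#' @param records mutation records, already passed through
#'   [filter_pathogenic()].
#' @param manifest cohort manifest data.frame.
#' @param gene gene symbol.
#' @param group cohort group label.
#' @param assessed optional character vector of sample ids with assessment
#'   coverage for this gene.
#' @return data.frame with `group`, `gene`, `k`, `n`, `pct`.
#' @export
mutation_frequency <- function(records, manifest, gene, group,
                               assessed = NULL) {
  in_group <- manifest$sample_id[manifest$group == group]
  n_samples <- if (is.null(assessed)) in_group else intersect(in_group, assessed)
  if (length(n_samples) == 0) {
    abort("no assessed samples for gene ", gene, " in group ", group)
  }
  mutated <- unique(records$sample_id[records$gene == gene])
  k <- length(intersect(mutated, n_samples))
  data.frame(group = group, gene = gene, k = k, n = length(n_samples),
             pct = round_half_up(100 * k / length(n_samples), 1),
             stringsAsFactors = FALSE)
}

#' HLA homozygosity calls and cohort rates
#'
#' A sample is homozygous at a locus when both detected alleles are
#' identical (string equality after whitespace trimming). Samples missing a
#' locus are excluded from that locus's denominator. When a manifest is
#' supplied, rates are additionally reported per group.
#'
#' @param genotypes HLA genotype data.frame (see [read_hla()]).
#' @param loci loci to assess (subset of [HLA_LOCI]).
#' @param manifest optional cohort manifest for per-group rates.
#' @return list with `calls` (sample_id, locus, homozygous) and `summary`
#'   (locus, optionally group, n, n_homozygous, pct).
#' @export
hla_homozygosity <- function(genotypes, loci = HLA_LOCI, manifest = NULL) {
  bad <- setdiff(loci, HLA_LOCI)
  if (length(bad) > 0) abort("unknown HLA locus: ", paste(bad, collapse = ", "))
  g <- genotypes[genotypes$locus %in% loci, , drop = FALSE]
  calls <- data.frame(sample_id = g$sample_id, locus = g$locus,
                      homozygous = trimws(g$allele1) == trimws(g$allele2),
                      stringsAsFactors = FALSE)
  if (is.null(manifest)) {
    summary <- do.call(rbind, lapply(loci, function(l) {
      cl <- calls[calls$locus == l, ]
      data.frame(locus = l, n = nrow(cl), n_homozygous = sum(cl$homozygous),
                 pct = round_half_up(100 * mean(cl$homozygous), 1),
                 stringsAsFactors = FALSE)
    }))
  } else {
    grp <- stats::setNames(manifest$group, manifest$sample_id)
    summary <- do.call(rbind, lapply(loci, function(l) {
      cl <- calls[calls$locus == l, ]
      do.call(rbind, lapply(intersect(COHORT_GROUPS, unique(grp)), function(g0) {
        sub <- cl[grp[cl$sample_id] == g0, ]
        if (nrow(sub) == 0) return(NULL)
        data.frame(locus = l, group = g0, n = nrow(sub),
                   n_homozygous = sum(sub$homozygous),
                   pct = round_half_up(100 * mean(sub$homozygous), 1),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(calls = calls, summary = summary)
}

NEOANTIGEN_BINS <- c("high", "intermediate", "low", "none")

#' Bin neoantigen MHC-I binding affinities
#'
#' IC50 intervals (nmol/L): high `[0, 50)`, intermediate `[50, 500)`, low
#' `[500, 5000)`, none `[5000, Inf)`. The published interval wording leaves
#' the exact boundary points 50/500/5000 unassigned; lower-closed half-open
#' intervals are used as the convention, so e.g. IC50 = 50 is intermediate.
#'
#' @param ic50 positive numeric vector, nmol/L.
#' @return factor with levels high, intermediate, low, none.
#' @export
neoantigen_bin <- function(ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0)) {
    abort("validation error: ic50 must be positive and finite")
  }
  cut(ic50, breaks = c(0, 50, 500, 5000, Inf), labels = NEOANTIGEN_BINS,
      right = FALSE)
}

#' Neoantigen load per sample and affinity bin
#'
#' @param records neoantigen record data.frame (see [read_neoantigens()]).
#' @param samples optional sample ids to report (zero counts included).
#' @return data.frame with `sample_id` and one count column per bin; the
#'   four bin counts sum to the sample's record count.
#' @export
neoantigen_load <- function(records, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  bins <- neoantigen_bin(records$ic50)
  tab <- table(factor(records$sample_id, levels = samples), bins)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (b in NEOANTIGEN_BINS) out[[b]] <- as.integer(tab[, b])
  out
}
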
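#' Configuration of the sequential trio-filtering cascade
#'
#' The published workflow states the filtering principles (phenotype
#' consistency, inheritance-model compatibility, population frequency
#' consistent with disease prevalence, expected pathogenic mechanism)
#' without numeric thresholds; the frequency gates here are this
#' package's defaults, chosen at values conventional for severe
#' dominant-acting (1e-4) and recessive-allele (5e-3) pediatric disease,
#' and are fully configurable.
#'
#' @param af_max_dominant frequency ceiling for de novo / inherited
#'   dominant / X-linked variants.
#' @param af_max_recessive_allele per-allele ceiling for recessive
#'   (homozygous or compound-heterozygous) configurations.
#' @param require_panel_match require the gene on the phenotype panel.
#' @param require_mechanism_match enforce the expected pathogenic
#'   mechanism (loss-of-function consistency check).
#' @param reportable_classes clinical classes eligible for reporting;
#'   variants of uncertain significance are excluded by default,
#'   mirroring the laboratory reporting policy.
#' @return list of class \code{prioritize_config}.
#' @export
prioritize_config <- function(af_max_dominant = 1e-4,
                              af_max_recessive_allele = 5e-3,
                              require_panel_match = TRUE,
                              require_mechanism_match = TRUE,
                              reportable_classes = c("pathogenic",
                                                     "likely_pathogenic")) {
  stopifnot(af_max_dominant <= af_max_recessive_allele)
  structure(list(af_max_dominant = af_max_dominant,
                 af_max_recessive_allele = af_max_recessive_allele,
                 require_panel_match = require_panel_match,
                 require_mechanism_match = require_mechanism_match,
                 reportable_classes = reportable_classes),
            class = "prioritize_config")
}

#' Resolve the Mendelian transmission model of trio variants
#'
#' Per autosomal (or female-proband chrX) variant: proband het with both
#' parents homozygous reference is de novo; proband het with exactly one
#' carrier parent is inherited from that parent; proband homozygous
#' alternate with both parents het is autosomal-recessive homozygous.
#' Per gene, two proband hets with strictly opposite single-parent
#' origins additionally yield a compound-heterozygous call (one per
#' maternal/paternal pairing). The singleton dominant interpretations are
#' retained alongside it: which reading is correct depends on the
#' downstream frequency, panel-mode and classification gates (a
#' recessive-only gene eliminates the singletons, a pairing involving an
#' unreportable allele eliminates the compound call), so the resolution
#' stage reports both and lets the conjunctive cascade decide. On
#' non-pseudoautosomal chrX of a male proband, a
#' hemizygous call with carrier mother and reference father is X-linked
#' hemizygous. Everything else — including Mendelian-inconsistent
#' configurations, which are flagged rather than raised — is unresolved.
#'
#' @param variants TrioVariant data.frame (from \code{\link{read_trio_vcf}},
#'   \code{\link{simulate_trio_variants}} or \code{\link{load_trio_genotypes}}).
#' @param proband_sex "M" or "F".
#' @return data.frame with one row per call: \code{model}, \code{gene},
#'   \code{keys} (list column of chrom:pos:ref:alt keys), \code{row_idx}
#'   (list column of contributing variant row indices),
#'   \code{mendel_error}.
#' @export
determine_inheritance <- function(variants, proband_sex = "M") {
  n <- nrow(variants)
  key <- variant_key(variants)
  xctx <- is_nonpar_x(variants$chrom, variants$pos) & proband_sex == "M"
  model <- rep("unresolved", n)
  mendel <- rep(FALSE, n)
  gp <- variants$gt_proband; gm <- variants$gt_mother; gf <- variants$gt_father
  complete <- gp != "missing" & gm != "missing" & gf != "missing"
  carrier <- function(g) g %in% c("het", "hom_alt", "hemi")

  auto <- complete & !xctx
  model[auto & gp == "het" & gm == "hom_ref" & gf == "hom_ref"] <- "de_novo"
  model[auto & gp == "het" & carrier(gm) & gf == "hom_ref"] <- "inherited_maternal"
  model[auto & gp == "het" & gm == "hom_ref" & carrier(gf)] <- "inherited_paternal"
  model[auto & gp == "hom_alt" & gm == "het" & gf == "het"] <- "ar_homozygous"
  mendel[auto & gp == "hom_alt" & (gm == "hom_ref" | gf == "hom_ref")] <- TRUE

  xl <- complete & xctx
  model[xl & gp == "hemi" & gm == "het" & gf == "hom_ref"] <- "xl_hemizygous"
  mendel[xl & gp == "hemi" & gm == "hom_ref" & carrier(gf)] <- TRUE

  calls <- data.frame(model = model, gene = variants$gene,
                      stringsAsFactors = FALSE)
  calls$keys <- as.list(key)
  calls$row_idx <- as.list(seq_len(n))
  calls$mendel_error <- mendel

  # per-gene compound heterozygotes: every maternal x paternal het pairing
  extra <- list()
  for (g in unique(variants$gene[!is.na(variants$gene)])) {
    ix <- which(variants$gene == g)
    mat <- ix[model[ix] == "inherited_maternal"]
    pat <- ix[model[ix] == "inherited_paternal"]
    for (i in mat) {
      for (j in pat) {
        extra[[length(extra) + 1]] <- data.frame(
          model = "compound_het", gene = g,
          keys = I(list(c(key[i], key[j]))),
          row_idx = I(list(c(i, j))), mendel_error = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(calls, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Population-frequency gate of an inheritance call
#'
#' Dominant-acting models (de novo, inherited dominant, X-linked) require
#' every variant at or below \code{af_max_dominant}; recessive models
#' (homozygous, compound het) use the per-allele recessive ceiling.
#' Absent frequencies count as novel (0).
#'
#' @param call one row of \code{\link{determine_inheritance}} output.
#' @param variants the TrioVariant data.frame the call indexes into.
#' @param config \code{\link{prioritize_config}}.
#' @return TRUE/FALSE.
#' @export
frequency_filter <- function(call, variants, config = prioritize_config()) {
  af <- variants$af_pop[call$row_idx[[1]]]
  af[is.na(af)] <- 0
  lim <- if (call$model %in% c("ar_homozygous", "compound_het")) {
    config$af_max_recessive_allele
  } else {
    config$af_max_dominant
  }
  all(af <= lim)
}

#' Phenotype-panel and pathogenic-mechanism gate
#'
#' The gene must sit on the panel (unless disabled) with an inheritance
#' mode compatible with the resolved model (de novo / inherited map to
#' AD, recessive models to AR, hemizygous to XL), and the variant
#' consequence must match the gene's expected mechanism: genes with a
#' loss-of-function mechanism require lof (or splice) alleles, genes with
#' a non-lof mechanism reject lof alleles, \code{either} accepts both.
#'
#' @inheritParams frequency_filter
#' @param panel panel data.frame (\code{\link{load_panel}}).
#' @return TRUE/FALSE.
#' @export
panel_mechanism_filter <- function(call, variants, panel,
                                   config = prioritize_config()) {
  if (call$model == "unresolved") return(FALSE)
  i <- match(call$gene, panel$symbol)
  if (is.na(i)) return(!config$require_panel_match)
  modes <- strsplit(panel$inheritance_modes[i], ",")[[1]]
  need <- switch(call$model,
                 de_novo = "AD", inherited_maternal = "AD",
                 inherited_paternal = "AD",
                 ar_homozygous = "AR", compound_het = "AR",
                 xl_hemizygous = "XL")
  if (!(need %in% modes)) return(FALSE)
  if (!config$require_mechanism_match) return(TRUE)
  csq <- variants$consequence[call$row_idx[[1]]]
  lofish <- csq %in% c("lof", "splice")
  switch(panel$mechanism[i],
         either = TRUE,
         lof = all(lofish),
         non_lof = all(!lofish),
         FALSE)
}

#' Sequential prioritization of resolved trio calls
#'
#' Applies, in order, the inheritance resolution, the frequency gate, the
#' panel/mechanism gate, and the reportable-class gate (variants of
#' uncertain significance and below are never reported). Survivors are
#' ranked by clinical class (pathogenic before likely pathogenic), then
#' rarity (lower maximum allele frequency first), then model specificity
#' (de novo and recessive/hemizygous configurations before inherited
#' dominant). The filters are conjunctive, so the survivor set does not
#' depend on their order; the \code{passed_filters} audit string records
#' the cascade.
#'
#' @param variants TrioVariant data.frame.
#' @param proband_sex "M" or "F".
#' @param panel panel data.frame.
#' @param config \code{\link{prioritize_config}}.
#' @return data.frame of candidate diagnoses, ranked; columns model,
#'   gene, keys (list), max_af, clinical_class, score, passed_filters.
#' @export
prioritize_candidates <- function(variants, proband_sex = "M",
                                  panel = load_panel(),
                                  config = prioritize_config()) {
  calls <- determine_inheritance(variants, proband_sex)
  empty <- data.frame(model = character(0), gene = character(0),
                      keys = I(list()), max_af = numeric(0),
                      clinical_class = character(0), score = numeric(0),
                      rank = integer(0), passed_filters = character(0),
                      stringsAsFactors = FALSE)
  calls <- calls[calls$model != "unresolved", , drop = FALSE]
  if (nrow(calls) == 0) return(empty)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, , drop = FALSE]
    rows <- call$row_idx[[1]]
    cls <- variants$clinical_class[rows]
    keep[i] <- frequency_filter(call, variants, config) &&
      panel_mechanism_filter(call, variants, panel, config) &&
      all(cls %in% config$reportable_classes)
  }
  surv <- calls[keep, , drop = FALSE]
  if (nrow(surv) == 0) return(empty)
  class_rank <- vapply(seq_len(nrow(surv)), function(i) {
    cls <- variants$clinical_class[surv$row_idx[[i]]]
    if (all(cls == "pathogenic")) 2 else 1
  }, numeric(1))
  max_af <- vapply(seq_len(nrow(surv)), function(i) {
    af <- variants$af_pop[surv$row_idx[[i]]]
    af[is.na(af)] <- 0
    max(af)
  }, numeric(1))
  specific <- ifelse(surv$model %in% c("inherited_maternal",
                                       "inherited_paternal"), 0, 1)
  o <- order(-class_rank, max_af, -specific)
  out <- data.frame(model = surv$model[o], gene = surv$gene[o],
                    stringsAsFactors = FALSE)
  out$keys <- surv$keys[o]
  out$max_af <- max_af[o]
  out$clinical_class <- ifelse(class_rank[o] == 2, "pathogenic",
                               "likely_pathogenic")
  out$score <- class_rank[o] * 1e4 + specific[o] * 1e2 - log10(max_af[o] + 1e-9)
  out$rank <- seq_len(nrow(out))
  out$passed_filters <- paste("inheritance", "frequency", "panel_mechanism",
                              "reportable_class", sep = ">")
  out
}

#' Full trio prioritization from a VCF file
#'
#' Composition of \code{\link{read_trio_vcf}} and
#' \code{\link{prioritize_candidates}}.
#'
#' @param vcf path to the trio VCF.
#' @param pedigree named vector (proband/mother/father) of sample names.
#' @param proband_sex "M" or "F".
#' @param panel panel data.frame.
#' @param config \code{\link{prioritize_config}}.
#' @return ranked candidate data.frame (see
#'   \code{\link{prioritize_candidates}}).
#' @export
prioritize_trio <- function(vcf, pedigree = c(proband = "PROBAND",
                                              mother = "MOTHER",
                                              father = "FATHER"),
                            proband_sex = "M", panel = load_panel(),
                            config = prioritize_config()) {
  variants <- read_trio_vcf(vcf, pedigree, proband_sex)
  prioritize_candidates(variants, proband_sex, panel, config)
}
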
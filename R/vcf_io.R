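#' Read a trio VCF into the variant table the prioritization cascade uses
#'
#' One row is emitted per ALT allele per site. Genotypes are interpreted
#' relative to that ALT allele: \code{hom_ref} (no copy of the allele),
#' \code{het} (one copy, diploid call), \code{hom_alt} (two copies),
#' \code{hemi} (one copy in a haploid call on non-pseudoautosomal chrX/chrY
#' of a male sample), \code{missing}. A diploid heterozygous call on
#' non-PAR chrX of a male proband is kept as \code{het} and flagged in the
#' \code{x_het_male} column rather than silently converted.
#'
#' @param path VCF 4.x file with per-sample GT.
#' @param pedigree named character vector with elements \code{proband},
#'   \code{mother}, \code{father} giving the VCF sample names.
#' @param proband_sex "M" or "F".
#' @param info_keys named list of INFO keys carrying the annotations:
#'   \code{af} (population allele frequency, per-ALT), \code{class}
#'   (clinical classification), \code{gene}, \code{consequence}. Defaults
#'   follow gnomAD/ClinVar-style conventions.
#' @return data.frame with columns chrom, pos, ref, alt, gene, consequence,
#'   gt_proband, gt_mother, gt_father, af_pop, clinical_class, x_het_male.
#' @export
read_trio_vcf <- function(path, pedigree, proband_sex = "M",
                          info_keys = list(af = "GNOMAD_AF",
                                           class = "CLNSIG",
                                           gene = "GENE",
                                           consequence = "CSQ")) {
  stopifnot(all(c("proband", "mother", "father") %in% names(pedigree)))
  vcf <- VariantAnnotation::readVcf(path, genome = "toy")
  samples <- colnames(vcf)
  missing_samples <- setdiff(unname(pedigree[c("proband", "mother", "father")]),
                             samples)
  if (length(missing_samples) > 0) {
    stop("pedigree sample(s) absent from VCF header: ",
         paste(missing_samples, collapse = ", "))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  idx <- rep(seq_along(n_alt), n_alt)       # site index per output row
  alt_k <- sequence(n_alt)                  # ALT allele index per row
  alts <- as.character(unlist(VariantAnnotation::alt(vcf)))

  gt <- VariantAnnotation::geno(vcf)$GT
  info <- VariantAnnotation::info(vcf)
  pull_info <- function(key, per_alt = FALSE, default = NA) {
    if (is.null(key) || !(key %in% colnames(info))) {
      return(rep(default, length(idx)))
    }
    v <- info[[key]]
    if (methods::is(v, "List") || is.list(v)) {
      u <- unlist(lapply(seq_along(idx), function(i) {
        vi <- v[[idx[i]]]
        if (length(vi) == 0) return(default)
        if (per_alt && length(vi) >= alt_k[i]) return(vi[alt_k[i]])
        vi[1]
      }))
      u
    } else {
      v[idx]
    }
  }

  chrom <- as.character(GenomicRanges::seqnames(rr))[idx]
  pos <- GenomicRanges::start(rr)[idx]
  sex_hemi_ok <- proband_sex == "M" & is_nonpar_x(chrom, pos)

  classify <- function(sample_name, hemi_legal) {
    g <- gt[idx, pedigree[[sample_name]]]
    vapply(seq_along(g), function(i) {
      classify_gt(g[i], alt_k[i], hemi_legal[i])
    }, character(1))
  }
  gt_p <- classify("proband", sex_hemi_ok)
  gt_m <- classify("mother", rep(FALSE, length(idx)))
  gt_f <- classify("father", sex_hemi_ok)  # father is male by definition

  out <- data.frame(
    chrom = chrom, pos = pos,
    ref = as.character(rr$REF)[idx],
    alt = alts,
    gene = as.character(pull_info(info_keys$gene, default = NA_character_)),
    consequence = as.character(pull_info(info_keys$consequence,
                                         default = "other")),
    gt_proband = gt_p, gt_mother = gt_m, gt_father = gt_f,
    af_pop = as.numeric(pull_info(info_keys$af, per_alt = TRUE,
                                  default = NA_real_)),
    clinical_class = normalize_clinical_class(
      as.character(pull_info(info_keys$class, default = "unknown"))),
    stringsAsFactors = FALSE
  )
  out$x_het_male <- sex_hemi_ok & out$gt_proband == "het"
  rownames(out) <- NULL
  out
}

# One GT string -> genotype class relative to ALT allele index `k`.
classify_gt <- function(g, k, hemi_legal) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(k))
  if (length(alleles) == 1L) {
    if (n_alt == 1L) return(if (hemi_legal) "hemi" else "hom_alt")
    return("hom_ref")
  }
  if (n_alt == 0L) "hom_ref" else if (n_alt == 1L) "het" else "hom_alt"
}

normalize_clinical_class <- function(x) {
  x <- tolower(gsub("[ _]", "_", x))
  allowed <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
               "benign", "unknown")
  x[x == "uncertain_significance"] <- "vus"
  x[!(x %in% allowed)] <- "unknown"
  x
}
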
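#' Declare a planted causal configuration for the trio simulator
#'
#' @param model one of de_novo, ar_homozygous, compound_het,
#'   xl_hemizygous, inherited_dominant.
#' @param gene panel gene symbol to plant into.
#' @return one-row data.frame (rbind-able).
#' @export
trio_truth <- function(model = c("de_novo", "ar_homozygous", "compound_het",
                                 "xl_hemizygous", "inherited_dominant"),
                       gene) {
  model <- match.arg(model)
  data.frame(model = model, gene = gene, stringsAsFactors = FALSE)
}

#' Simulate a trio variant table with planted causal variants
#'
#' Generates \code{n_noise} Mendelian-consistent background variants
#' (parents drawn from Hardy-Weinberg at a population frequency sampled
#' from a common-to-rare spectrum, proband genotype by random
#' transmission; clinical classes benign / likely_benign / vus /
#' unknown) plus the planted causal variant(s) for each truth row, with
#' genotypes dictated by the declared model and population frequency
#' below the corresponding rarity gate. Causal consequence honours the
#' panel mechanism (lof for lof-mechanism genes, missense for non-lof).
#'
#' @param truth \code{\link{trio_truth}} rows (NULL for a negative trio).
#' @param panel panel data.frame (\code{\link{load_panel}}).
#' @param n_noise background variant count.
#' @param proband_sex "M" or "F"; xl_hemizygous truth requires "M".
#' @param af_causal_max frequency ceiling for planted dominant-acting
#'   variants (recessive alleles use 10x this ceiling, still below the
#'   default recessive gate).
#' @param seed integer seed.
#' @return list with \code{variants} (TrioVariant data.frame),
#'   \code{manifest} (causal keys per truth row).
#' @export
simulate_trio_variants <- function(truth = NULL, panel = load_panel(),
                                   n_noise = 200L, proband_sex = "M",
                                   af_causal_max = 5e-5, seed = 1L) {
  if (!is.null(truth) && nrow(truth) > 0) {
    if (!all(truth$gene %in% panel$symbol)) {
      stop("truth gene(s) absent from panel")
    }
    if (any(truth$model == "xl_hemizygous") && proband_sex != "M") {
      stop("xl_hemizygous truth requires a male proband")
    }
  }
  with_seed(seed, {
    rows <- list()
    if (n_noise > 0) {
      af <- 10^stats::runif(n_noise, -5, log10(0.5))
      gene_pool <- c(panel$symbol, sprintf("GENE%03d", 1:60))
      g_m <- draw_hwe(af); g_f <- draw_hwe(af)
      g_p <- transmit(g_m, g_f)
      rows$noise <- data.frame(
        chrom = sprintf("chr%d", sample(1:22, n_noise, replace = TRUE)),
        pos = sample.int(5e7, n_noise),
        ref = sample(c("A", "C", "G", "T"), n_noise, replace = TRUE),
        alt = NA_character_,
        gene = sample(gene_pool, n_noise, replace = TRUE),
        consequence = sample(c("missense", "other", "inframe", "splice"),
                             n_noise, replace = TRUE,
                             prob = c(0.5, 0.3, 0.1, 0.1)),
        gt_proband = g_p, gt_mother = g_m, gt_father = g_f,
        af_pop = af,
        clinical_class = sample(c("benign", "likely_benign", "vus", "unknown"),
                                n_noise, replace = TRUE),
        causal = FALSE, stringsAsFactors = FALSE)
      # transversion partner so ref != alt
      rows$noise$alt <- chartr("ACGT", "TGCA", rows$noise$ref)
    }
    manifest <- list()
    if (!is.null(truth) && nrow(truth) > 0) {
      for (i in seq_len(nrow(truth))) {
        mech <- panel$mechanism[match(truth$gene[i], panel$symbol)]
        csq <- if (mech == "non_lof") "missense" else "lof"
        cls <- sample(c("pathogenic", "likely_pathogenic"), 1)
        mk <- function(n) data.frame(
          chrom = "chr2", pos = 1e8 + i * 1000L + seq_len(n),
          ref = "G", alt = "A", gene = truth$gene[i], consequence = csq,
          gt_proband = NA, gt_mother = NA, gt_father = NA,
          af_pop = stats::runif(n, 0, af_causal_max),
          clinical_class = cls, causal = TRUE, stringsAsFactors = FALSE)
        v <- switch(truth$model[i],
          de_novo = within(mk(1), {
            gt_proband <- "het"; gt_mother <- "hom_ref"; gt_father <- "hom_ref"
            af_pop <- 0
          }),
          ar_homozygous = within(mk(1), {
            gt_proband <- "hom_alt"; gt_mother <- "het"; gt_father <- "het"
            af_pop <- af_pop * 10
          }),
          compound_het = {
            v2 <- mk(2)
            v2$gt_proband <- "het"
            v2$gt_mother <- c("het", "hom_ref")
            v2$gt_father <- c("hom_ref", "het")
            v2$af_pop <- v2$af_pop * 10
            v2
          },
          xl_hemizygous = within(mk(1), {
            chrom <- "chrX"; pos <- 70000000L + i
            gt_proband <- "hemi"; gt_mother <- "het"; gt_father <- "hom_ref"
          }),
          inherited_dominant = within(mk(1), {
            gt_proband <- "het"
            from_mother <- stats::runif(1) < 0.5
            gt_mother <- if (from_mother) "het" else "hom_ref"
            gt_father <- if (from_mother) "hom_ref" else "het"
            rm(from_mother)
          }))
        rows[[paste0("causal", i)]] <- v
        manifest[[i]] <- list(model = truth$model[i], gene = truth$gene[i],
                              keys = variant_key(v))
      }
    }
    variants <- do.call(rbind, lapply(rows, function(d) d[names(rows[[1]])]))
    rownames(variants) <- NULL
    list(variants = variants,
         manifest = list(truth = manifest, n_noise = n_noise,
                         proband_sex = proband_sex, seed = as.integer(seed)))
  })
}

draw_hwe <- function(af) {
  u <- stats::runif(length(af))
  ifelse(u < (1 - af)^2, "hom_ref", ifelse(u < (1 - af)^2 + 2 * af * (1 - af),
                                           "het", "hom_alt"))
}

# child genotype by one random allele from each parent
transmit <- function(gm, gf) {
  p <- function(g) ifelse(g == "hom_alt", 1,
                          ifelse(g == "het", (stats::runif(length(g)) < 0.5) * 1, 0))
  n <- p(gm) + p(gf)
  c("hom_ref", "het", "hom_alt")[n + 1]
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Simulate a trio VCF file with planted causal variants
#'
#' Renders the table from \code{\link{simulate_trio_variants}} as VCF 4.2
#' text with samples PROBAND, MOTHER, FATHER and INFO keys
#' \code{GNOMAD_AF}, \code{CLNSIG}, \code{GENE}, \code{CSQ}. Male-proband
#' hemizygous chrX genotypes are written haploid.
#'
#' @inheritParams simulate_trio_variants
#' @return list with \code{vcf_lines}, \code{variants}, \code{manifest}.
#' @export
simulate_trio_vcf <- function(truth = NULL, panel = load_panel(),
                              n_noise = 200L, proband_sex = "M",
                              af_causal_max = 5e-5, seed = 1L) {
  sim <- simulate_trio_variants(truth, panel, n_noise, proband_sex,
                                af_causal_max, seed)
  v <- sim$variants
  o <- order(factor(v$chrom, levels = unique(v$chrom[order(v$chrom)])), v$pos)
  v <- v[o, , drop = FALSE]
  gt_str <- function(g, hap) {
    out <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", hemi = "1",
             missing = "./.")[g]
    out[hap & g == "hom_ref"] <- "0"
    unname(out)
  }
  hemi_ctx <- is_nonpar_x(v$chrom, v$pos)
  hap_p <- hemi_ctx & proband_sex == "M"
  info <- sprintf("GNOMAD_AF=%.3g;CLNSIG=%s;GENE=%s;CSQ=%s",
                  v$af_pop, v$clinical_class, v$gene, v$consequence)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t%s\tGT\t%s\t%s\t%s",
                  v$chrom, v$pos, v$ref, v$alt, info,
                  gt_str(v$gt_proband, hap_p),
                  gt_str(v$gt_mother, FALSE),
                  gt_str(v$gt_father, hemi_ctx))
  contigs <- unique(v$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical classification\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPROBAND\tMOTHER\tFATHER")
  list(vcf_lines = c(header, body), variants = v, manifest = sim$manifest)
}
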
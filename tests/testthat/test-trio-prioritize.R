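tv <- function(gene, gp, gm, gf, chrom = "chr2", pos = 1000L, ref = "G",
               alt = "A", csq = "missense", cls = "pathogenic", af = 0) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = csq, gt_proband = gp, gt_mother = gm,
             gt_father = gf, af_pop = af, clinical_class = cls,
             stringsAsFactors = FALSE)
}

test_that("inheritance resolution covers the canonical trio configurations", {
  v <- rbind(
    tv("TNNT2", "het", "hom_ref", "hom_ref", pos = 1L),
    tv("TNNI3", "hom_alt", "het", "het", pos = 2L),
    tv("MYH7", "het", "het", "hom_ref", pos = 3L),
    tv("ACTC1", "het", "hom_ref", "het", pos = 4L),
    tv("FAH", "missing", "het", "het", pos = 5L))
  calls <- determine_inheritance(v, "F")
  expect_equal(calls$model[match(c("TNNT2", "TNNI3", "MYH7", "ACTC1", "FAH"),
                                 calls$gene)],
               c("de_novo", "ar_homozygous", "inherited_maternal",
                 "inherited_paternal", "unresolved"))
})

test_that("two hets in one gene with opposite origins yield a compound het call", {
  v <- rbind(
    tv("GAA", "het", "hom_ref", "het", pos = 78078910L, chrom = "chr17"),
    tv("GAA", "het", "het", "hom_ref", pos = 78090909L, chrom = "chr17"))
  calls <- determine_inheritance(v, "F")
  ch <- calls[calls$model == "compound_het", ]
  expect_equal(nrow(ch), 1L)
  expect_equal(length(ch$keys[[1]]), 2L)
  expect_equal(classify_case_inheritance(calls), "autosomal_recessive")
  # in a recessive-only gene the cascade reports only the compound reading
  cand <- prioritize_candidates(v, "F")
  expect_equal(cand$model, "compound_het")
  expect_equal(length(cand$keys[[1]]), 2L)
  # a reportable dominant variant is not silenced by a same-gene VUS het
  # inherited from the other parent
  v3 <- rbind(
    tv("MYH7", "het", "hom_ref", "het", pos = 100L, chrom = "chr14"),
    tv("MYH7", "het", "het", "hom_ref", pos = 200L, chrom = "chr14",
       cls = "vus"))
  cand3 <- prioritize_candidates(v3, "M")
  expect_equal(cand3$model, "inherited_paternal")
  expect_equal(cand3$keys[[1]], "chr14:100:G:A")
  # two genes, one variant each, opposite parents: stays two dominant calls
  v2 <- rbind(
    tv("MYL2", "het", "het", "hom_ref", pos = 111356937L, chrom = "chr12"),
    tv("MYH7", "het", "hom_ref", "het", pos = 23887522L, chrom = "chr14"))
  calls2 <- determine_inheritance(v2, "M")
  expect_setequal(calls2$model, c("inherited_maternal", "inherited_paternal"))
  expect_equal(classify_case_inheritance(calls2), "inherited_dominant")
})

test_that("male X hemizygosity resolves and pedigree violations flag not throw", {
  v <- tv("NONO", "hemi", "het", "hom_ref", chrom = "chrX", pos = 70514185L)
  expect_equal(determine_inheritance(v, "M")$model, "xl_hemizygous")
  # hom_alt child of a hom_ref parent on an autosome: Mendelian error
  bad <- tv("FAH", "hom_alt", "hom_ref", "het")
  calls <- determine_inheritance(bad, "M")
  expect_equal(calls$model, "unresolved")
  expect_true(calls$mendel_error)
})

test_that("frequency gates match an exhaustive predicate sweep", {
  cfg <- prioritize_config()
  af_grid <- c(0, 1e-6, 5e-5, 1e-4, 2e-4, 1e-3, 5e-3, 6e-3, 0.01, 0.2, NA)
  models <- list(
    de_novo = tv("MYH7", "het", "hom_ref", "hom_ref"),
    dominant = tv("MYH7", "het", "het", "hom_ref"),
    xl = tv("NONO", "hemi", "het", "hom_ref", chrom = "chrX",
            pos = 70514185L),
    recessive = tv("FAH", "hom_alt", "het", "het"))
  for (m in names(models)) {
    for (af in af_grid) {
      v <- models[[m]]
      v$af_pop <- af
      call <- determine_inheritance(v, "M")
      got <- frequency_filter(call[1, ], v, cfg)
      lim <- if (m == "recessive") cfg$af_max_recessive_allele else
        cfg$af_max_dominant
      want <- is.na(af) || af <= lim  # absent frequency counts as novel
      expect_identical(got, want)
    }
  }
})

test_that("panel and mechanism gates enforce mode and lof consistency", {
  panel <- load_panel()
  cfg <- prioritize_config()
  # recessive lof in an AR gene passes
  ar <- tv("HADHB", "hom_alt", "het", "het", csq = "lof")
  call <- determine_inheritance(ar, "M")
  expect_true(panel_mechanism_filter(call[1, ], ar, panel, cfg))
  # de novo in an AR-only gene fails the mode match
  dn <- tv("HADHB", "het", "hom_ref", "hom_ref", csq = "lof")
  call <- determine_inheritance(dn, "M")
  expect_false(panel_mechanism_filter(call[1, ], dn, panel, cfg))
  # truncating allele in a gain-of-function gene fails the mechanism check
  lof_gof <- tv("PTPN11", "het", "hom_ref", "hom_ref", csq = "lof")
  call <- determine_inheritance(lof_gof, "M")
  expect_false(panel_mechanism_filter(call[1, ], lof_gof, panel, cfg))
  expect_true(panel_mechanism_filter(
    call[1, ], lof_gof, panel, prioritize_config(require_mechanism_match = FALSE)))
  # off-panel gene passes only when the panel match is not required
  off <- tv("GENE042", "het", "hom_ref", "hom_ref")
  call <- determine_inheritance(off, "M")
  expect_false(panel_mechanism_filter(call[1, ], off, panel, cfg))
  expect_true(panel_mechanism_filter(
    call[1, ], off, panel, prioritize_config(require_panel_match = FALSE)))
})

test_that("the cascade suppresses VUS and common variants", {
  vus <- tv("MYH7", "het", "hom_ref", "hom_ref", cls = "vus")
  expect_equal(nrow(prioritize_candidates(vus, "M")), 0L)
  common <- tv("MYH7", "het", "het", "hom_ref", af = 0.02)
  expect_equal(nrow(prioritize_candidates(common, "M")), 0L)
  ok <- tv("MYH7", "het", "hom_ref", "hom_ref", cls = "pathogenic")
  got <- prioritize_candidates(ok, "M")
  expect_equal(got$model, "de_novo")
  expect_equal(got$rank, 1L)
  expect_match(got$passed_filters, "inheritance.*frequency.*panel")
})

test_that("prioritization recovers every planted model from VCF round trips", {
  cases <- list(
    list(tt = trio_truth("de_novo", "PTPN11"), sex = "F"),
    list(tt = trio_truth("ar_homozygous", "TNNI3"), sex = "F"),
    list(tt = trio_truth("compound_het", "GAA"), sex = "M"),
    list(tt = trio_truth("xl_hemizygous", "TAZ"), sex = "M"),
    list(tt = trio_truth("inherited_dominant", "MYH7"), sex = "M"))
  for (i in seq_along(cases)) {
    sim <- simulate_trio_vcf(cases[[i]]$tt, n_noise = 150,
                             proband_sex = cases[[i]]$sex, seed = 100 + i)
    f <- write_temp_lines(sim$vcf_lines, ".vcf")
    cand <- prioritize_trio(f, proband_sex = cases[[i]]$sex)
    expect_gte(nrow(cand), 1L)
    expect_equal(cand$gene[1], cases[[i]]$tt$gene)
    expect_setequal(cand$keys[[1]], sim$manifest$truth[[1]]$keys)
  }
})

test_that("the conjunctive cascade is order-insensitive in its survivor set", {
  sim <- simulate_trio_variants(trio_truth("ar_homozygous", "HADHB"),
                                n_noise = 100, seed = 55)
  v <- sim$variants
  cfg <- prioritize_config()
  panel <- load_panel()
  calls <- determine_inheritance(v, "M")
  calls <- calls[calls$model != "unresolved", , drop = FALSE]
  survivors <- function(order_fns) {
    keep <- rep(TRUE, nrow(calls))
    for (fn in order_fns) keep <- keep & vapply(seq_len(nrow(calls)),
                                                function(i) fn(calls[i, ]),
                                                logical(1))
    which(keep)
  }
  f_freq <- function(c) frequency_filter(c, v, cfg)
  f_panel <- function(c) panel_mechanism_filter(c, v, panel, cfg)
  f_class <- function(c) all(v$clinical_class[c$row_idx[[1]]] %in%
                               cfg$reportable_classes)
  expect_equal(survivors(list(f_freq, f_panel, f_class)),
               survivors(list(f_class, f_panel, f_freq)))
  expect_equal(survivors(list(f_panel, f_class, f_freq)),
               survivors(list(f_freq, f_class, f_panel)))
})
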
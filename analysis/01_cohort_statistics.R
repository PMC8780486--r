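#!/usr/bin/env Rscript

# Cohort analysis: diagnostic yield of trio-WES in infantile cardiomyopathy,
# overall and by care setting, with inheritance-mode and etiology breakdowns.
#
# Finding (from the packaged 42-case cohort): 29/42 probands (69.0%) receive
# a molecular diagnosis; the yield is comparable in urgent (17/24, 70.8%) and
# non-urgent (12/18, 66.7%) settings. De novo events dominate (13/29, 44.8%),
# followed by autosomal-recessive forms (10, of which 3 compound
# heterozygous), inherited-dominant sarcomeric disease (4) and X-linked
# conditions (2). Metabolic/mitochondrial disorders are the most frequent
# etiology (10/29), then sarcomeric (9) and RASopathies (8).
#
# Writes: results/cohort_yield.tsv, results/cohort_breakdowns.tsv

library(cardiotrio)

dir.create("results", showWarnings = FALSE)
cases <- load_cohort_fixture()

yield <- do.call(rbind, lapply(c("all", "urgent", "non_urgent"), function(s) {
  y <- diagnostic_yield(cases, s)
  data.frame(stratum = s, n_total = y$n_total, n_diagnosed = y$n_diagnosed,
             yield_pct = y$yield_pct)
}))
write.table(yield, "results/cohort_yield.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(yield)

# inheritance: once from the case table, once by replaying the transcribed
# trio genotypes through the Mendelian resolver -- the two must agree
inh_table <- inheritance_breakdown(cases)
gt <- load_trio_genotypes()
replay <- vapply(split(seq_len(nrow(gt)), gt$case_id), function(ix) {
  sex <- cases$sex[match(gt$case_id[ix[1]], cases$case_id)]
  classify_case_inheritance(determine_inheritance(gt[ix, ], sex))
}, character(1))
stopifnot(all(table(replay)[names(inh_table$category_counts)] ==
                inh_table$category_counts))

eti <- etiology_breakdown(cases)
breakdowns <- rbind(
  data.frame(family = "inheritance",
             category = names(inh_table$category_counts),
             n = unname(inh_table$category_counts),
             pct = round(100 * unname(inh_table$fractions), 1)),
  data.frame(family = "etiology",
             category = names(eti$category_counts),
             n = unname(eti$category_counts),
             pct = round(100 * unname(eti$fractions), 1)))
write.table(breakdowns, "results/cohort_breakdowns.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(breakdowns)

cat("\nGenotype replay agrees with the transcribed inheritance labels for all",
    length(replay), "diagnosed cases.\n")
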
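fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "cardiotrio")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

read_fixture_tsv <- function(name) {
  utils::read.delim(fixture_path(name), comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Load the packaged infantile-cardiomyopathy cohort
#'
#' Forty-two consecutive trio-WES probands of the first year of life:
#' 29 per-case diagnostic records plus 13 undiagnosed cases reconstructed
#' to satisfy the published aggregate margins (those rows are marked
#' \code{record_source = "margin_synthetic"}). Every load re-validates the
#' fixture against the published counts and fails loudly on any mismatch;
#' the fixture is never repaired in code.
#'
#' @return data.frame, one row per case; see the column comments in
#'   \code{inst/extdata/cohort_cases.tsv}.
#' @examples
#' cases <- load_cohort_fixture()
#' table(cases$urgent, cases$diagnosed)
#' @export
load_cohort_fixture <- function() {
  x <- read_fixture_tsv("cohort_cases.tsv")
  x$case_id <- as.character(x$case_id)
  chk <- function(cond, what) {
    if (!isTRUE(cond)) stop("cohort fixture integrity failure: ", what)
  }
  chk(nrow(x) == 42L, "expected 42 cases")
  chk(identical(x$diagnosed, !is.na(x$gene)), "diagnosed must match gene presence")
  chk(sum(x$diagnosed) == 29L, "expected 29 diagnosed cases")
  chk(sum(x$urgent) == 24L && sum(!x$urgent) == 18L, "urgent/non-urgent split")
  chk(sum(x$sex == "M") == 26L && sum(x$sex == "F") == 16L, "sex margin")
  chk(sum(x$cm_type == "HCM") == 30L && sum(x$cm_type == "DCM") == 12L,
      "CM-type margin")
  chk(sum(x$cm_class == "isolated") == 12L, "isolated margin")
  chk(sum(x$cm_class %in% c("syndromic", "metabolic")) == 30L, "complex margin")
  chk(sum(x$family_history) == 5L, "family-history margin")
  chk(sum(x$prenatal_detection) == 9L, "prenatal-detection margin")
  chk(all(is.na(x$t1_days) | is.na(x$t2_days) | x$t1_days <= x$t2_days),
      "t1 must not exceed t2")
  chk(all(!x$diagnosed | x$zygosity %in% c("hetero", "homo", "hemi",
                                           "compound_het")),
      "diagnosed cases need a zygosity")
  x
}

#' Load the transcribed trio genotype configurations of the diagnosed cases
#'
#' One row per reported variant (33 rows over 29 cases; compound
#' heterozygotes and the two-gene double heterozygote carry two rows).
#' Suitable for replaying through \code{\link{determine_inheritance}}.
#'
#' @return data.frame with the \code{TrioVariant} columns plus \code{case_id}.
#' @export
load_trio_genotypes <- function() {
  x <- read_fixture_tsv("trio_genotypes.tsv")
  x$case_id <- as.character(x$case_id)
  if (nrow(x) != 33L) stop("genotype fixture integrity failure: expected 33 rows")
  gt_levels <- c("hom_ref", "het", "hom_alt", "hemi", "missing")
  ok <- x$gt_proband %in% gt_levels & x$gt_mother %in% gt_levels &
    x$gt_father %in% gt_levels
  if (!all(ok)) stop("genotype fixture integrity failure: bad genotype code")
  x
}

#' Load the packaged cardiomyopathy gene panel
#'
#' @return data.frame with columns \code{symbol},
#'   \code{inheritance_modes} (comma-separated subset of AD/AR/XL),
#'   \code{mechanism} (lof/non_lof/either), \code{phenotype_tags}.
#' @export
load_panel <- function() {
  x <- read_fixture_tsv("panel_genes.tsv")
  if (any(!nzchar(x$inheritance_modes))) {
    stop("panel integrity failure: empty inheritance_modes")
  }
  x
}

#' Load the packaged gene-to-etiology class map
#'
#' @return data.frame with columns \code{gene}, \code{etiology_class}
#'   (metabolic_mito / sarcomeric / rasopathy / ultra_rare).
#' @export
load_gene_etiology <- function() {
  read_fixture_tsv("gene_etiology.tsv")
}
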
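#' Diagnostic yield of a case stratum
#'
#' Fractions are kept exact internally; the percentage is rounded to one
#' decimal only for display, matching the reporting convention of
#' clinical-yield tables.
#'
#' @param cases cohort data.frame (\code{\link{load_cohort_fixture}}).
#' @param stratum "all", "urgent" or "non_urgent".
#' @return list with n_total, n_diagnosed, yield_fraction (exact),
#'   yield_pct (rounded to one decimal), stratum.
#' @examples
#' diagnostic_yield(load_cohort_fixture(), "urgent")
#' @export
diagnostic_yield <- function(cases, stratum = c("all", "urgent", "non_urgent")) {
  stratum <- match.arg(stratum)
  sel <- switch(stratum, all = rep(TRUE, nrow(cases)),
                urgent = cases$urgent, non_urgent = !cases$urgent)
  if (!any(sel)) stop("empty stratum: ", stratum)
  n <- sum(sel)
  d <- sum(cases$diagnosed[sel])
  list(n_total = n, n_diagnosed = d, yield_fraction = d / n,
       yield_pct = round(100 * d / n, 1), stratum = stratum)
}

#' Inheritance-mode breakdown of the diagnosed cases
#'
#' Categories are derived from zygosity and parental origin: homozygous
#' and compound-heterozygous configurations are autosomal recessive;
#' hemizygous ones X-linked; heterozygous de novo is de novo;
#' heterozygous with a transmitting parent (one or, for a two-gene
#' double heterozygote, both) is inherited dominant.
#'
#' @param cases cohort data.frame; only diagnosed rows are used.
#' @return list with category_counts, denominator, fractions.
#' @export
inheritance_breakdown <- function(cases) {
  d <- cases[cases$diagnosed, , drop = FALSE]
  cat <- ifelse(d$zygosity %in% c("homo", "compound_het"), "autosomal_recessive",
         ifelse(d$zygosity == "hemi", "x_linked",
         ifelse(d$zygosity == "hetero" & d$parental_origin == "de_novo",
                "de_novo",
         ifelse(d$zygosity == "hetero" &
                  d$parental_origin %in% c("mother", "father", "both"),
                "inherited_dominant", NA_character_))))
  if (any(is.na(cat))) {
    stop("diagnosed case with unmappable zygosity/origin: ",
         paste(d$case_id[is.na(cat)], collapse = ", "))
  }
  levels <- c("de_novo", "autosomal_recessive", "x_linked",
              "inherited_dominant")
  counts <- vapply(levels, function(l) sum(cat == l), integer(1))
  list(category_counts = counts, denominator = nrow(d),
       fractions = counts / nrow(d))
}

#' Etiological-class breakdown of the diagnosed cases
#'
#' @param cases cohort data.frame.
#' @param gene_class_map data.frame gene -> etiology_class
#'   (\code{\link{load_gene_etiology}}). Multi-gene diagnoses
#'   (semicolon-separated) must map to a single class.
#' @return list with category_counts, denominator, fractions.
#' @export
etiology_breakdown <- function(cases, gene_class_map = load_gene_etiology()) {
  d <- cases[cases$diagnosed, , drop = FALSE]
  cls <- vapply(d$gene, function(g) {
    syms <- strsplit(g, ";", fixed = TRUE)[[1]]
    k <- gene_class_map$etiology_class[match(syms, gene_class_map$gene)]
    if (any(is.na(k))) stop("gene not in the etiology map: ", g)
    u <- unique(k)
    if (length(u) > 1) stop("multi-gene diagnosis maps to several classes: ", g)
    u
  }, character(1))
  levels <- c("metabolic_mito", "sarcomeric", "rasopathy", "ultra_rare")
  counts <- vapply(levels, function(l) sum(cls == l), integer(1))
  list(category_counts = counts, denominator = nrow(d),
       fractions = counts / nrow(d))
}

#' Turnaround-time summary per setting
#'
#' Arithmetic mean, median (mean of the central pair on even counts) and
#' min-max range of the requested turnaround field, per stratum; cases
#' without the field are excluded and counted. When no case carries the
#' field the result is an explicit absent marker, never zero.
#'
#' @param cases cohort data.frame.
#' @param field "t1_days" or "t2_days".
#' @param stratum "all", "urgent" or "non_urgent".
#' @return list with n, n_missing, mean, median, min, max; or a list
#'   with \code{absent = TRUE} when no case carries the field.
#' @export
turnaround_summary <- function(cases, field = c("t1_days", "t2_days"),
                               stratum = c("all", "urgent", "non_urgent")) {
  field <- match.arg(field)
  stratum <- match.arg(stratum)
  sel <- switch(stratum, all = rep(TRUE, nrow(cases)),
                urgent = cases$urgent, non_urgent = !cases$urgent)
  v <- cases[[field]][sel]
  ok <- !is.na(v)
  if (!any(ok)) {
    return(list(absent = TRUE, field = field, stratum = stratum,
                n_missing = sum(!ok)))
  }
  x <- v[ok]
  list(absent = FALSE, field = field, stratum = stratum,
       n = length(x), n_missing = sum(!ok),
       mean = mean(x), median = stats::median(x), min = min(x), max = max(x))
}

#' Case-level inheritance classification from resolved calls
#'
#' Aggregates the per-variant output of
#' \code{\link{determine_inheritance}} for one case into the label the
#' cohort breakdown uses: a compound-heterozygous call (or any
#' homozygous-recessive call) classifies the case as recessive; a
#' hemizygous call as X-linked; otherwise de novo or inherited dominant
#' by the remaining calls. Two dominant variants in two different genes
#' count as inherited dominant, not compound heterozygous.
#'
#' @param calls output of \code{\link{determine_inheritance}} for the
#'   case's reported variants.
#' @return one of "de_novo", "autosomal_recessive", "x_linked",
#'   "inherited_dominant", "unresolved".
#' @export
classify_case_inheritance <- function(calls) {
  m <- calls$model
  if (any(m %in% c("ar_homozygous", "compound_het"))) return("autosomal_recessive")
  if (any(m == "xl_hemizygous")) return("x_linked")
  if (any(m %in% c("inherited_maternal", "inherited_paternal"))) {
    return("inherited_dominant")
  }
  if (any(m == "de_novo")) return("de_novo")
  "unresolved"
}
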
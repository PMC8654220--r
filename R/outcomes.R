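# Burden accounting: disability weights, YLD, YLL, DALYs averted, QALYs,
# effectiveness ratios, and the burden ledger comparing scenarios with the
# base case.

#' Disability weight of OA
#'
#' Difference in mean utility between people without and with OA
#' (person-time weighted), computed separately per stratum; scenario- and
#' year-specific because treatment changes the utility of the OA group.
#' @param uw_non,uw_oa summed utility-weighted person-time among non-OA and
#'   OA members.
#' @param pt_free,pt_oa the corresponding person-time denominators (> 0).
#' @return disability weight (may be negative; a negative value is reported
#'   as-is).
#' @export
disability_weight <- function(uw_non, uw_oa, pt_free, pt_oa) {
  if (any(pt_free <= 0) || any(pt_oa <= 0))
    stop("disability weight undefined: empty OA or non-OA group",
         call. = FALSE)
  uw_non / pt_free - uw_oa / pt_oa
}

#' Years lived with disability
#'
#' `prevalence x disability weight x person-time`.
#' @param prevalence OA prevalence rate in the stratum.
#' @param dw disability weight.
#' @param person_time total person-years in the stratum.
#' @return YLD in years.
#' @export
yld <- function(prevalence, dw, person_time) {
  stopifnot(all(prevalence >= 0), all(person_time >= 0))
  prevalence * dw * person_time
}

#' Difference in years of life lost
#'
#' Signed person-time difference between a scenario and the base case for
#' the same year/sex stratum; positive when the scenario extends life (YLLs
#' averted). BMI-reduction scenarios are assumed to have no effect on
#' OA-related YLLs, so their difference is forced to zero.
#' @param pt_scenario,pt_base person-years in the scenario and base case.
#' @param is_bmi_scenario logical; force the difference to zero.
#' @return years (positive = life extended).
#' @export
yll_difference <- function(pt_scenario, pt_base, is_bmi_scenario = FALSE) {
  if (length(pt_scenario) != length(pt_base))
    stop("misaligned strata: person-time series differ in length",
         call. = FALSE)
  if (is_bmi_scenario) return(rep(0, length(pt_scenario)))
  pt_scenario - pt_base
}

#' DALYs averted
#'
#' Annual DALYs averted are the YLD difference plus the YLL difference
#' (positive = burden averted); the cumulative series is the exact running
#' sum.
#' @param d_yld,d_yll aligned annual difference series.
#' @return list with `annual` and `cumulative` numeric vectors.
#' @export
dalys_averted <- function(d_yld, d_yll) {
  stopifnot(length(d_yld) == length(d_yll))
  annual <- d_yld + d_yll
  list(annual = annual, cumulative = cumsum(annual))
}

#' Total OA-related DALYs
#'
#' Denominator for percentage-averted reporting: base-case YLD plus the
#' OA-related YLL obtained as the person-time difference between the
#' suppressed-treatment counterfactual and the base case (life lost to
#' treatment of OA).
#' @param yld_base annual base-case YLD series.
#' @param pt_base,pt_suppressed aligned annual person-time series.
#' @return list with `annual` and `cumulative` total DALYs.
#' @export
total_oa_dalys <- function(yld_base, pt_base, pt_suppressed) {
  if (is.null(pt_suppressed))
    stop("total OA DALYs require a suppressed-treatment run", call. = FALSE)
  stopifnot(length(yld_base) == length(pt_base),
            length(pt_base) == length(pt_suppressed))
  annual <- yld_base + (pt_suppressed - pt_base)
  list(annual = annual, cumulative = cumsum(annual))
}

#' Effectiveness ratio
#'
#' QALYs gained per additional surgery relative to base case; undefined
#' (NA) when no additional surgeries were performed.
#' @param d_qaly QALY difference vs base.
#' @param d_surgeries difference in the number of surgeries vs base.
#' @return ratio (NA where `d_surgeries == 0`).
#' @export
effectiveness_ratio <- function(d_qaly, d_surgeries) {
  ifelse(d_surgeries == 0, NA_real_, d_qaly / d_surgeries)
}

# collapse a person-year table over age groups to (year, sex) rows
.collapse_sex_year <- function(tab) {
  num <- setdiff(names(tab), c("scenario", "year", "sex", "agegrp"))
  ag <- aggregate(tab[num], by = list(year = tab$year, sex = tab$sex), sum)
  ag[order(ag$sex, ag$year), , drop = FALSE]
}

#' Burden ledger: scenario vs base-case differences
#'
#' For every scenario, year and sex (plus combined-sex rows) computes the
#' scenario-specific disability weight, YLD, differences in YLD and YLL vs
#' the base case, annual and cumulative DALYs averted, QALYs and QALY
#' differences, additional surgeries, the effectiveness ratio, and (when a
#' suppressed-treatment run is supplied) cumulative DALYs averted as a
#' percentage of cumulative total OA DALYs.
#'
#' @param results a named list of scenario results from [run_scenarios()]
#'   (or a named list of person-year tables).
#' @param base_name name of the base-case entry.
#' @return a `data.frame` ledger.
#' @export
burden_ledger <- function(results, base_name = "Base-case") {
  tabs <- lapply(results, function(r) if (is.data.frame(r)) r else r$table)
  if (!base_name %in% names(tabs))
    stop("base-case table '", base_name, "' missing", call. = FALSE)
  base <- .collapse_sex_year(tabs[[base_name]])
  supp <- if ("Suppressed-treatment" %in% names(tabs))
    .collapse_sex_year(tabs[["Suppressed-treatment"]]) else NULL

  base$dw <- disability_weight(base$uw_non, base$uw_oa, base$pt_free,
                               base$pt_oa)
  base$yld <- yld(base$pt_oa / base$pt, base$dw, base$pt)

  is_bmi <- function(nm) grepl("^BMI", nm)
  out <- list()
  for (nm in names(tabs)) {
    if (nm == "Suppressed-treatment") next
    s <- .collapse_sex_year(tabs[[nm]])
    stopifnot(identical(s$year, base$year), identical(s$sex, base$sex))
    s$dw <- disability_weight(s$uw_non, s$uw_oa, s$pt_free, s$pt_oa)
    s$yld <- yld(s$pt_oa / s$pt, s$dw, s$pt)
    for (sx in c("male", "female", "all")) {
      if (sx == "all") {
        bs <- aggregate(base[c("yld", "pt", "qaly", "primary_jrs",
                               "revision_jrs")],
                        by = list(year = base$year), sum)
        ss <- aggregate(s[c("yld", "pt", "qaly", "primary_jrs",
                            "revision_jrs")],
                        by = list(year = s$year), sum)
        sp <- if (!is.null(supp))
          aggregate(supp["pt"], by = list(year = supp$year), sum) else NULL
      } else {
        bs <- base[base$sex == sx, ]
        ss <- s[s$sex == sx, ]
        sp <- if (!is.null(supp)) supp[supp$sex == sx, ] else NULL
      }
      d_yld <- bs$yld - ss$yld
      d_yll <- yll_difference(ss$pt, bs$pt, is_bmi(nm))
      da <- dalys_averted(d_yld, d_yll)
      d_qaly <- ss$qaly - bs$qaly
      add_surg <- (ss$primary_jrs + ss$revision_jrs) -
        (bs$primary_jrs + bs$revision_jrs)
      row <- data.frame(
        scenario = nm, year = bs$year, sex = sx, yld = ss$yld,
        d_yld = d_yld, d_yll = d_yll, dalys_averted = da$annual,
        cum_dalys_averted = da$cumulative, qalys = ss$qaly,
        d_qaly = d_qaly, add_surgeries = add_surg,
        eff_ratio = effectiveness_ratio(cumsum(d_qaly), cumsum(add_surg)),
        stringsAsFactors = FALSE)
      if (!is.null(sp)) {
        tot <- total_oa_dalys(bs$yld, bs$pt, sp$pt)
        row$pct_total_dalys <- 100 * da$cumulative / tot$cumulative
      } else row$pct_total_dalys <- NA_real_
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a burden ledger to CSV
#' @param ledger data frame from [burden_ledger()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}
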
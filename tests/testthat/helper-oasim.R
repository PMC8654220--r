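# Shared fixtures, all generated in code.

default_params <- build_default_parameters(1)

# demographically frozen variant: nobody dies, enters, or leaves
frozen_demography <- function(p = default_params) {
  p$demography$mortality$a_male <- 0
  p$demography$mortality$a_female <- 0
  p$demography$entry_rate <- 0
  p$demography$immigration_rate <- 0
  p$demography$emigration_rate <- 0
  p
}

# variant with no analgesic use and (effectively) no surgery
untreated_params <- function(p = default_params) {
  for (d in names(p$medications)) p$medications[[d]]$prevalence[] <- 0
  p$jrs$intercept <- log(1e-12)
  p$jrs$revision_rate <- 0
  p
}

# population-mean utility among OA / non-OA per year, summed over strata
collapse_years <- function(tab) {
  num <- setdiff(names(tab), c("scenario", "year", "sex", "agegrp"))
  out <- aggregate(tab[num], by = list(year = tab$year), sum)
  out[order(out$year), ]
}

# random person-year tables for the accounting oracle: plausible magnitudes,
# not balanced in any way
random_pytable <- function(n_years, scenario = "X") {
  years <- 2020 + seq_len(n_years) - 1
  do.call(rbind, lapply(c("male", "female"), function(sx) {
    pt <- runif(n_years, 5000, 20000)
    pt_oa <- pt * runif(n_years, 0.05, 0.3)
    pt_free <- pt - pt_oa
    u_oa <- runif(n_years, 0.5, 0.9)
    u_non <- runif(n_years, 0.7, 1.0)
    data.frame(scenario = scenario, year = years, sex = sx, agegrp = "20-69",
               pt = pt, pt_oa = pt_oa, pt_free = pt_free,
               uw_oa = u_oa * pt_oa, uw_non = u_non * pt_free,
               qaly = u_oa * pt_oa + u_non * pt_free,
               primary_jrs = rpois(n_years, 50),
               revision_jrs = rpois(n_years, 5),
               stringsAsFactors = FALSE)
  }))
}
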
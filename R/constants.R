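#' Microdose cocktail dose regimen
#'
#' The five probe substrates and their microgram doses: 10 ug midazolam
#' (MDZ, CYP3A), 375 ug dabigatran etexilate dosed as the prodrug but
#' modelled as dabigatran (DAB, intestinal P-gp), 10 ug pitavastatin
#' (PTV, OATP1B), 50 ug rosuvastatin (RSV, OATP1B/BCRP) and 100 ug
#' atorvastatin (ATV, mixed CYP3A/OATP1B/P-gp/BCRP). The DABE-to-DAB mass
#' conversion is absorbed into apparent bioavailability, so the
#' administered DABE mass is used as the DAB dose amount.
#'
#' @return Tibble with columns `drug`, `amount_ug`, `dmet`.
#' @export
cocktail_doses <- function() {
  tibble::tibble(
    drug = c("MDZ", "DAB", "PTV", "RSV", "ATV"),
    amount_ug = c(10, 375, 10, 50, 100),
    dmet = c("CYP3A", "Pgp_intestinal", "OATP1B", "OATP1B/BCRP", "mixed")
  )
}

#' Group summary statistics used by the cohort generator
#'
#' Mean and coefficient of variation (CV%) of each numeric covariate, per
#' group (healthy volunteers, HV, n = 14 reference; end-stage renal disease,
#' ESRD, n = 10 reference). Rows flagged `fixture = TRUE` are plausible
#' defaults for covariates required by the regression model cards but not
#' published as group summaries; they are synthetic fixture values, not
#' study data.
#'
#' @return Tibble with columns `covariate`, `unit`, `mean_hv`, `cv_hv`,
#'   `mean_esrd`, `cv_esrd`, `fixture` (CVs in percent).
#' @export
covariate_stats <- function() {
  tibble::tribble(
    ~covariate,       ~unit,          ~mean_hv, ~cv_hv, ~mean_esrd, ~cv_esrd, ~fixture,
    "age",            "year",            35.6,   36,      43.4,      12,      FALSE,
    "bmi",            "kg/m2",           22.4,   11,      21.9,      13,      FALSE,
    "scr",            "umol/L",          70.1,   14,      1150.3,    23,      FALSE,
    "total_protein",  "g/L",             71.9,    4,      72.2,       4,      FALSE,
    "albumin",        "g/L",             44.9,    8,      42.1,       4,      FALSE,
    "globulin",       "g/L",             27.2,   12,      30.1,       9,      FALSE,
    "alt",            "U/L",             13.1,   40,      16.8,     142,      FALSE,
    "ast",            "U/L",             18.2,   27,      14.5,      74,      FALSE,
    "tbil",           "umol/L",          14.9,   51,      6.4,       20,      FALSE,
    "alp",            "U/L",             67.1,   28,      82.8,      38,      FALSE,
    "hct",            "fraction",        0.44,   20,      0.35,       9,      FALSE,
    "hgb",            "g/L",            137.1,   12,      112.9,      8,      FALSE,
    "urea",           "mmol/L",           5.0,   20,      22.0,      25,      TRUE,
    "triglyceride",   "mmol/L",           1.3,   40,      1.8,       45,      TRUE,
    "platelet",       "1e9/L",          250,     15,      210,       20,      TRUE,
    "ckmb",           "U/L",              2.0,   40,      3.0,       50,      TRUE,
    "height",         "cm",             167,      6,      168,        6,      TRUE
  )
}

#' Default gut-microbiome genus abundance ranges
#'
#' Per-genus relative-abundance ranges (percent) sampled log-uniformly by
#' the generator. Veillonella (0.015-1.42%) and Phascolarctobacterium
#' (0.005-37%) use the reported study ranges; the remaining genera carry
#' plausible fixture ranges chosen once for the synthetic cohorts.
#'
#' @return Tibble with columns `genus`, `lo`, `hi` (percent), `fixture`.
#' @export
genus_ranges <- function() {
  tibble::tribble(
    ~genus,                   ~lo,    ~hi,  ~fixture,
    "Veillonella",            0.015,  1.42, FALSE,
    "Phascolarctobacterium",  0.005, 37,    FALSE,
    "Clostridium_XIVb",       0.005,  1.5,  TRUE,
    "Clostridium_XVIII",      0.005,  2,    TRUE,
    "Anaerostipes",           0.005,  2,    TRUE,
    "Sutterella",             0.005,  3,    TRUE,
    "Bilophila",              0.005,  1,    TRUE,
    "Clostridium_IV",         0.005,  2,    TRUE
  )
}

#' Default per-drug unbound fractions
#'
#' Fraction unbound in plasma (f_u) by drug and group. These are synthetic
#' fixture values consistent with the drugs' known high protein binding and
#' with the reported 62% f_u increase for midazolam in ESRD; individual
#' measured values are not published.
#'
#' @return Tibble with columns `drug`, `fu_hv`, `fu_esrd`.
#' @export
fu_defaults <- function() {
  tibble::tibble(
    drug = c("MDZ", "DAB", "PTV", "RSV", "ATV"),
    fu_hv = c(0.030, 0.650, 0.004, 0.100, 0.020),
    fu_esrd = c(0.030 * 1.62, 0.650, 0.006, 0.130, 0.030)
  )
}

#' Default transporter/enzyme SNP allele frequencies
#'
#' Variant-allele frequencies used to draw diplotypes under
#' Hardy-Weinberg equilibrium. East-Asian-plausible fixture values; the
#' study does not publish its genotype frequencies.
#'
#' @return Tibble with columns `snp`, `gene`, `ref`, `alt`, `alt_freq`.
#' @export
snp_defaults <- function() {
  tibble::tribble(
    ~snp,        ~gene,      ~ref, ~alt, ~alt_freq,
    "rs776746",  "CYP3A5",   "A",  "G",  0.71,  # *3 (G) non-functional
    "rs2306283", "SLCO1B1",  "A",  "G",  0.74,  # 388A>G (*1b)
    "rs4149056", "SLCO1B1",  "T",  "C",  0.12,  # 521T>C (*5, decreased)
    "rs2231142", "ABCG2",    "C",  "A",  0.29   # 421C>A (Q141K, decreased)
  )
}

#' Reference group eGFR means
#'
#' Mean estimated glomerular filtration rate of the two study arms
#' (mL/min/1.73 m2), used by the P-gp activity mass-balance calculation.
#'
#' @return Named numeric vector with elements `HV` and `ESRD`.
#' @export
egfr_group_means <- function() c(HV = 106.6, ESRD = 4)
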
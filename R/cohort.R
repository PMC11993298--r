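#' CKD-EPI estimated glomerular filtration rate
#'
#' 2009 CKD-EPI creatinine equation, evaluated without the race coefficient
#' (single-ethnicity cohorts): with `s = scr_mg/dL / kappa`,
#' `eGFR = 141 * min(s, 1)^a * max(s, 1)^-1.209 * 0.993^age * 1.018[female]`,
#' where `kappa` = 0.7 (female) / 0.9 (male) and `a` = -0.329 / -0.411.
#' Serum creatinine is taken in umol/L and converted by /88.4.
#'
#' @param scr Serum creatinine, umol/L (vectorized).
#' @param age Age in years.
#' @param sex `"F"`/`"M"` (or `"female"`/`"male"`).
#' @return eGFR in mL/min/1.73 m2.
#' @examples
#' ckd_epi_egfr(1150.3, 43.4, "M")
#' @export
ckd_epi_egfr <- function(scr, age, sex) {
  if (any(scr <= 0)) stop("serum creatinine must be > 0", call. = FALSE)
  if (any(age <= 0)) stop("age must be > 0", call. = FALSE)
  female <- toupper(substr(sex, 1, 1)) == "F"
  if (anyNA(female)) stop("sex must be 'F' or 'M'", call. = FALSE)
  scr_mgdl <- scr / 88.4
  kappa <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  s <- scr_mgdl / kappa
  141 * pmin(s, 1)^a * pmax(s, 1)^(-1.209) * 0.993^age * ifelse(female, 1.018, 1)
}

parse_diplotype <- function(x, alleles, snp) {
  parts <- strsplit(x, "/", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (!all(ok)) {
    stop("malformed diplotype for ", snp, ": '", x[!ok][1], "' (expected 'X/Y')",
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  known <- m[, 1] %in% alleles & m[, 2] %in% alleles
  # count of variant (second) allele; NA when an allele is unrecognized
  counts <- (m[, 1] == alleles[2]) + (m[, 2] == alleles[2])
  counts[!known] <- NA_integer_
  counts
}

#' Assign DMET phenotypes from transporter/enzyme diplotypes
#'
#' CPIC-style lookup from the four genotyped loci to phenotype labels:
#' * CYP3A5 (rs776746, A functional): A/A normal, A/G intermediate,
#'   G/G poor metabolizer;
#' * OATP1B1 (rs4149056 521T>C decreased-function, rs2306283 388A>G):
#'   two C alleles poor, one C decreased, none: increased function when
#'   388 G/G (homozygous *1b), otherwise normal;
#' * BCRP (rs2231142 421C>A): C/C normal, C/A decreased, A/A poor function.
#'
#' Any diplotype with an unrecognized allele maps to `"indeterminate"`; a
#' string not of the form `"X/Y"` is a parse error. The mapping is total
#' over the recognized diplotype space.
#'
#' @param genotypes Data frame with character columns `rs776746`,
#'   `rs2306283`, `rs4149056`, `rs2231142` holding diplotypes like `"A/G"`.
#' @return Tibble with columns `cyp3a5`, `oatp1b1`, `bcrp`.
#' @examples
#' assign_phenotype(tibble::tibble(rs776746 = "G/G", rs2306283 = "A/A",
#'                                 rs4149056 = "T/T", rs2231142 = "C/C"))
#' @export
assign_phenotype <- function(genotypes) {
  need <- c("rs776746", "rs2306283", "rs4149056", "rs2231142")
  miss <- setdiff(need, names(genotypes))
  if (length(miss)) stop("missing diplotype column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  n3a5 <- parse_diplotype(genotypes$rs776746, c("A", "G"), "rs776746")
  n388 <- parse_diplotype(genotypes$rs2306283, c("A", "G"), "rs2306283")
  n521 <- parse_diplotype(genotypes$rs4149056, c("T", "C"), "rs4149056")
  n421 <- parse_diplotype(genotypes$rs2231142, c("C", "A"), "rs2231142")
  lab <- function(idx, labels) {
    out <- labels[idx + 1L]
    out[is.na(out)] <- "indeterminate"
    out
  }
  cyp3a5 <- lab(n3a5, c("normal", "intermediate", "poor"))
  oatp1b1 <- dplyr::case_when(
    is.na(n521) | is.na(n388) ~ "indeterminate",
    n521 == 2 ~ "poor",
    n521 == 1 ~ "decreased",
    n388 == 2 ~ "increased",
    TRUE ~ "normal"
  )
  bcrp <- lab(n421, c("normal", "decreased", "poor"))
  tibble::tibble(cyp3a5 = cyp3a5, oatp1b1 = oatp1b1, bcrp = bcrp)
}

lognormal_pars <- function(mean, cv_pct) {
  cv <- cv_pct / 100
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}

draw_group_covariates <- function(n, group, stats) {
  male_frac <- if (group == "HV") 5 / 14 else 7 / 10
  n_male <- round(n * male_frac)
  sex <- c(rep("M", n_male), rep("F", n - n_male))
  out <- tibble::tibble(group = group, sex = sex)
  mcol <- if (group == "HV") "mean_hv" else "mean_esrd"
  ccol <- if (group == "HV") "cv_hv" else "cv_esrd"
  for (i in seq_len(nrow(stats))) {
    m <- stats[[mcol]][i]; cv <- stats[[ccol]][i]
    if (cv < 0) stop("CV% must be >= 0 for covariate '", stats$covariate[i], "'",
                     call. = FALSE)
    lp <- lognormal_pars(m, cv)
    out[[stats$covariate[i]]] <- if (cv == 0) rep(m, n) else
      stats::rlnorm(n, lp$meanlog, lp$sdlog)
  }
  out
}

#' Generate a synthetic cohort covariate table
#'
#' Draws per-subject demographics and laboratory covariates for a healthy
#' volunteer (HV) arm and an end-stage renal disease (ESRD) arm. Each
#' numeric covariate is log-normal with the group's published mean and CV%
#' ([covariate_stats()]); sex ratios follow the study arms (5M/9F and 7M/3F,
#' scaled). eGFR is computed from creatinine, age and sex with
#' [ckd_epi_egfr()]; creatinine is redrawn (up to 200 tries) until the
#' group's eGFR eligibility bound holds (HV >= 90, ESRD <= 15). Per-drug
#' unbound fractions are attached from `fu` by group.
#'
#' @param n_hv,n_esrd Arm sizes (default: the study's 14 and 10).
#' @param seed Integer seed.
#' @param stats Covariate summary table, see [covariate_stats()].
#' @param fu Per-drug unbound fractions, see [fu_defaults()].
#' @return Tibble, one row per subject: `id`, `group`, `dis` (0/1), `sex`,
#'   covariates, `egfr`, and `fu_<drug>` columns.
#' @export
simulate_covariates <- function(n_hv = 14, n_esrd = 10, seed = NULL,
                                stats = covariate_stats(), fu = fu_defaults()) {
  stopifnot(n_hv >= 1, n_esrd >= 1)
  if (!is.null(seed)) set.seed(seed)
  cohort <- dplyr::bind_rows(
    draw_group_covariates(n_hv, "HV", stats),
    draw_group_covariates(n_esrd, "ESRD", stats)
  )
  cohort$id <- seq_len(nrow(cohort))
  cohort$dis <- as.integer(cohort$group == "ESRD")
  # age eligibility window (18-65 years): redraw out-of-window ages
  age_stats <- stats[stats$covariate == "age", ]
  for (i in seq_len(nrow(cohort))) {
    mcol <- if (cohort$group[i] == "HV") "mean_hv" else "mean_esrd"
    ccol <- if (cohort$group[i] == "HV") "cv_hv" else "cv_esrd"
    lp <- lognormal_pars(age_stats[[mcol]], age_stats[[ccol]])
    while (cohort$age[i] < 18 || cohort$age[i] > 65) {
      cohort$age[i] <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
    }
  }
  # enforce the eligibility bound on eGFR by redrawing creatinine; after the
  # retry cap the draw is pushed deterministically across the boundary
  scr_stats <- stats[stats$covariate == "scr", ]
  for (i in seq_len(nrow(cohort))) {
    hv <- cohort$group[i] == "HV"
    lo_hi <- if (hv) c(90, Inf) else c(0, 15)
    mcol <- if (hv) "mean_hv" else "mean_esrd"
    ccol <- if (hv) "cv_hv" else "cv_esrd"
    lp <- lognormal_pars(scr_stats[[mcol]], scr_stats[[ccol]])
    scr <- cohort$scr[i]
    ok <- function(s) {
      eg <- ckd_epi_egfr(s, cohort$age[i], cohort$sex[i])
      eg >= lo_hi[1] && eg <= lo_hi[2]
    }
    for (try in 1:200) {
      if (ok(scr)) break
      scr <- stats::rlnorm(1, lp$meanlog, lp$sdlog)
    }
    while (!ok(scr)) scr <- scr * if (hv) 0.95 else 1.05
    cohort$scr[i] <- scr
  }
  cohort$egfr <- ckd_epi_egfr(cohort$scr, cohort$age, cohort$sex)
  for (j in seq_len(nrow(fu))) {
    cohort[[paste0("fu_", fu$drug[j])]] <-
      ifelse(cohort$group == "ESRD", fu$fu_esrd[j], fu$fu_hv[j])
  }
  dplyr::relocate(cohort, "id", "group", "dis", "sex")
}

#' Attach gut-microbiome genus relative abundances
#'
#' Draws per-genus relative abundances (percent) log-uniformly within each
#' genus's configured range and appends one column per genus to the subject
#' table. A degenerate range `[x, x]` yields the constant `x`.
#'
#' @param subjects Subject table (one row per subject).
#' @param seed Integer seed.
#' @param ranges Tibble with columns `genus`, `lo`, `hi`; see
#'   [genus_ranges()].
#' @return `subjects` with abundance columns added.
#' @export
simulate_microbiome <- function(subjects, seed = NULL, ranges = genus_ranges()) {
  if (any(ranges$lo < 0) || any(ranges$hi < ranges$lo)) {
    stop("invalid genus range: need 0 <= lo <= hi", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  for (i in seq_len(nrow(ranges))) {
    lo <- ranges$lo[i]; hi <- ranges$hi[i]
    subjects[[ranges$genus[i]]] <- if (hi == lo) rep(lo, n) else
      exp(stats::runif(n, log(lo), log(hi)))
  }
  subjects
}

#' Attach transporter/enzyme genotypes and phenotypes
#'
#' Draws diplotypes for the four genotyped loci under Hardy-Weinberg
#' equilibrium at the configured variant-allele frequencies
#' ([snp_defaults()], fixture values) and appends phenotype labels via
#' [assign_phenotype()].
#'
#' @inheritParams simulate_microbiome
#' @param snps Tibble of SNP definitions, see [snp_defaults()].
#' @return `subjects` with diplotype and phenotype columns added.
#' @export
simulate_genotypes <- function(subjects, seed = NULL, snps = snp_defaults()) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  for (i in seq_len(nrow(snps))) {
    alleles <- c(snps$ref[i], snps$alt[i])
    a1 <- alleles[1 + stats::rbinom(n, 1, snps$alt_freq[i])]
    a2 <- alleles[1 + stats::rbinom(n, 1, snps$alt_freq[i])]
    subjects[[snps$snp[i]]] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  }
  dplyr::bind_cols(subjects, assign_phenotype(subjects))
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_covariates()],
#' [simulate_microbiome()] and [simulate_genotypes()] with sub-seeds
#' derived from `seed`.
#'
#' @inheritParams simulate_covariates
#' @return Subject tibble with demographics, labs, eGFR, unbound fractions,
#'   genus abundances, diplotypes and phenotypes.
#' @examples
#' simulate_cohort(n_hv = 2, n_esrd = 2, seed = 1)
#' @export
simulate_cohort <- function(n_hv = 14, n_esrd = 10, seed = 1,
                            stats = covariate_stats(), fu = fu_defaults()) {
  simulate_covariates(n_hv, n_esrd, seed = seed, stats = stats, fu = fu) |>
    simulate_microbiome(seed = seed + 1L) |>
    simulate_genotypes(seed = seed + 2L)
}
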
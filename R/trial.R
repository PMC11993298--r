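#' Blood sampling schedules of the two study arms
#'
#' Healthy volunteers: pre-dose plus 0.5, 1, 2, 4, 8, 12 and 24 h post-dose.
#' ESRD patients: pre-dose plus 1, 4, 24 h (before dialysis) and 28 h
#' (post-dialysis).
#'
#' @return Named list of numeric time vectors (hours) for `HV` and `ESRD`.
#' @export
default_schedules <- function() {
  list(HV = c(0, 0.5, 1, 2, 4, 8, 12, 24),
       ESRD = c(0, 1, 4, 24, 28))
}

#' Simulate a cocktail trial from population models
#'
#' For each drug and subject, individual parameters are drawn from the
#' population model (log-normal IIV), the closed-form two-compartment curve
#' is evaluated at the subject's arm schedule, and combined
#' proportional/additive residual error is applied. Observations below the
#' lower limit of quantification are kept but flagged `blq` (M1-style
#' handling downstream). Each subject-drug has exactly one dose event at
#' time 0.
#'
#' @param subjects Subject table from [simulate_cohort()] (needs `id`,
#'   `group` and every covariate named by the models).
#' @param models Named list of [population_model()]s (default
#'   [default_models()]).
#' @param schedules Named list of sampling times per group, see
#'   [default_schedules()].
#' @param seed Integer seed.
#' @param lloq Lower limit of quantification, pg/mL (default 5).
#' @param doses Dose table, see [cocktail_doses()].
#' @return Long-format tibble of dose and observation records: `id`,
#'   `group`, `drug`, `time`, `amt` (ug, dose rows), `evid` (1 dose /
#'   0 observation), `dv` (pg/mL, NA on dose rows), `blq`.
#' @export
simulate_trial <- function(subjects, models = default_models(),
                           schedules = default_schedules(), seed = 1,
                           lloq = 5, doses = cocktail_doses()) {
  stopifnot(all(c("id", "group") %in% names(subjects)))
  set.seed(seed)
  out <- vector("list", length(models))
  for (k in seq_along(models)) {
    model <- models[[k]]
    amt <- doses$amount_ug[match(model$drug, doses$drug)]
    if (is.na(amt)) stop("no dose defined for drug ", model$drug, call. = FALSE)
    ind <- draw_individual_params(model, subjects)
    recs <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      tt <- schedules[[subjects$group[i]]]
      p <- row_to_params(ind[i, ])
      f <- conc_2cmt_oral(p, amt, 0, tt)
      eps_p <- stats::rnorm(length(tt), 0, model$sigma$prop)
      eps_a <- stats::rnorm(length(tt), 0, model$sigma$add)
      y <- pmax(f * (1 + eps_p) + eps_a, 0)
      recs[[i]] <- tibble::tibble(
        id = subjects$id[i], group = subjects$group[i], drug = model$drug,
        time = c(0, tt), amt = c(amt, rep(NA_real_, length(tt))),
        evid = c(1L, rep(0L, length(tt))),
        dv = c(NA_real_, y), blq = c(FALSE, y < lloq)
      )
    }
    out[[k]] <- dplyr::bind_rows(recs)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$drug, .data$id, .data$evid != 1, .data$time)
}

required_dataset_cols <- c("ID", "GROUP", "DRUG", "TIME", "AMT", "EVID", "DV", "BLQ")

#' Write / read the long-format analysis dataset
#'
#' NONMEM-compatible CSV dialect: comma-separated, UTF-8, columns `ID`,
#' `GROUP`, `DRUG`, `TIME`, `AMT`, `EVID` (1 = dose, 0 = observation),
#' `DV` (missing written as `.`), `BLQ`, followed by any covariate columns
#' joined from the subject table. Lines starting with `#` are header
#' comments (seed / configuration echo) and are skipped on read.
#'
#' @param records Concentration-record tibble from [simulate_trial()].
#' @param path File path.
#' @param subjects Optional subject table joined on `id` before writing.
#' @param header Optional character vector of comment lines (written
#'   prefixed with `#`).
#' @return `write_pk_dataset`: the path, invisibly. `read_pk_dataset`: a
#'   list with `records` (tibble: `id, group, drug, time, amt, evid, dv,
#'   blq`) and `subjects` (one row per subject of the remaining columns).
#' @export
write_pk_dataset <- function(records, path, subjects = NULL, header = NULL) {
  df <- records
  if (!is.null(subjects)) {
    df <- dplyr::left_join(df, dplyr::select(subjects, -dplyr::any_of("group")),
                           by = "id")
  }
  names(df)[match(c("id", "group", "drug", "time", "amt", "evid", "dv", "blq"),
                  names(df))] <- required_dataset_cols
  df$DV <- ifelse(is.na(df$DV), ".", format(df$DV, digits = 12, trim = TRUE,
                                            scientific = FALSE))
  df$AMT <- ifelse(is.na(df$AMT), ".", as.character(df$AMT))
  df$BLQ <- as.integer(df$BLQ)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  miss <- setdiff(required_dataset_cols, names(df))
  if (length(miss)) {
    stop("dataset ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num_or_dot <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  recs <- tibble::tibble(
    id = df$ID, group = as.character(df$GROUP), drug = as.character(df$DRUG),
    time = as.numeric(df$TIME), amt = num_or_dot(as.character(df$AMT)),
    evid = as.integer(df$EVID), dv = num_or_dot(as.character(df$DV)),
    blq = as.logical(as.integer(df$BLQ))
  )
  if (any(!is.na(recs$dv) & recs$dv < 0)) {
    stop("negative DV value(s) at row(s): ",
         paste(utils::head(which(!is.na(recs$dv) & recs$dv < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(recs$id, recs$drug)
  for (k in unique(key)) {
    sub <- recs[key == k & recs$evid == 0L, ]
    if (is.unsorted(sub$time, strictly = TRUE)) {
      stop("non-monotone observation times for subject-drug ", k, call. = FALSE)
    }
    if (sum(key == k & recs$evid == 1L) > 1L) {
      stop("duplicate dose rows for subject-drug ", k, call. = FALSE)
    }
  }
  covcols <- setdiff(names(df), required_dataset_cols)
  subjects <- dplyr::distinct(
    dplyr::select(tibble::as_tibble(df), "ID", "GROUP", dplyr::all_of(covcols)))
  names(subjects)[1:2] <- c("id", "group")
  list(records = recs, subjects = subjects)
}
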
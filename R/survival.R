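# Conversion-to-depression modelling: counting-process event tables,
# time-dependent Cox regression and Kaplan-Meier strata.

#' Build a counting-process event table from longitudinal phenotypes
#'
#' Samples need at least `min_records` visits; GDS-defined depression
#' (GDS >= `gds_cut`) must be present at `min_event_visits` or more visits
#' to count as an event. The event time is the first qualifying visit
#' (given later confirmation; `event_at = "second"` uses the second
#' qualifying visit instead); otherwise the sample is censored at its last
#' visit. Samples whose first qualifying visit is the baseline visit are
#' prevalent cases and are excluded from the time-to-event table. Each
#' visit interval `(start, stop]` carries the visit-level age and UPDRS3
#' covariates. A cross-sectional binary outcome (any single visit with
#' GDS >= `gds_cut`, over all samples with enough records) is also
#' returned for the PRS association model.
#'
#' @param pheno data.frame sample, visit_month, GDS, UPDRS3, age, sex.
#' @param gds_cut depression threshold on the GDS scale.
#' @param min_records minimum longitudinal records per sample.
#' @param min_event_visits qualifying visits required to confirm an event.
#' @param event_at `"first"` or `"second"` qualifying visit as event time.
#' @return list of class `event_table`: `events` (sample, start, stop,
#'   event, age, UPDRS3, sex), `binary` (named 0/1 vector), `excluded`
#'   (sample, reason).
#' @export
build_event_table <- function(pheno, gds_cut = 5, min_records = 3,
                              min_event_visits = 2,
                              event_at = c("first", "second")) {
  event_at <- match.arg(event_at)
  rows <- list(); binary <- c(); excluded <- list()
  for (s in unique(pheno$sample)) {
    d <- pheno[pheno$sample == s, , drop = FALSE]
    stop_if_not(!is.unsorted(d$visit_month, strictly = TRUE),
                "non-monotone visit times for sample %s", s)
    if (nrow(d) < min_records) {
      excluded[[length(excluded) + 1]] <-
        data.frame(sample = s, reason = "too_few_records")
      next
    }
    binary[s] <- as.integer(any(d$GDS >= gds_cut))
    qual <- which(d$GDS >= gds_cut)
    has_event <- length(qual) >= min_event_visits
    ev_idx <- if (has_event) {
      if (event_at == "first") qual[1] else qual[2]
    } else nrow(d)
    if (has_event && ev_idx == 1) {
      excluded[[length(excluded) + 1]] <-
        data.frame(sample = s, reason = "prevalent_at_baseline")
      next
    }
    # intervals (m_j, m_{j+1}] up to the event/censor visit, covariates
    # carried from the interval's opening visit
    for (j in seq_len(ev_idx - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, start = d$visit_month[j], stop = d$visit_month[j + 1],
        event = as.integer(has_event && (j + 1) == ev_idx),
        age = d$age[j], UPDRS3 = d$UPDRS3[j], sex = d$sex[1],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(events = do.call(rbind, rows), binary = binary,
                 excluded = if (length(excluded))
                   do.call(rbind, excluded)
                 else data.frame(sample = character(0),
                                 reason = character(0))),
            class = "event_table")
}

#' Time-dependent Cox model of conversion to depression
#'
#' Counting-process Cox partial likelihood (Efron tie handling, via the
#' survival package) with the polygenic score(s) as predictors, sex as a
#' fixed covariate and age and UPDRS3 as time-dependent covariates.
#' Predictors are standardized to unit variance before fitting, so hazard
#' ratios are per SD of PRS.
#'
#' @param events an [build_event_table()] object (or its `events`
#'   data.frame).
#' @param prs named numeric vector, or a named list of named vectors for
#'   several score sets fit jointly.
#' @return data.frame predictor, coef, HR, SE, p; the fitted model is
#'   attached as attribute `"fit"`.
#' @export
cox_time_dependent <- function(events, prs) {
  ev <- if (inherits(events, "event_table")) events$events else events
  stop_if_not(sum(ev$event) >= 2, "need at least 2 events")
  if (!is.list(prs)) prs <- list(PRS = prs)
  dat <- ev
  for (nm in names(prs)) {
    v <- prs[[nm]][dat$sample]
    s <- stats::sd(prs[[nm]], na.rm = TRUE)
    dat[[nm]] <- if (!is.na(s) && s > 0)
      (v - mean(prs[[nm]], na.rm = TRUE)) / s else v - v  # constant -> 0
  }
  dat$sex <- factor(dat$sex)
  covs <- c("age", "UPDRS3")
  if (nlevels(droplevels(dat$sex)) >= 2) covs <- c("sex", covs)
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~",
    paste(c(names(prs), covs), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  sm <- summary(fit)$coefficients
  out <- data.frame(predictor = rownames(sm), coef = sm[, "coef"],
                    HR = exp(sm[, "coef"]), SE = sm[, "se(coef)"],
                    p = sm[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  # a constant (zero-information) predictor is reported at its null value
  con <- is.na(out$coef) & out$predictor %in% names(prs)
  out$coef[con] <- 0; out$HR[con] <- 1
  attr(out, "fit") <- fit
  out
}

#' Kaplan-Meier curves and hazard ratios across PRS percentile strata
#'
#' Subsets samples into percentile strata of polygenic risk, computes the
#' Kaplan-Meier estimator per stratum (time to the first qualifying
#' visit), and estimates per-stratum hazard ratios against a reference
#' stratum from a Cox model with stratum indicators, adjusting for sex,
#' age and UPDRS3 as in [cox_time_dependent()].
#'
#' @param events an [build_event_table()] object.
#' @param prs named numeric score vector.
#' @param strata increasing percentile bounds covering `[0, 100]`.
#' @param reference index of the reference stratum.
#' @return list with `km` (stratum, time, surv, n_risk, n_event), `hr`
#'   (stratum, HR, SE, p) and `strata_labels`.
#' @export
km_percentile_strata <- function(events, prs,
                                 strata = c(0, 5, 50, 95, 100),
                                 reference = 2) {
  stop_if_not(strata[1] == 0 && strata[length(strata)] == 100 &&
                !is.unsorted(strata, strictly = TRUE),
              "strata must be increasing percentile bounds covering [0,100]")
  ev <- if (inherits(events, "event_table")) events$events else events
  samples <- unique(ev$sample)
  q <- stats::quantile(prs[samples], probs = strata / 100, na.rm = TRUE)
  lab <- paste0(utils::head(strata, -1), "-", utils::tail(strata, -1), "%")
  st <- cut(prs[samples], breaks = q, include.lowest = TRUE, labels = lab)
  names(st) <- samples
  empty <- setdiff(lab, unique(as.character(st)))
  if (length(empty))
    warning("empty stratum(s) dropped: ", paste(empty, collapse = ", "))
  dat <- ev
  dat$stratum <- factor(as.character(st[dat$sample]),
                        levels = intersect(lab, unique(as.character(st))))
  dat$stratum <- stats::relevel(dat$stratum, ref = lab[reference])
  sf <- survival::survfit(
    survival::Surv(start, stop, event) ~ stratum, data = dat)
  strat <- if (is.null(sf$strata)) rep(levels(dat$stratum)[1],
                                       length(sf$time))
           else rep(sub("^stratum=", "", names(sf$strata)), sf$strata)
  km <- data.frame(
    stratum = strat, time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
    n_event = sf$n.event, stringsAsFactors = FALSE)
  dat$sex <- factor(dat$sex)
  hr <- data.frame(stratum = character(0), HR = numeric(0),
                   SE = numeric(0), p = numeric(0))
  if (nlevels(droplevels(dat$stratum)) >= 2 && sum(dat$event) >= 2) {
    covs <- c("age", "UPDRS3")
    if (nlevels(droplevels(dat$sex)) >= 2) covs <- c("sex", covs)
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(start, stop, event) ~ stratum +",
                              paste(covs, collapse = " + "))),
      data = dat, ties = "efron")
    sm <- summary(fit)$coefficients
    hr_rows <- grepl("^stratum", rownames(sm))
    hr <- data.frame(stratum = sub("^stratum", "", rownames(sm)[hr_rows]),
                     HR = exp(sm[hr_rows, "coef"]),
                     SE = sm[hr_rows, "se(coef)"],
                     p = sm[hr_rows, "Pr(>|z|)"], row.names = NULL,
                     stringsAsFactors = FALSE)
  }
  list(km = km, hr = hr, strata_labels = lab,
       reference = lab[reference])
}
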
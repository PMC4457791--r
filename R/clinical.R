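#' Cohen's kappa for a 2x2 concordance table
#'
#' kappa = (p_o - p_e) / (1 - p_e), with the large-sample z-test of
#' kappa = 0 (null standard error from the marginal proportions; two-sided
#' p). Degenerate margins (p_e = 1) leave kappa undefined and flagged.
#'
#' @param tab 2x2 nonnegative integer table (rows: truth; columns: predicted).
#' @return list: kappa, z, p, n, degenerate.
#' @export
cohenKappa <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || sum(tab) <= 0) stop("table must be nonnegative with total > 0")
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (abs(1 - pe) < .Machine$double.eps * 8)
    return(list(kappa = NA_real_, z = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  kappa <- (po - pe) / (1 - pe)
  # Fleiss null variance of kappa-hat
  se0 <- sqrt(pe + pe^2 - sum(rowm * colm * (rowm + colm))) / ((1 - pe) * sqrt(n))
  z <- kappa / se0
  list(kappa = kappa, z = z, p = 2 * stats::pnorm(-abs(z)), n = n,
       degenerate = FALSE)
}

#' Blinded-test concordance summary
#'
#' Cross-tabulates truth (tissue assay) against the classifier's label,
#' counting unclassifiable (invalid) spectra per truth class. The
#' denominators follow the blinded-test convention: invalid spectra count
#' against sensitivity, specificity and accuracy
#' (sensitivity = TP / (TP + FN + invalid among true mutants),
#' specificity = TN / (TN + FP + invalid among true wilds),
#' accuracy = (TP + TN) / all samples including invalid), while Cohen's
#' kappa is computed on classified samples only.
#'
#' @param records data.frame with columns `truth` ("mutant"/"wild") and
#'   `predicted` ("mutant"/"wild"/"unclassifiable").
#' @return list: counts (TP, FN, FP, TN, invalidMutant, invalidWild, total),
#'   sensitivity, specificity, accuracy (percent), kappa, kappaP.
#' @export
confusionSummary <- function(records) {
  if (NROW(records) == 0L) stop("no records")
  stopifnot(all(c("truth", "predicted") %in% names(records)))
  if (anyNA(records$truth) || anyNA(records$predicted))
    stop("every record needs truth and predicted")
  tr <- records$truth; pr <- records$predicted
  TP <- sum(tr == "mutant" & pr == "mutant")
  FN <- sum(tr == "mutant" & pr == "wild")
  FP <- sum(tr == "wild" & pr == "mutant")
  TN <- sum(tr == "wild" & pr == "wild")
  invM <- sum(tr == "mutant" & pr == "unclassifiable")
  invW <- sum(tr == "wild" & pr == "unclassifiable")
  total <- length(tr)
  k <- if (TP + FN + FP + TN > 0)
    cohenKappa(matrix(c(TP, FN, FP, TN), 2, 2, byrow = TRUE))
  else list(kappa = NA_real_, p = NA_real_)
  div <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  list(counts = c(TP = TP, FN = FN, FP = FP, TN = TN,
                  invalidMutant = invM, invalidWild = invW, total = total),
       sensitivity = div(TP, TP + FN + invM),
       specificity = div(TN, TN + FP + invW),
       accuracy = div(TP + TN, total),
       kappa = k$kappa, kappaP = k$p)
}

#' Response rates by classifier label
#'
#' Restricted to TKI-treated patients with a non-missing RECIST response and
#' a definite label, tabulates CR/PR/SD/PD per label and computes the
#' objective response rate (CR+PR) and disease control rate (CR+PR+SD), with
#' a chi-squared test (no continuity correction) and Fisher's exact test on
#' the objective-response and disease-control 2x2 tables. Labels with no
#' patients are omitted with a warning.
#'
#' @param records data.frame with columns `predicted`, `response` and
#'   optionally `tki_treated` (default all treated).
#' @return list: table (per-label counts and rates), orr (chisq p, fisher p),
#'   dcr (ditto).
#' @export
responseTable <- function(records) {
  if (!"tki_treated" %in% names(records)) records$tki_treated <- TRUE
  keep <- records$tki_treated & !is.na(records$response) &
    records$predicted %in% c("mutant", "wild")
  r <- records[keep, , drop = FALSE]
  labs <- c("mutant", "wild")
  empty <- labs[!labs %in% r$predicted]
  if (length(empty)) {
    warning("label(s) with no patients omitted: ", paste(empty, collapse = ", "))
    labs <- setdiff(labs, empty)
  }
  if (!length(labs)) stop("no evaluable patients")
  lev <- c("CR", "PR", "SD", "PD")
  tab <- t(vapply(labs, function(l) {
    cnt <- table(factor(r$response[r$predicted == l], levels = lev))
    as.numeric(cnt)
  }, numeric(4)))
  colnames(tab) <- lev
  n <- rowSums(tab)
  orrPct <- 100 * (tab[, "CR"] + tab[, "PR"]) / n
  dcrPct <- 100 * (tab[, "CR"] + tab[, "PR"] + tab[, "SD"]) / n
  out <- data.frame(label = labs, tab, n = n, orrPct = orrPct, dcrPct = dcrPct,
                    row.names = NULL, check.names = FALSE)
  tests <- function(success) {
    if (length(labs) < 2L) return(list(chisqP = NA_real_, fisherP = NA_real_,
                                       chisqStat = NA_real_))
    m <- rbind(success, n - success)
    if (sum(m) == 0 || any(rowSums(m) == 0))
      return(list(chisqP = NA_real_, fisherP = NA_real_, chisqStat = NA_real_))
    cs <- suppressWarnings(stats::chisq.test(t(m), correct = FALSE))
    fp <- stats::fisher.test(t(m))$p.value
    list(chisqStat = unname(cs$statistic), chisqP = cs$p.value, fisherP = fp)
  }
  list(table = out,
       orr = tests(tab[, "CR"] + tab[, "PR"]),
       dcr = tests(tab[, "CR"] + tab[, "PR"] + tab[, "SD"]))
}

#' Kaplan-Meier estimate with median and 95% CI
#'
#' Product-limit estimator (via the survival package) with the
#' log(-log)-transformed confidence interval; the median is the earliest
#' time at which the survivor function drops to 0.5 or below, `NA` ("not
#' reached") when it never does.
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param conf confidence level.
#' @return list: curve (data.frame time, nRisk, nEvent, surv, lower, upper),
#'   median, medianLower, medianUpper, nEvents.
#' @export
kmEstimate <- function(times, events, conf = 0.95) {
  if (any(times < 0)) stop("negative follow-up time")
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf)
  tab <- summary(fit)$table
  # earliest time at which the survivor curve reaches 0.5 (not the midpoint
  # of an exactly-0.5 plateau)
  med <- if (any(fit$surv <= 0.5 + 1e-12))
    min(fit$time[fit$surv <= 0.5 + 1e-12]) else NA_real_
  list(curve = data.frame(time = fit$time, nRisk = fit$n.risk,
                          nEvent = fit$n.event, surv = fit$surv,
                          lower = fit$lower, upper = fit$upper),
       median = med,
       medianLower = unname(tab[grep("LCL$", names(tab))][1]),
       medianUpper = unname(tab[grep("UCL$", names(tab))][1]),
       nEvents = sum(events))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the shared risk
#' sets, 1 degree of freedom. With no events in either group the statistic
#' is undefined and returned as NA with a flag.
#'
#' @param timesA,eventsA,timesB,eventsB per-group times and event flags.
#' @return list: chisq, p, nEvents, undefined.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0)
    return(list(chisq = NA_real_, p = NA_real_, nEvents = 0L, undefined = TRUE))
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       nEvents = sum(event), undefined = FALSE)
}

#' Full clinical evaluation of blinded predictions
#'
#' Convenience wrapper: concordance summary on all records, response table
#' and PFS/OS Kaplan-Meier + log-rank comparisons between the two predicted
#' labels (unclassifiable patients are excluded from outcome analyses, as in
#' a blinded test they receive no label).
#'
#' @param records data.frame with truth, predicted, response, pfs_months,
#'   pfs_event, os_months, os_event (and optionally tki_treated).
#' @return list: confusion, response, km (per label and endpoint), logrank
#'   (per endpoint).
#' @export
clinicalEvaluation <- function(records) {
  conf <- confusionSummary(records)
  resp <- responseTable(records)
  lab <- records$predicted
  out <- list(confusion = conf, response = resp, km = list(), logrank = list())
  for (ep in c("pfs", "os")) {
    tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(records))) next
    mut <- lab == "mutant"; wld <- lab == "wild"
    out$km[[ep]] <- list(
      mutant = kmEstimate(records[[tcol]][mut], records[[ecol]][mut]),
      wild = kmEstimate(records[[tcol]][wld], records[[ecol]][wld]))
    out$logrank[[ep]] <- logrankTest(records[[tcol]][mut], records[[ecol]][mut],
                                     records[[tcol]][wld], records[[ecol]][wld])
  }
  out
}
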
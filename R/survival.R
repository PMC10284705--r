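#' Build per-tumour survival records from phenotype timelines
#'
#' Event = tumour rejection: time is the first day the code reaches 5. Mouse
#' death censors at the last observed pre-death day; tumours with neither
#' event are censored at the horizon (last day). Survival units are
#' individual tumours, as in per-lesion array survival analyses.
#'
#' @param timelines a [phenotype_timelines()] or code matrix.
#' @param group optional per-tumour group labels carried into the records.
#' @return data.frame(tumour_id, time, event, group); tumours dead on day 1
#'   (no pre-death observation) are dropped with a warning.
#' @export
build_records <- function(timelines, group = NULL) {
  codes <- if (inherits(timelines, "stamp_timelines")) timelines$codes else
    as.matrix(timelines)
  days <- if (inherits(timelines, "stamp_timelines")) timelines$days else
    seq_len(ncol(codes))
  ids <- if (inherits(timelines, "stamp_timelines")) timelines$tumour_ids else
    seq_len(nrow(codes))
  n <- nrow(codes)
  if (!is.null(group) && length(group) != n)
    stop("group must have one label per tumour")
  time <- event <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    x <- codes[i, ]
    t5 <- which(x == 5L)[1]
    t0 <- which(x == 0L)[1]
    if (!is.na(t5) && (is.na(t0) || t5 < t0)) {
      time[i] <- days[t5]; event[i] <- 1
    } else if (!is.na(t0)) {
      if (t0 == 1L) { keep[i] <- FALSE; next }
      time[i] <- days[t0 - 1L]; event[i] <- 0
    } else {
      time[i] <- days[length(days)]; event[i] <- 0
    }
  }
  if (!all(keep)) warning(sum(!keep), " tumour(s) dead on day 1 dropped")
  out <- data.frame(tumour_id = ids, time = time, event = event)
  if (!is.null(group)) out$group <- group
  out[keep, , drop = FALSE]
}

#' Kaplan-Meier estimate with 95% confidence band
#'
#' Product-limit estimate with Greenwood variance and a log-log transformed
#' 95% confidence interval.
#'
#' @param records data.frame with `time` and `event` columns (1 = rejection,
#'   0 = censored).
#' @param conf_level confidence level.
#' @return data.frame(time, n_risk, n_event, surv, lower, upper), one row per
#'   distinct observed time.
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  if (nrow(records) < 1) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log", conf.int = conf_level)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Pairwise log-rank tests against a reference group
#'
#' Standard log-rank chi-square (1 df) for each group versus the reference.
#' Empty groups are skipped with a warning.
#'
#' @param records data.frame with `time`, `event` and a group column.
#' @param group_col name of the group column.
#' @param reference reference group label (default: first level).
#' @return data.frame(group, n, chisq, p) with one row per non-reference group.
#' @export
logrank_test <- function(records, group_col = "group", reference = NULL) {
  g <- as.character(records[[group_col]])
  if (is.null(g)) stop("missing group column: ", group_col)
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("reference group not present")
  out <- list()
  for (other in setdiff(lev, reference)) {
    sub <- records[g %in% c(reference, other), ]
    if (sum(g == other) == 0 || nrow(sub) == 0) {
      warning("empty group skipped: ", other)
      next
    }
    sub$grp <- factor(g[g %in% c(reference, other)],
                      levels = c(reference, other))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = sub)
    out[[other]] <- data.frame(
      group = other, n = sum(g == other), chisq = sd$chisq,
      p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }
  do.call(rbind, out)
}

#' Phenotype at a landmark day
#'
#' Convenience grouping for landmark survival analyses: the phenotype state
#' each tumour shows at the given day (e.g. day 8), with later changes
#' ignored.
#'
#' @param timelines a [phenotype_timelines()] or code matrix.
#' @param day landmark day.
#' @return character vector of state names.
#' @export
phenotype_at_day <- function(timelines, day) {
  codes <- if (inherits(timelines, "stamp_timelines")) timelines$codes else
    as.matrix(timelines)
  days <- if (inherits(timelines, "stamp_timelines")) timelines$days else
    seq_len(ncol(codes))
  j <- match(day, days)
  if (is.na(j)) stop("landmark day not in the series")
  code_to_state(codes[, j])
}
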
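# Kaplan-Meier estimation and log-rank comparison across subtypes, backed
# by the survival package.

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survivor function. Standard conventions
#' apply: censored observations at an event time are counted at risk for
#' that time (deaths processed before censorings at equal times), S(0) = 1,
#' and the curve is a right-continuous non-increasing step function.
#'
#' @param time Nonnegative follow-up times (months).
#' @param event Event indicator, 1 = event, 0 = censored.
#' @return A list of class \code{"km_curve"}: \code{time} (ordered unique
#'   event times), \code{surv} (survival probability after each event
#'   time), \code{n_risk}, \code{n_event}, and the underlying
#'   \code{survfit} object.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("need at least one record")
  stopifnot(length(time) == length(event),
            all(is.finite(time)), all(time >= 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep],
                 surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep],
                 fit = fit),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Step-function evaluation: the survival probability after the last event
#' time at or before \code{t}; 1 before the first event.
#'
#' @param curve A \code{"km_curve"}.
#' @param t Nonnegative time.
#' @return Survival probability in [0, 1].
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- which(curve$time <= t)
  if (!length(idx)) return(1)
  curve$surv[max(idx)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "event time(s)\n")
  print(data.frame(time = x$time, n_risk = x$n_risk,
                   n_event = x$n_event, surv = round(x$surv, 4)),
        row.names = FALSE)
  invisible(x)
}

#' K-group log-rank test
#'
#' Compares survival across two or more groups with the log-rank
#' chi-square (df = k - 1), using hypergeometric expected event counts per
#' group at every event time.
#'
#' @param time,event As in [km_curve()].
#' @param group Group label per record (e.g. EHBMT subtype).
#' @return A list: \code{statistic}, \code{df}, \code{p_value}, and
#'   per-group observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  k <- nlevels(group)
  list(statistic = unname(sd$chisq),
       df = k - 1L,
       p_value = stats::pchisq(sd$chisq, df = k - 1L, lower.tail = FALSE),
       observed = stats::setNames(as.vector(sd$obs), levels(group)),
       expected = stats::setNames(as.vector(sd$exp), levels(group)))
}
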
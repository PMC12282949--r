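#' Signed survival score from a hazard ratio
#'
#' Harmful and protective effects are made symmetric around +/-1:
#' the score equals HR when HR >= 1 and -1/HR when HR < 1 (HR exactly 1
#' maps to +1).
#'
#' @param hr hazard ratio(s), > 0.
#' @return numeric vector of scores with |score| >= 1.
#' @export
survival_score <- function(hr) {
  if (any(!is.na(hr) & hr <= 0)) stop("hazard ratios must be positive")
  ifelse(hr >= 1, hr, -1 / hr)
}

#' Univariate Cox regression per bin and direction
#'
#' For every bin, fits a proportional-hazards model on the binary gain
#' indicator and, separately, on the loss indicator (Efron ties). Bins
#' whose indicator is constant, or with too few samples in either group,
#' are flagged untestable.
#'
#' @param states character state matrix samples x bins from
#'   [call_states()].
#' @param surv data.frame with `sample`, `time` (> 0), `event` (0/1).
#' @param directions subset of `c("gain", "loss")`.
#' @param min_events minimum total events, default 10.
#' @param min_group minimum samples per indicator group, default 3.
#' @return data.frame per (bin, direction): `bin_id`, `direction`,
#'   `n_with`, `n_without`, `HR`, `p` (Wald), `score`, `untestable`.
#' @export
cox_per_bin <- function(states, surv, directions = c("gain", "loss"),
                        min_events = 10L, min_group = 3L) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  if (any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  samples <- intersect(rownames(states), surv$sample)
  surv <- surv[match(samples, surv$sample), , drop = FALSE]
  if (sum(surv$event) < min_events)
    stop("fewer than ", min_events, " events")
  S <- survival::Surv(surv$time, surv$event)
  rows <- list()
  for (b in colnames(states)) {
    st <- states[samples, b]
    for (dir in directions) {
      ind <- as.integer(!is.na(st) & st == dir)
      ind[is.na(st)] <- NA
      n1 <- sum(ind == 1, na.rm = TRUE); n0 <- sum(ind == 0, na.rm = TRUE)
      rec <- data.frame(bin_id = b, direction = dir, n_with = n1,
                        n_without = n0, HR = NA_real_, p = NA_real_,
                        score = NA_real_, untestable = TRUE,
                        stringsAsFactors = FALSE)
      if (n1 >= min_group && n0 >= min_group) {
        fit <- try(survival::coxph(S ~ ind, ties = "efron"), silent = TRUE)
        if (!inherits(fit, "try-error") && is.finite(stats::coef(fit)[1])) {
          sm <- summary(fit)
          rec$HR <- unname(exp(stats::coef(fit)[1]))
          rec$p <- sm$coefficients[1, "Pr(>|z|)"]
          rec$score <- survival_score(rec$HR)
          rec$untestable <- FALSE
        }
      }
      rows[[paste(b, dir)]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier strata with log-rank test
#'
#' @param groups named character/factor vector of group labels per
#'   sample (>= 2 non-empty groups required).
#' @param surv data.frame with `sample`, `time`, `event`.
#' @return list with `curves` (data.frame `group`, `time`, `surv`,
#'   `n_risk`, including the `time = 0, surv = 1` anchor per group) and
#'   `logrank_p`.
#' @export
km_strata <- function(groups, surv) {
  samples <- intersect(names(groups)[!is.na(groups)], surv$sample)
  g <- factor(groups[samples])
  if (nlevels(droplevels(g)) < 2L) stop("need at least two non-empty groups")
  surv <- surv[match(samples, surv$sample), , drop = FALSE]
  S <- survival::Surv(surv$time, surv$event)
  fit <- survival::survfit(S ~ g)
  strata_names <- sub("^g=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_names, time = fit$time,
                       surv = fit$surv, n_risk = fit$n.risk,
                       stringsAsFactors = FALSE)
  anchors <- data.frame(group = sub("^g=", "", names(fit$strata)), time = 0,
                        surv = 1, n_risk = as.integer(fit$n),
                        stringsAsFactors = FALSE)
  curves <- rbind(anchors, curves)
  curves <- curves[order(curves$group, curves$time), , drop = FALSE]
  rownames(curves) <- NULL
  lr <- survival::survdiff(S ~ g)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  list(curves = curves, logrank_p = p)
}
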
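# Time-to-distant-recurrence analysis: outcome construction, Kaplan-Meier
# product-limit estimation, and Cox proportional-hazards fitting by
# Newton-Raphson on the partial likelihood (Efron or Breslow ties).

#' Time-to-distant-recurrence outcome from follow-up fields
#'
#' The event of interest is the first distant recurrence (DR). Secondary
#' carcinoma (including contralateral breast cancer), death of any cause,
#' and end of follow-up all censor at the follow-up time.
#'
#' @param cohort data.frame with `followup_time` (years, > 0) and
#'   `event_type` in `{"distant_recurrence","secondary_carcinoma","death","none"}`;
#'   or a single record as a list with those fields.
#' @return data.frame: `sample_id`, `duration` (years), `event` (0/1).
#' @export
#' @examples
#' time_to_dr(data.frame(followup_time = c(4, 2.5, 11),
#'            event_type = c("secondary_carcinoma", "distant_recurrence", "none")))
time_to_dr <- function(cohort) {
  if (!is.data.frame(cohort)) cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  need <- c("followup_time", "event_type")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("missing field(s): %s", paste(miss, collapse = ", "))
  ft <- cohort$followup_time
  if (any(is.na(ft) | ft <= 0))
    stopf("followup_time must be positive for every record")
  known <- c("distant_recurrence", "secondary_carcinoma", "death", "none")
  if (!all(cohort$event_type %in% known))
    stopf("event_type must be one of %s", paste(known, collapse = ", "))
  data.frame(sample_id = cohort[["sample_id"]] %||% seq_len(nrow(cohort)),
             duration = ft,
             event = as.integer(cohort$event_type == "distant_recurrence"),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimator
#'
#' Right-continuous non-increasing step function with S(0) = 1:
#' \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)} over distinct event times
#' \eqn{t_j} with \eqn{d_j} events among \eqn{n_j} at risk.
#'
#' @param duration event/censoring times (> 0).
#' @param event 0/1 event indicator.
#' @return object of class `km_curve`: data.frame `steps` (`time`, `n_risk`,
#'   `n_event`, `surv`), plus `n` and `n_events`.
#' @export
#' @examples
#' km <- km_curve(c(1, 2, 3), c(1, 1, 1))
#' km$steps$surv   # 2/3, 1/3, 0
km_curve <- function(duration, event) {
  if (!length(duration)) stopf("at least one outcome is required")
  if (any(is.na(duration) | duration <= 0)) stopf("durations must be positive")
  event <- as.integer(event)
  et <- sort(unique(duration[event == 1]))
  n_risk <- vapply(et, function(t) sum(duration >= t), integer(1))
  n_event <- vapply(et, function(t) sum(duration == t & event == 1), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(steps = data.frame(time = et, n_risk = n_risk,
                                    n_event = n_event, surv = surv),
                 n = length(duration), n_events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, %d event times\n",
              x$n, x$n_events, nrow(x$steps)))
  print(utils::head(x$steps, 10), row.names = FALSE)
  if (nrow(x$steps) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Years", ylab = "Distant recurrence-free proportion",
                          ...) {
  s <- x$steps
  graphics::plot(stats::stepfun(s$time, c(1, s$surv)), do.points = FALSE,
                 xlim = c(0, max(s$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# Partial log-likelihood, gradient and Hessian at beta, using suffix sums
# over the time-sorted data. Ties: Efron (default) or Breslow.
cox_pl <- function(beta, tm, ev, X, efron = TRUE) {
  n <- length(tm); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  revcs <- function(v) rev(cumsum(rev(v)))
  S0 <- revcs(w)
  S1 <- apply(w * X, 2, revcs); dim(S1) <- c(n, p)
  # S2 columns indexed (j,k), j<=k
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  W2 <- X[, idx[, 1], drop = FALSE] * X[, idx[, 2], drop = FALSE] * w
  S2 <- apply(W2, 2, revcs); dim(S2) <- c(n, nrow(idx))
  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(idx[, 1], idx[, 2])] <- v
    M[cbind(idx[, 2], idx[, 1])] <- v
    M
  }
  ll <- 0; g <- numeric(p); H <- matrix(0, p, p)
  ut <- unique(tm[ev == 1])
  first <- match(ut, tm)          # tm is sorted ascending
  for (k in seq_along(ut)) {
    D <- which(tm == ut[k] & ev == 1)
    d <- length(D)
    s0r <- S0[first[k]]; s1r <- S1[first[k], ]; s2r <- unpack(S2[first[k], ])
    wD <- w[D]; XD <- X[D, , drop = FALSE]
    s0d <- sum(wD); s1d <- colSums(wD * XD)
    s2d <- unpack(colSums(W2[D, , drop = FALSE]))
    ll <- ll + sum(eta[D])
    g <- g + colSums(XD)
    for (l in seq_len(d) - 1L) {
      f <- if (efron) l / d else 0
      phi <- s0r - f * s0d
      u <- s1r - f * s1d
      V <- s2r - f * s2d
      ll <- ll - log(phi)
      g <- g - u / phi
      H <- H - (V / phi - tcrossprod(u) / phi^2)
    }
  }
  list(ll = ll, g = g, H = H)
}

#' Cox proportional-hazards fit by Newton-Raphson on the partial likelihood
#'
#' Maximises the partial likelihood with Efron (default) or Breslow tie
#' handling, with step-halving whenever a Newton step would decrease the
#' log-likelihood. Convergence when the gradient max-norm falls below `tol`
#' (default 1e-8) within `max_iter` iterations, or when the likelihood can
#' no longer be improved in floating point while the score is already
#' negligible (< 1e-5) for the likelihood's scale. Wald confidence
#' intervals and p-values from the observed information.
#'
#' @param duration event/censoring times (> 0).
#' @param event 0/1 event indicator (at least one event required).
#' @param x covariates: numeric matrix, or data.frame (factors expanded
#'   against their first level via [stats::model.matrix()]).
#' @param ties `"efron"` or `"breslow"`.
#' @param conf.level confidence level for the Wald intervals.
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `strat4_cox`: `coefficients`, `se`, `hr`,
#'   `lower`, `upper`, `z`, `p.value`, `loglik` (null, final), `iterations`,
#'   `gradient_norm`, `converged`, `vcov`, `n`, `n_events`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 1, 0.5)
#' t <- rexp(200, 0.1 * exp(0.7 * x)); c0 <- runif(200, 2, 15)
#' fit <- cox_fit(pmin(t, c0), as.integer(t <= c0), cbind(marker = x))
#' coef(fit)
cox_fit <- function(duration, event, x, ties = c("efron", "breslow"),
                    conf.level = 0.95, max_iter = 50, tol = 1e-8) {
  ties <- match.arg(ties)
  if (is.data.frame(x)) {
    x <- droplevels(x)       # an empty factor level would give a zero column
    mm <- stats::model.matrix(~ ., data = x)
    x <- mm[, -1, drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(is.na(duration) | duration <= 0)) stopf("durations must be positive")
  if (anyNA(x)) stopf("covariates must be complete (drop incomplete records first)")
  event <- as.integer(event)
  if (sum(event) < 1) stopf("at least one event is required")
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    stopf("constant covariate(s): %s", paste(colnames(x)[const], collapse = ", "))

  o <- order(duration)
  tm <- duration[o]; ev <- event[o]; X <- x[o, , drop = FALSE]
  p <- ncol(X)
  beta <- numeric(p)
  efron <- ties == "efron"
  cur <- cox_pl(beta, tm, ev, X, efron)
  ll0 <- cur$ll
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    if (max(abs(cur$g)) < tol) { converged <- TRUE; break }
    it <- it + 1
    step <- tryCatch(solve(-cur$H, cur$g), error = function(e)
      stopf("singular information matrix: design not full rank on the risk sets"))
    h <- 1; improved <- FALSE; nxt <- cur
    for (k in 1:20) {
      cand <- beta + h * step
      nxt <- cox_pl(cand, tm, ev, X, efron)
      if (is.finite(nxt$ll) && nxt$ll > cur$ll) { improved <- TRUE; break }
      h <- h / 2
    }
    if (!improved) {
      # likelihood at its floating-point ceiling; a still-small score means
      # the optimum is resolved to machine precision
      converged <- max(abs(cur$g)) < 1e-5
      break
    }
    beta <- beta + h * step
    cur <- nxt
  }
  if (!converged && max(abs(cur$g)) < tol) converged <- TRUE
  # under a monotone partial likelihood (complete separation) the gradient
  # decays exponentially in beta, so the gradient criterion can be met at an
  # absurd coefficient; flag that as non-convergence
  diverged <- any(abs(beta) > 10)
  vcov <- tryCatch(solve(-cur$H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm((1 + conf.level) / 2)
  wald <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = exp(beta), lower = exp(beta - z * se),
                 upper = exp(beta + z * se),
                 z = wald, p.value = 2 * stats::pnorm(-abs(wald)),
                 loglik = c(null = ll0, final = cur$ll),
                 iterations = it, gradient_norm = max(abs(cur$g)),
                 converged = converged && !diverged,
                 monotone_likelihood = diverged,
                 vcov = vcov, ties = ties, conf.level = conf.level,
                 n = length(tm), n_events = sum(ev)),
            class = "strat4_cox")
}

#' @export
coef.strat4_cox <- function(object, ...) object$coefficients

#' @export
vcov.strat4_cox <- function(object, ...) object$vcov

#' @export
confint.strat4_cox <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste(round(100 * c((1 - level) / 2, (1 + level) / 2), 1), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.strat4_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  if (!x$converged)
    cat(sprintf("WARNING: did not converge (%s; gradient max-norm %.2e after %d iterations)\n",
                if (x$monotone_likelihood) "monotone likelihood / separation"
                else "iteration limit", x$gradient_norm, x$iterations))
  df <- data.frame(coef = round(x$coefficients, 4),
                   HR = round_half_up(x$hr, 2),
                   lower = round_half_up(x$lower, 2),
                   upper = round_half_up(x$upper, 2),
                   p = signif(x$p.value, 2))
  print(df)
  invisible(x)
}

#' @export
summary.strat4_cox <- function(object, ...) {
  df <- data.frame(term = names(object$coefficients),
                   coef = object$coefficients, se = object$se,
                   hr = object$hr, lower = object$lower, upper = object$upper,
                   z = object$z, p.value = object$p.value,
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = df, loglik = object$loglik, n = object$n,
                 n_events = object$n_events, converged = object$converged),
            class = "summary.strat4_cox")
}

#' @export
print.summary.strat4_cox <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("loglik: null %.3f, final %.3f; n = %d, events = %d%s\n",
              x$loglik["null"], x$loglik["final"], x$n, x$n_events,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Build the covariate frame for the distant-recurrence models from a cohort
# table plus its calls and reference classifications. Reference levels:
# pT1, 0 nodes, G1, marker-negative, Ki67 low.
dr_model_frame <- function(cohort, calls, reference) {
  bin <- function(s) factor(s, levels = c("negative", "positive"))
  df <- data.frame(
    sample_id = cohort$sample_id,
    age = cohort$age,
    pt_category = factor(cohort$pt_category, levels = c("pT1", "pT2", "pT3")),
    nodal = factor(cohort$nodal, levels = c("0", "1-3", "4-10", ">10")),
    grade = factor(cohort$grade, levels = c("G1", "G2", "G3", "GX")),
    stringsAsFactors = FALSE)
  for (m in MARKERS) {
    s <- calls[[paste0("status_", tolower(m))]]
    s[!s %in% c("positive", "negative")] <- NA
    df[[tolower(m)]] <- bin(s)
  }
  df$er_ref <- bin(reference$er)
  df$pr_ref <- bin(reference$pr)
  df$her2_ref <- bin(reference$her2)
  df$ki67_ref <- factor(reference$ki67_group,
                        levels = c("low", "intermediate", "high"))
  df$ki67_ref_gt20 <- factor(reference$ki67_binary, levels = c("le20", "gt20"))
  df
}

#' Univariable and multivariable distant-recurrence Cox models
#'
#' Reproduces the standard model layout for this study design: univariable
#' fits for each clinical covariate and each marker (both the delta-Ct calls
#' and the IHC/ISH reference, including the 3-level and the >20\% vs <=20\%
#' Ki67 groupings), plus two multivariable models combining age, tumour
#' size, nodal status and grade with either the four delta-Ct call statuses
#' or the reference statuses (3-level Ki67). Records with any incomplete
#' covariate (including invalid/indeterminate calls) are dropped once for
#' all models and tallied. Constant covariates are excluded with a message.
#'
#' @param cohort full cohort table (Ct, IHC, covariate and follow-up columns).
#' @param thresholds a [strat4_thresholds()] object.
#' @param ties tie handling passed to [cox_fit()].
#' @return object of class `dr_models`: `univariable` (named list of
#'   `strat4_cox` fits), `multivariable_calls`, `multivariable_reference`,
#'   `n_complete`, `n_dropped`, `n_events`, `dropped_covariates`, `unfit`.
#' @export
run_dr_models <- function(cohort, thresholds = strat4_thresholds(),
                          ties = "efron") {
  calls <- classify_cohort(cohort, thresholds)
  reference <- classify_reference(cohort)
  outcome <- time_to_dr(cohort)
  df <- dr_model_frame(cohort, calls, reference)
  df$duration <- outcome$duration
  df$event <- outcome$event
  covars <- setdiff(names(df), c("sample_id", "duration", "event"))
  cc <- stats::complete.cases(df[covars])
  dat <- df[cc, , drop = FALSE]
  n_events <- sum(dat$event)
  out <- list(n_complete = nrow(dat), n_dropped = sum(!cc),
              n_events = n_events, dropped_covariates = character(0))
  if (n_events == 0) {
    out$unfit <- TRUE
    out$univariable <- list()
    class(out) <- "dr_models"
    return(out)
  }
  out$unfit <- FALSE
  usable <- covars[vapply(covars, function(v) {
    x <- dat[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))]
  dropped <- setdiff(covars, usable)
  if (length(dropped)) {
    message("excluding constant covariate(s): ", paste(dropped, collapse = ", "))
    out$dropped_covariates <- dropped
  }
  fit1 <- function(vars) {
    cox_fit(dat$duration, dat$event, dat[vars], ties = ties)
  }
  out$univariable <- lapply(stats::setNames(usable, usable),
                            function(v) fit1(v))
  base <- intersect(c("age", "pt_category", "nodal", "grade"), usable)
  m_call <- intersect(tolower(MARKERS), usable)
  m_ref <- intersect(c("er_ref", "pr_ref", "her2_ref", "ki67_ref"), usable)
  out$multivariable_calls <- fit1(c(base, m_call))
  out$multivariable_reference <- fit1(c(base, m_ref))
  class(out) <- "dr_models"
  out
}

#' @export
print.dr_models <- function(x, ...) {
  cat(sprintf("Distant-recurrence Cox model report: %d complete records (%d dropped), %d events\n",
              x$n_complete, x$n_dropped, x$n_events))
  if (isTRUE(x$unfit)) {
    cat("No events: all models unfit.\n")
    return(invisible(x))
  }
  cat("\nUnivariable models:\n")
  for (v in names(x$univariable)) {
    f <- x$univariable[[v]]
    for (i in seq_along(f$coefficients))
      cat(sprintf("  %-28s HR %5.2f (%.2f-%.2f) p=%.2g\n",
                  names(f$coefficients)[i], round_half_up(f$hr[i], 2),
                  round_half_up(f$lower[i], 2), round_half_up(f$upper[i], 2),
                  f$p.value[i]))
  }
  for (nm in c("multivariable_calls", "multivariable_reference")) {
    cat(sprintf("\n%s:\n", if (nm == "multivariable_calls")
      "Multivariable model (delta-Ct calls)" else "Multivariable model (IHC/ISH reference)"))
    f <- x[[nm]]
    for (i in seq_along(f$coefficients))
      cat(sprintf("  %-28s HR %5.2f (%.2f-%.2f) p=%.2g\n",
                  names(f$coefficients)[i], round_half_up(f$hr[i], 2),
                  round_half_up(f$lower[i], 2), round_half_up(f$upper[i], 2),
                  f$p.value[i]))
  }
  invisible(x)
}
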
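#' Score bulk samples against a gene signature
#'
#' Mean expression of the signature's (present) genes per sample; for a
#' directional signature the down-gene mean is subtracted. The cohort
#' table convention is `sample_id`, `time`, `event`, then one column per
#' gene.
#'
#' @param cohort data.frame in cohort layout, or a samples x genes
#'   numeric matrix.
#' @param signature a [gene_signature()].
#' @return named per-sample score vector.
#' @export
score_bulk_samples <- function(cohort, signature) {
  stopifnot(inherits(signature, "GeneSignature"))
  if (is.data.frame(cohort)) {
    m <- as.matrix(cohort[, setdiff(colnames(cohort),
                                    c("sample_id", "time", "event")),
                          drop = FALSE])
    rownames(m) <- cohort$sample_id
  } else {
    m <- as.matrix(cohort)
  }
  expr <- expression_matrix(m, "normalized_log")
  score_directional_signature(expr, signature)
}

#' Stratify samples into score quartiles
#'
#' Cut points are the 25/50/75 empirical percentiles (linear
#' interpolation); samples tied exactly at a cut point fall into the
#' lower group. With distinct scores, group sizes differ by at most 1.
#'
#' @param scores numeric vector (>= 8 values, not all equal).
#' @return integer group labels 1 (lowest) to 4 (highest).
#' @export
stratify_by_quartiles <- function(scores) {
  if (length(scores) < 8) stop("need >= 8 samples for quartiles")
  if (max(scores) == min(scores)) stop("constant scores cannot be stratified")
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  g <- 1L + (scores > qs[1]) + (scores > qs[2]) + (scores > qs[3])
  stats::setNames(as.integer(g), names(scores))
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return data.frame with one row per distinct time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (the estimate just after that
#'   time). `S(0) = 1` implicitly; censored times reduce the risk set
#'   without contributing a factor.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("negative time")
  events <- as.integer(events)
  ut <- sort(unique(times))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk[i] <- sum(times >= t)
    n_event[i] <- sum(times == t & events == 1)
    n_censor[i] <- sum(times == t & events == 0)
    if (n_event[i] > 0) s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' K-group log-rank test
#'
#' Standard unweighted log-rank: at each distinct event time the observed
#' events per group are compared with their hypergeometric expectations
#' given the risk sets; the chi-square statistic uses the
#' variance-covariance matrix of the first K-1 groups, with K-1 degrees
#' of freedom.
#'
#' @param group_labels per-sample group labels (>= 2 non-empty groups).
#' @param times,events as in [km_estimate()]; at least one event.
#' @return list with `statistic`, `df`, `p`, and per-group
#'   observed/expected counts.
#' @export
logrank_test <- function(group_labels, times, events) {
  group_labels <- as.character(group_labels)
  groups <- sort(unique(group_labels))
  K <- length(groups)
  if (K < 2) stop("need at least 2 groups")
  if (any(table(factor(group_labels, levels = groups)) == 0))
    stop("a group has 0 samples")
  events <- as.integer(events)
  if (sum(events) < 1) stop("need at least 1 event")
  event_times <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(K), groups)
  V <- matrix(0, K - 1, K - 1)
  for (t in event_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    n_g <- vapply(groups, function(g) sum(at_risk & group_labels == g),
                  numeric(1))
    d_g <- vapply(groups, function(g)
      sum(times == t & events == 1 & group_labels == g), numeric(1))
    O <- O + d_g
    E <- E + n_g * d / n
    if (n > 1) {
      for (a in seq_len(K - 1)) for (b in seq_len(K - 1)) {
        V[a, b] <- V[a, b] +
          d * (n - d) / (n - 1) *
          (n_g[a] * ((a == b) * n - n_g[b])) / n^2
      }
    }
  }
  z <- (O - E)[seq_len(K - 1)]
  Vi <- tryCatch(solve(V), error = function(e) MASS_ginv(V))
  stat <- drop(t(z) %*% Vi %*% z)
  p <- stats::pchisq(stat, df = K - 1, lower.tail = FALSE)
  list(statistic = stat, df = K - 1, p = p, observed = O, expected = E)
}

# Moore-Penrose pseudoinverse (avoids a MASS dependency for the rare
# singular variance matrix).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Breslow
#' handling of tied event times (Efron available via `ties`). Iteration
#' stops when the coefficient moves < 1e-8 or after `max_iter` rounds.
#' Monotone likelihood (complete separation) is detected when the
#' coefficient escapes `cap`; it is then capped with a warning and
#' flagged in the result.
#'
#' @param score numeric covariate (must vary).
#' @param times,events as in [km_estimate()]; >= 2 events required.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter,tol Newton controls.
#' @param cap absolute bound declaring monotone likelihood (default 10).
#' @return list with `coef`, `hr`, `se`, `z`, `p`, `iterations`,
#'   `separation` flag.
#' @export
cox_univariate <- function(score, times, events, ties = c("breslow", "efron"),
                           max_iter = 50, tol = 1e-8, cap = 10) {
  ties <- match.arg(ties)
  events <- as.integer(events)
  if (max(score) == min(score)) stop("score does not vary")
  if (sum(events) < 2) stop("need at least 2 events")
  beta <- 0
  separation <- FALSE
  deriv <- function(beta) cox_partial_derivs(beta, score, times, events, ties)
  it <- 0
  repeat {
    it <- it + 1
    d <- deriv(beta)
    if (d$info <= 0) break
    step <- d$grad / d$info
    beta_new <- beta + step
    if (abs(beta_new) > cap) {
      separation <- TRUE
      beta_new <- sign(beta_new) * cap
    }
    done <- abs(beta_new - beta) < tol || it >= max_iter || separation
    beta <- beta_new
    if (done) break
  }
  if (separation)
    warning("monotone partial likelihood (complete separation); ",
            "coefficient capped at ", sign(beta) * cap)
  info <- deriv(beta)$info
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  z <- beta / se
  list(coef = beta, hr = exp(beta), se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), iterations = it,
       separation = separation)
}

# Gradient and information of the Cox partial log-likelihood at beta.
cox_partial_derivs <- function(beta, score, times, events, ties) {
  event_times <- sort(unique(times[events == 1]))
  grad <- 0; info <- 0
  eta <- exp(beta * score)
  for (t in event_times) {
    risk <- times >= t
    dead <- times == t & events == 1
    d <- sum(dead)
    s0 <- sum(eta[risk])
    s1 <- sum(eta[risk] * score[risk])
    s2 <- sum(eta[risk] * score[risk]^2)
    sum_x <- sum(score[dead])
    if (ties == "breslow") {
      grad <- grad + sum_x - d * s1 / s0
      info <- info + d * (s2 / s0 - (s1 / s0)^2)
    } else {
      ed0 <- sum(eta[dead]); ed1 <- sum(eta[dead] * score[dead])
      ed2 <- sum(eta[dead] * score[dead]^2)
      for (l in seq_len(d) - 1) {
        f <- l / d
        s0l <- s0 - f * ed0; s1l <- s1 - f * ed1; s2l <- s2 - f * ed2
        grad <- grad + sum_x / d - s1l / s0l
        info <- info + s2l / s0l - (s1l / s0l)^2
      }
    }
  }
  list(grad = grad, info = info)
}

#' Breslow partial log-likelihood (exposed for validation)
#'
#' @inheritParams cox_univariate
#' @param beta coefficient at which to evaluate.
#' @return scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, score, times, events) {
  events <- as.integer(events)
  event_times <- sort(unique(times[events == 1]))
  ll <- 0
  eta <- beta * score
  for (t in event_times) {
    risk <- times >= t
    dead <- times == t & events == 1
    ll <- ll + sum(eta[dead]) - sum(dead) * log(sum(exp(eta[risk])))
  }
  ll
}

#' Signature-vs-outcome survival validation
#'
#' The headline analysis: scores a cohort against a signature, runs a
#' continuous-score univariate Cox model (the primary test), and a
#' 4-group log-rank across score quartiles with per-quartile
#' Kaplan-Meier curves (the visualization-style stratification).
#'
#' @param cohort cohort data.frame (`sample_id`, `time`, `event`, genes).
#' @param signature a [gene_signature()].
#' @param ties passed to [cox_univariate()].
#' @return list with `scores`, `quartile`, `cox`, `logrank`, `km` (list
#'   of per-quartile KM tables).
#' @export
validate_signature_survival <- function(cohort, signature, ties = "breslow") {
  scores <- score_bulk_samples(cohort, signature)
  quartile <- stratify_by_quartiles(scores)
  cox <- cox_univariate(scores, cohort$time, cohort$event, ties = ties)
  lr <- logrank_test(quartile, cohort$time, cohort$event)
  km <- lapply(split(seq_along(quartile), quartile), function(ix)
    km_estimate(cohort$time[ix], cohort$event[ix]))
  list(scores = scores, quartile = quartile, cox = cox, logrank = lr, km = km)
}
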
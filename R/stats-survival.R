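#' Kaplan-Meier product-limit estimator
#'
#' @param times Follow-up times (>= 0).
#' @param events Logical/0-1 event indicators (TRUE = event, FALSE =
#'   censored).
#' @param group Optional grouping vector; one curve per level.
#' @return data.table of class `km_fit`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the step function evaluated at each
#'   distinct observed time; `surv` at time 0 is 1 by construction).
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (any(times < 0, na.rm = TRUE)) stop("negative follow-up time")
  events <- as.logical(events)
  if (is.null(group)) group <- rep("all", length(times))
  stopifnot(length(times) == length(events), length(times) == length(group))
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  out <- lapply(split(seq_along(times), group), function(idx) {
    tt <- times[idx]; ev <- events[idx]
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ev), numeric(1))
    n_censor <- vapply(ut, function(u) sum(tt == u & !ev), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.table::data.table(time = ut, n_risk = n_risk, n_event = n_event,
                           n_censor = n_censor, surv = surv)
  })
  res <- data.table::rbindlist(out, idcol = "group")
  data.table::setattr(res, "class", c("km_fit", class(res)))
  res[]
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-squared statistic on 1 df,
#' accumulated over distinct event times with the hypergeometric variance.
#'
#' @param times,events As in [km_estimate()].
#' @param group Two-level grouping vector. Records with a missing time,
#'   event or group are dropped (pairwise deletion).
#' @return List of class `assoc_test`: `statistic`, `p.value`, `method`,
#'   `observed`, `expected` (group-1 sums).
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]
  g <- droplevels(as.factor(group[keep]))
  if (nlevels(g) != 2L) stop("log-rank test requires exactly two groups")
  if (!any(events)) stop("log-rank test requires at least one event")
  event_times <- sort(unique(times[events]))
  O <- E <- V <- 0
  for (t in event_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g == levels(g)[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  structure(list(statistic = stat,
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "log-rank", observed = O, expected = E),
            class = "assoc_test")
}

# Breslow partial log-likelihood, score and information at beta
cox_partial <- function(beta, times, events, X) {
  p <- ncol(X)
  eta <- if (p) drop(X %*% beta) else rep(0, length(times))
  w <- exp(eta)
  ord <- order(times, decreasing = TRUE)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  n <- length(times)
  while (i <= n) {
    t <- times[ord[i]]
    # admit everyone with this time into the risk set
    j <- i
    while (j <= n && times[ord[j]] == t) {
      k <- ord[j]
      S0 <- S0 + w[k]
      if (p) {
        xk <- X[k, ]
        S1 <- S1 + w[k] * xk
        S2 <- S2 + w[k] * tcrossprod(xk)
      }
      j <- j + 1L
    }
    # Breslow: every event at t sees the same risk set
    for (jj in i:(j - 1L)) {
      k <- ord[jj]
      if (!events[k]) next
      ll <- ll + eta[k] - log(S0)
      if (p) {
        m1 <- S1 / S0
        U <- U + X[k, ] - m1
        I <- I + S2 / S0 - tcrossprod(m1)
      }
    }
    i <- j
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Maximises the partial likelihood by Newton iteration with step halving;
#' converges when the largest score component falls below `tol` (default
#' 1e-6) or after `max_iter` iterations, in which case an error is raised
#' rather than returning a silently unconverged fit. Columns with zero
#' variance are held at coefficient 0 (relative risk 1) with infinite
#' standard error.
#'
#' @param times,events Follow-up times and event indicators.
#' @param X Numeric covariate matrix (categorical covariates pre-encoded);
#'   NULL or zero columns gives the null model (log-likelihood only).
#' @param tol Score convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return List of class `cox_model`: `coef`, `se`, `rr`, `ci_lower`,
#'   `ci_upper` (Wald 95%), `loglik`, `loglik_null`, `n`, `n_events`,
#'   `iter`, `converged`.
#' @export
cox_fit <- function(times, events, X = NULL, tol = 1e-6, max_iter = 50L) {
  events <- as.logical(events)
  if (!any(events)) stop("no events: Cox model undefined")
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(times), ncol = 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(times), length(events) == length(times))

  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  Xa <- X[, !const, drop = FALSE]
  p <- ncol(Xa)

  ll_null <- cox_partial(numeric(0), times, events,
                         matrix(numeric(0), length(times), 0))$loglik

  beta <- numeric(p)
  ll <- ll_null
  converged <- p == 0L
  iter <- 0L
  if (p) {
    repeat {
      iter <- iter + 1L
      pieces <- cox_partial(beta, times, events, Xa)
      ll <- pieces$loglik
      if (max(abs(pieces$score)) < tol) { converged <- TRUE; break }
      if (iter > max_iter)
        stop("Cox model failed to converge in ", max_iter,
             " iterations (possible separation)")
      step <- tryCatch(solve(pieces$info, pieces$score),
                       error = function(e) stop("singular information matrix ",
                                                "(possible separation)"))
      # step-halving: guard against genuine decreases of the partial
      # likelihood; the tolerance scales with |ll| so that rounding noise
      # near the optimum (where ll is flat to machine precision) does not
      # freeze the final Newton step
      h <- 1
      repeat {
        cand <- beta + h * step
        ll_new <- cox_partial(cand, times, events, Xa)$loglik
        if (is.finite(ll_new) && ll_new >= ll - 1e-9 * (abs(ll) + 1)) break
        h <- h / 2
        if (h < 1e-10) stop("Cox step-halving failed (possible separation)")
      }
      beta <- cand
    }
    info <- cox_partial(beta, times, events, Xa)$info
    se_active <- sqrt(diag(solve(info)))
  }

  coef <- stats::setNames(numeric(ncol(X)), colnames(X))
  se <- stats::setNames(rep(Inf, ncol(X)), colnames(X))
  if (p) {
    coef[!const] <- beta
    se[!const] <- se_active
  }
  structure(list(coef = coef, se = se, rr = exp(coef),
                 ci_lower = exp(coef - 1.96 * se),
                 ci_upper = exp(coef + 1.96 * se),
                 loglik = ll, loglik_null = ll_null,
                 n = length(times), n_events = sum(events),
                 iter = iter, converged = converged),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("Cox model (Breslow ties): n = %d, events = %d, loglik = %.4f\n",
              x$n, x$n_events, x$loglik))
  if (length(x$coef)) {
    tab <- data.frame(coef = x$coef, RR = x$rr, se = x$se,
                      ci_low = x$ci_lower, ci_high = x$ci_upper)
    print(round(tab, 4))
  } else cat("(null model)\n")
  invisible(x)
}

#' Forward likelihood-ratio stepwise Cox selection
#'
#' Starts from the empty model; at each step fits every remaining
#' candidate on top of the current model and adds the one with the
#' smallest likelihood-ratio p-value (2 * delta log partial likelihood
#' against chi-squared with the candidate's column count as df) provided
#' it is below `p_enter`; stops otherwise. Entry-only: no removal step.
#'
#' @param times,events Follow-up and event indicators.
#' @param candidates Named list of candidate covariates; each element a
#'   numeric vector or a matrix (multi-column block enters as a unit).
#' @param p_enter LR p-value required to enter (default 0.05).
#' @return List of class `cox_stepwise`: `model` (final [cox_fit()]),
#'   `included` (names in entry order), `trail` (per-step data.frame with
#'   every candidate's LR statistic, df and p).
#' @export
cox_stepwise_forward_lr <- function(times, events, candidates, p_enter = 0.05) {
  stopifnot(is.list(candidates), length(candidates) >= 2L,
            !is.null(names(candidates)))
  candidates <- lapply(candidates, function(v) {
    m <- as.matrix(v); storage.mode(m) <- "double"; m
  })
  included <- character(0)
  cur_X <- NULL
  cur_fit <- cox_fit(times, events, NULL)
  trail <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(names(candidates), included)
    if (!length(remaining)) break
    step <- step + 1L
    rows <- lapply(remaining, function(nm) {
      blk <- candidates[[nm]]
      colnames(blk) <- paste0(nm, if (ncol(blk) > 1L) seq_len(ncol(blk)) else "")
      fit <- tryCatch(cox_fit(times, events, cbind(cur_X, blk)),
                      error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(step = step, candidate = nm, lr = NA_real_,
                          df = ncol(blk), p = NA_real_))
      lr <- 2 * (fit$loglik - cur_fit$loglik)
      data.frame(step = step, candidate = nm, lr = lr, df = ncol(blk),
                 p = stats::pchisq(lr, df = ncol(blk), lower.tail = FALSE))
    })
    tr <- do.call(rbind, rows)
    trail[[step]] <- tr
    ok <- which(!is.na(tr$p))
    if (!length(ok)) break
    best <- ok[which.min(tr$p[ok])]
    if (!(tr$p[best] < p_enter)) break
    nm <- tr$candidate[best]
    blk <- candidates[[nm]]
    colnames(blk) <- paste0(nm, if (ncol(blk) > 1L) seq_len(ncol(blk)) else "")
    cur_X <- cbind(cur_X, blk)
    cur_fit <- cox_fit(times, events, cur_X)
    included <- c(included, nm)
  }
  structure(list(model = cur_fit, included = included,
                 trail = do.call(rbind, trail)),
            class = "cox_stepwise")
}

#' @export
print.cox_stepwise <- function(x, ...) {
  cat("Forward LR stepwise Cox: included =",
      if (length(x$included)) paste(x$included, collapse = ", ") else "(none)",
      "\n")
  print(x$model)
  invisible(x)
}
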
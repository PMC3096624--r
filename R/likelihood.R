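#' Build the inter-event interval table for a classification
#'
#' The sufficient statistic of the mixed Yule-coalescent likelihood.
#' Internal-node heights (after de-tying, strictly decreasing) define
#' `n - 1` events; interval `i` runs from event `i` down to event
#' `i + 1` (the last interval ends at height 0). Lineage counts are
#' accumulated in a single rootward-to-tipward sweep: a diversification
#' event adds one lineage to the between-species (Yule) process, whose
#' count equals the lineage-through-time curve of the tree with every
#' cluster contracted to a tip and is therefore frozen at the number of
#' delimited entities once diversification events are exhausted; a
#' coalescent event adds one lineage to its cluster's count.
#'
#' @param classification a [node_classification()].
#' @return a list of class `interval_table`: `x` (durations, > 0),
#'   `n_div` (Yule lineage count per interval), `csq` (matrix, interval
#'   x cluster, of `n(n-1)` pair counts), `has_div`/`has_coal` flags,
#'   `n_div_events`/`n_coal_events`, and `n_entities`.
#' @export
build_intervals <- function(classification) {
  stopifnot(inherits(classification, "node_classification"))
  tree <- classification$tree
  n <- tree$n_tips
  coal <- classification$coal
  internal <- (n + 1L):(2L * n - 1L)

  h <- tree$heights[internal]
  ord <- order(h, decreasing = TRUE)
  ev_nodes <- internal[ord]
  ev_h <- h[ord]
  if (any(diff(ev_h) >= 0)) {
    stop("branching times are not strictly decreasing; de-tying failed",
         call. = FALSE)
  }
  x <- c(-diff(ev_h), ev_h[length(ev_h)])
  if (any(x <= 0)) stop("nonpositive inter-event interval", call. = FALSE)

  ## cluster membership of each internal node: index of the maximal
  ## coalescent subtree containing it, 0 for diversification nodes
  et <- entity_table(classification)
  cl_idx <- which(vapply(et, `[[`, "", "type") == "cluster")
  member <- integer(2L * n - 1L)
  if (length(cl_idx)) {
    kids <- child_list(tree$phy)
    for (j in seq_along(cl_idx)) {
      stack <- et[[cl_idx[j]]]$root
      while (length(stack)) {
        nd <- stack[length(stack)]
        stack <- stack[-length(stack)]
        member[nd] <- j
        k <- kids[[nd]]
        stack <- c(stack, k[k > n])
      }
    }
  }

  m <- n - 1L
  k_cl <- length(cl_idx)
  n_div <- integer(m)
  csq <- matrix(0, nrow = m, ncol = k_cl)
  cnt_div <- 1L                      # stem of the contracted tree
  cnt_cl <- rep(1L, k_cl)            # each cluster's stem lineage
  for (i in seq_len(m)) {
    nd <- ev_nodes[i]
    if (coal[[as.character(nd)]]) {
      j <- member[nd]
      cnt_cl[j] <- cnt_cl[j] + 1L
    } else {
      cnt_div <- cnt_div + 1L
    }
    n_div[i] <- cnt_div
    if (k_cl) csq[i, ] <- cnt_cl * (cnt_cl - 1L)
  }

  n_coal_events <- sum(coal)
  structure(list(x = x, n_div = n_div, csq = csq,
                 has_div = any(!coal), has_coal = n_coal_events > 0L,
                 n_div_events = sum(!coal), n_coal_events = n_coal_events,
                 n_entities = length(et)),
            class = "interval_table")
}

## Per-interval total branching rate. Pair-count cells of 0 (a cluster
## with a single lineage) contribute 0 for every exponent, by convention.
interval_rates <- function(iv, lambda1, lambda2, p1, p2) {
  b <- numeric(length(iv$x))
  if (iv$has_div) b <- b + lambda1 * iv$n_div^p1
  if (iv$has_coal) {
    z <- iv$csq
    pos <- z > 0
    zp <- z
    zp[pos] <- z[pos]^p2
    b <- b + lambda2 * rowSums(zp)
  }
  b
}

loglik_from_rates <- function(b, x) {
  if (any(b <= 0) || any(!is.finite(b))) return(-Inf)
  sum(log(b) - b * x)
}

#' Mixed Yule-coalescent log-likelihood
#'
#' Each inter-event interval of duration `x_i` contributes
#' `log(b_i) - b_i x_i`, where the total branching rate is
#' `b_i = lambda1 * n_div^p1 + lambda2 * sum_j (n_ij (n_ij - 1))^p2`:
#' a Yule term over between-species lineages and a coalescent term
#' summed over clusters, with common rate-scaling exponents `p1`, `p2`.
#' When the classification has no diversification node (the single
#' cluster of the null model) the Yule term is dropped, so the mixed
#' model nests the null exactly; symmetrically the coalescent term is
#' dropped when every entity is a singleton.
#'
#' @param intervals an `interval_table` from [build_intervals()].
#' @param lambda1,lambda2 positive rates (Yule, coalescent). The rate of
#'   a dropped term is ignored.
#' @param p1,p2 rate-scaling exponents.
#' @return the log-likelihood (scalar; `-Inf` if some interval has zero
#'   total rate).
#' @export
mixed_loglik <- function(intervals, lambda1, lambda2, p1, p2) {
  stopifnot(inherits(intervals, "interval_table"))
  if (length(intervals$x) == 0L) stop("empty interval table", call. = FALSE)
  if (intervals$has_div && (!is.finite(lambda1) || lambda1 <= 0)) {
    stop("lambda1 must be positive", call. = FALSE)
  }
  if (intervals$has_coal && (!is.finite(lambda2) || lambda2 <= 0)) {
    stop("lambda2 must be positive", call. = FALSE)
  }
  b <- interval_rates(intervals, lambda1, lambda2, p1, p2)
  loglik_from_rates(b, intervals$x)
}

#' Single-coalescent null log-likelihood
#'
#' The null model treats the entire tree as one coalescent cluster:
#' `b_i = lambda * (n_i (n_i - 1))^p` with `n_i` the lineage count in
#' interval `i`. For `p` fixed, the maximum-likelihood rate has the
#' closed form `lambda_hat = m / sum_i c_i x_i` with
#' `c_i = (n_i (n_i - 1))^p` and `m` the number of intervals.
#'
#' @param intervals an `interval_table` built from a single-cluster
#'   (all-coalescent) classification.
#' @param lambda positive coalescent rate.
#' @param p rate-scaling exponent.
#' @return the log-likelihood.
#' @export
null_loglik <- function(intervals, lambda, p) {
  stopifnot(inherits(intervals, "interval_table"))
  if (!is.finite(lambda) || lambda <= 0) {
    stop("lambda must be positive", call. = FALSE)
  }
  if (intervals$has_div || ncol(intervals$csq) != 1L) {
    stop("null model requires a single all-coalescent cluster", call. = FALSE)
  }
  if (any(intervals$csq[, 1L] < 2)) {
    stop("degenerate interval with fewer than 2 lineages", call. = FALSE)
  }
  mixed_loglik(intervals, lambda1 = NA_real_, lambda2 = lambda,
               p1 = NA_real_, p2 = p)
}

#' Closed-form rate estimates at fixed exponents
#'
#' For a single-process likelihood (pure coalescent or pure Yule) the
#' exponential waiting-time MLE is `m / sum(c_i x_i)`. For the mixed
#' model the same per-process formula (events of each process over its
#' own weighted exposure) is exact only when the processes occupy
#' disjoint intervals; it is used as the optimizer's starting value.
#'
#' @param intervals an `interval_table`.
#' @param p1,p2 exponents at which to evaluate the weights.
#' @return named numeric: `lambda1`, `lambda2` (NA for absent process).
#' @export
closed_form_rates <- function(intervals, p1 = 1, p2 = 1) {
  iv <- intervals
  l1 <- l2 <- NA_real_
  if (iv$has_div) {
    expo <- sum(iv$n_div^p1 * iv$x)
    l1 <- max(iv$n_div_events, 1L) / expo
  }
  if (iv$has_coal) {
    z <- iv$csq
    pos <- z > 0
    zp <- z
    zp[pos] <- z[pos]^p2
    expo <- sum(rowSums(zp) * iv$x)
    l2 <- max(iv$n_coal_events, 1L) / expo
  }
  c(lambda1 = l1, lambda2 = l2)
}

## Negative log-likelihood and gradient in the working parameterization
## theta = (log lambda1, p1, log lambda2, p2), restricted to the active
## processes. Returns functions closed over the interval table.
make_objective <- function(iv) {
  a <- if (iv$has_div) iv$n_div else NULL
  la <- if (iv$has_div) log(iv$n_div) else NULL
  if (iv$has_coal) {
    z <- iv$csq
    pos <- z > 0
    lz <- z
    lz[pos] <- log(z[pos])
  }
  x <- iv$x

  unpack <- function(theta, fix) {
    i <- 0L
    out <- numeric(4)  # lambda1, p1, lambda2, p2
    for (k in 1:4) {
      if (is.na(fix[k])) {
        i <- i + 1L
        out[k] <- if (k %% 2L == 1L) exp(theta[i]) else theta[i]
      } else out[k] <- fix[k]
    }
    out
  }

  list(
    value = function(theta, fix) {
      pr <- unpack(theta, fix)
      b <- numeric(length(x))
      if (iv$has_div) b <- b + pr[1] * a^pr[2]
      if (iv$has_coal) {
        zp <- iv$csq
        zp[pos] <- zp[pos]^pr[4]
        b <- b + pr[3] * rowSums(zp)
      }
      -loglik_from_rates(b, x)
    },
    grad = function(theta, fix) {
      pr <- unpack(theta, fix)
      b <- numeric(length(x))
      if (iv$has_div) {
        ta <- pr[1] * a^pr[2]
        b <- b + ta
      }
      if (iv$has_coal) {
        zp <- iv$csq
        zp[pos] <- zp[pos]^pr[4]
        sc <- rowSums(zp)
        sc_l <- rowSums(zp * lz)
        b <- b + pr[3] * sc
      }
      w <- 1 / b - x             # d logL / d b_i
      g4 <- numeric(4)
      if (iv$has_div) {
        g4[1] <- sum(w * ta)     # wrt log lambda1
        g4[2] <- sum(w * ta * la)
      }
      if (iv$has_coal) {
        g4[3] <- sum(w * pr[3] * sc)   # wrt log lambda2
        g4[4] <- sum(w * pr[3] * sc_l)
      }
      -g4[is.na(fix)]
    }
  )
}

#' Maximize the mixed likelihood over rates and exponents
#'
#' Bounded quasi-Newton (`L-BFGS-B`) from three deterministic starts:
#' exponents at 0.5, 1 and 1.5, rates at the closed-form per-process
#' estimates evaluated at those exponents. Bounds are
#' `lambda in (1e-12, 1e12)` and `p in [-5, 5]`. Either exponent can be
#' held fixed (used by the analytic-MLE checks).
#'
#' @param intervals an `interval_table`.
#' @param p1_fixed,p2_fixed optional fixed exponent values.
#' @return list: `lambda1`, `p1`, `lambda2`, `p2` (NA for an absent
#'   process), `logLik`, `convergence` (0 = at least one start
#'   converged), `n_params`.
#' @export
optimize_rates <- function(intervals, p1_fixed = NULL, p2_fixed = NULL) {
  iv <- intervals
  obj <- make_objective(iv)

  ## fix vector in (lambda1, p1, lambda2, p2) order; NA = free
  fix <- rep(NA_real_, 4)
  if (!iv$has_div) fix[1:2] <- c(1, 1)       # inert placeholders
  if (!iv$has_coal) fix[3:4] <- c(1, 1)
  if (iv$has_div && !is.null(p1_fixed)) fix[2] <- p1_fixed
  if (iv$has_coal && !is.null(p2_fixed)) fix[4] <- p2_fixed

  free <- which(is.na(fix))
  lower <- c(log(1e-12), -5, log(1e-12), -5)[free]
  upper <- c(log(1e12), 5, log(1e12), 5)[free]

  starts <- lapply(c(0.5, 1, 1.5), function(p0) {
    p1s <- if (is.na(fix[2])) p0 else fix[2]
    p2s <- if (is.na(fix[4])) p0 else fix[4]
    cf <- closed_form_rates(iv, p1 = p1s, p2 = p2s)
    full <- c(log(max(cf["lambda1"], 1e-12, na.rm = TRUE)), p1s,
              log(max(cf["lambda2"], 1e-12, na.rm = TRUE)), p2s)
    pmin(pmax(full[free], lower), upper)
  })

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, fn = obj$value, gr = obj$grad, fix = fix,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("optimizer failed to produce a finite likelihood at every start",
         call. = FALSE)
  }

  theta <- rep(NA_real_, 4)
  theta[free] <- best$par
  pr <- ifelse(is.na(fix), theta, fix)
  out <- list(
    lambda1 = if (iv$has_div) exp(pr[1]) else NA_real_,
    p1      = if (iv$has_div) pr[2] else NA_real_,
    lambda2 = if (iv$has_coal) exp(pr[3]) else NA_real_,
    p2      = if (iv$has_coal) pr[4] else NA_real_,
    logLik  = -best$value,
    convergence = if (any_conv) 0L else 1L,
    n_params = length(free))
  out
}
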
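#' Likelihood-ratio test between nested fits
#'
#' `LR = 2 (logL_alt - logL_null)`, clipped at zero, referred to an
#' upper-tail chi-square with `df` degrees of freedom.
#'
#' @param logL_null,logL_alt log-likelihoods of the nested and the
#'   richer model; nesting (`logL_alt >= logL_null - 1e-6`) is checked.
#' @param df positive integer degrees of freedom.
#' @return list with `LR`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(logL_null, logL_alt, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1) {
    stop("df must be a positive integer", call. = FALSE)
  }
  if (logL_alt < logL_null - 1e-6) {
    stop("models are not nested: alternative log-likelihood ",
         logL_alt, " below null ", logL_null, call. = FALSE)
  }
  lr <- max(0, 2 * (logL_alt - logL_null))
  list(LR = lr, df = as.integer(df),
       p_value = stats::pchisq(lr, df = df, lower.tail = FALSE))
}

#' Threshold confidence set from a likelihood profile
#'
#' All candidate thresholds whose profile log-likelihood is within
#' `delta` of the maximum. The default `delta = 1.92` is half the 95%
#' chi-square(1) quantile, the usual profile-likelihood cutoff; on a
#' lineage-through-time display the retained candidates form the shaded
#' confidence band around the transition point.
#'
#' @param profile data.frame with columns `candidate` (threshold
#'   heights) and `logL`, or a numeric vector of log-likelihoods named
#'   by candidate.
#' @param delta log-likelihood drop defining the set.
#' @return numeric vector of candidate heights in the confidence set.
#' @export
threshold_confidence_set <- function(profile, delta = 1.92) {
  if (is.data.frame(profile)) {
    cand <- profile$candidate
    ll <- profile$logL
  } else {
    cand <- as.numeric(names(profile))
    ll <- as.numeric(profile)
  }
  if (!length(ll)) stop("empty profile", call. = FALSE)
  cand[ll >= max(ll) - delta]
}

## Candidate thresholds: midpoints between consecutive distinct
## branching times, one candidate above the root (the null
## classification) and one below the shallowest node (all singletons).
threshold_candidates <- function(tree) {
  bt <- branching_times(tree)
  ub <- unique(bt)
  mids <- if (length(ub) > 1L) (ub[-1L] + ub[-length(ub)]) / 2 else numeric(0)
  c(tree$root_height * (1 + 1e-6), mids, min(ub) / 2)
}

gmyc_fit_obj <- function(tree, method, classification, assignment, pars,
                         logLik_mixed, null_fit, lrt, threshold, conf_set,
                         profile, single_ref = NULL) {
  structure(list(
    tree = tree, method = method,
    classification = classification, assignment = assignment,
    lambda1 = pars$lambda1, lambda2 = pars$lambda2,
    p1 = pars$p1, p2 = pars$p2,
    threshold = threshold,
    logLik_mixed = logLik_mixed,
    logLik_null = null_fit$logLik,
    null_lambda = null_fit$lambda2, null_p = null_fit$p2,
    LR = lrt$LR, df = lrt$df, p_value = lrt$p_value,
    n_species = assignment$n_entities,
    n_clusters = assignment$n_clusters,
    n_singletons = assignment$n_singletons,
    conf_set = conf_set, profile = profile,
    single_ref = single_ref), class = "gmyc_fit")
}

#' Fit the single-threshold GMYC model
#'
#' Profiles the mixed Yule-coalescent likelihood over the candidate
#' threshold set (midpoints between consecutive branching times, plus
#' the all-coalescent and all-singleton extremes), maximizing over
#' `(lambda1, p1, lambda2, p2)` at each candidate, and compares the best
#' mixed fit with the single-coalescent null by a chi-square
#' likelihood-ratio test. Because the classification, not the continuous
#' threshold, determines the likelihood, the reported threshold `T` is
#' the height of the youngest diversification node of the winning
#' classification -- the genetic distance from the branch tips at which
#' branching switches from speciation to coalescence. Profile ties are
#' broken toward fewer entities (conservative lumping).
#'
#' @param tree an [ultrametric_tree()] with at least 3 tips.
#' @param df degrees of freedom of the mixed-vs-null test (default 3,
#'   the parameter-count difference).
#' @param delta profile drop for the threshold confidence set
#'   (default 1.92).
#' @return a `gmyc_fit` with parameters, threshold, log-likelihoods, LR
#'   test, entity assignment, confidence set and the full profile
#'   (`candidate`, `logL`, `n_entities`, `n_clusters`, `n_singletons`).
#' @examples
#' tr <- simulate_mixed_tree(k = 4, lambda1 = 1, n_j = 5, lambda2 = 200,
#'                           seed = 1)$tree
#' fit <- fit_single_threshold(tr)
#' fit$n_species
#' @export
fit_single_threshold <- function(tree, df = 3L, delta = 1.92) {
  stopifnot(inherits(tree, "ultrametric_tree"))
  if (tree$n_tips < 3L) stop("need at least 3 tips", call. = FALSE)

  cands <- threshold_candidates(tree)
  fits <- vector("list", length(cands))
  prof <- data.frame(candidate = cands, logL = NA_real_,
                     n_entities = NA_integer_, n_clusters = NA_integer_,
                     n_singletons = NA_integer_)
  cls_list <- vector("list", length(cands))
  asg_list <- vector("list", length(cands))
  n_fail <- 0L
  for (i in seq_along(cands)) {
    cls <- classify_nodes(tree, cands[i])
    iv <- build_intervals(cls)
    ft <- tryCatch(optimize_rates(iv), error = function(e) NULL)
    if (is.null(ft)) { n_fail <- n_fail + 1L; next }
    asg <- extract_entities(cls)
    fits[[i]] <- ft
    cls_list[[i]] <- cls
    asg_list[[i]] <- asg
    prof$logL[i] <- ft$logLik
    prof$n_entities[i] <- asg$n_entities
    prof$n_clusters[i] <- asg$n_clusters
    prof$n_singletons[i] <- asg$n_singletons
  }
  ok <- which(!is.na(prof$logL))
  if (!length(ok)) {
    stop("optimizer failed at every candidate threshold (",
         n_fail, " candidates)", call. = FALSE)
  }

  ## null fit = the above-root candidate (single coalescent cluster)
  i_null <- 1L
  if (is.na(prof$logL[i_null])) {
    stop("null-model optimization failed", call. = FALSE)
  }
  null_fit <- fits[[i_null]]

  best_ll <- max(prof$logL[ok])
  tie_tol <- 1e-9 * max(1, abs(best_ll))
  tied <- ok[prof$logL[ok] >= best_ll - tie_tol]
  i_best <- tied[which.min(prof$n_entities[tied])]

  cls <- cls_list[[i_best]]
  asg <- asg_list[[i_best]]
  pars <- fits[[i_best]]
  div_heights <- tree$heights[(tree$n_tips + 1L):(2L * tree$n_tips - 1L)][!cls$coal]
  threshold <- if (length(div_heights)) min(div_heights) else NA_real_

  lrt <- likelihood_ratio_test(null_fit$logLik, pars$logLik, df = df)
  conf <- threshold_confidence_set(prof[ok, c("candidate", "logL")], delta)

  gmyc_fit_obj(tree, "single", cls, asg, pars,
               logLik_mixed = pars$logLik, null_fit = null_fit, lrt = lrt,
               threshold = threshold, conf_set = conf, profile = prof)
}

## neighbor classifications for the hill climb: split a cluster at its
## root, or merge a diversification node whose internal children are all
## coalescent (its child lineages are single entities)
neighbor_classifications <- function(cls) {
  tree <- cls$tree
  n <- tree$n_tips
  coal <- cls$coal
  kids <- child_list(tree$phy)
  internal <- (n + 1L):(2L * n - 1L)
  out <- list()
  for (nd in internal) {
    key <- as.character(nd)
    if (coal[[key]]) {
      ## split only at maximal coalescent roots (others violate closure)
      parent_ids <- tree$phy$edge[tree$phy$edge[, 2L] == nd, 1L]
      is_max <- nd == n + 1L ||
        (length(parent_ids) && !coal[[as.character(parent_ids[1L])]])
      if (is_max) {
        cc <- coal
        cc[key] <- FALSE
        out[[length(out) + 1L]] <- node_classification(tree, unname(cc))
      }
    } else {
      k_int <- kids[[nd]][kids[[nd]] > n]
      if (!length(k_int) || all(coal[as.character(k_int)])) {
        cc <- coal
        cc[key] <- TRUE
        out[[length(out) + 1L]] <- node_classification(tree, unname(cc))
      }
    }
  }
  out
}

#' Fit the multiple-threshold GMYC model
#'
#' Starting from a converged single-threshold fit, hill-climbs over
#' node classifications: each step either splits one cluster at its
#' root into its two child entities (the boundary moves one node toward
#' the terminals) or merges the entities under one diversification node
#' into a single cluster (one node toward the base), re-optimizing all
#' rates for each neighbor and accepting the best strict improvement
#' until a local maximum is reached. Lineages thereby acquire their own
#' transition depths instead of one shared threshold. The result is
#' compared with the single-threshold fit by a likelihood-ratio test;
#' no standard degrees of freedom exist for this comparison, so the
#' default counts one extra threshold per change in entity count
#' (`df = max(1, |N_multi - N_single|)`) and is user-overridable.
#'
#' @param tree an [ultrametric_tree()].
#' @param start a single-threshold `gmyc_fit` (computed when missing).
#' @param df degrees of freedom for the multiple-vs-single test;
#'   `NULL` = default above.
#' @param max_iter safety bound on hill-climbing steps.
#' @return a `gmyc_fit` (`method = "multiple"`); its `LR`/`p_value`
#'   refer to the multiple-vs-single comparison and `single_ref` holds
#'   the starting fit.
#' @export
fit_multiple_threshold <- function(tree, start = NULL, df = NULL,
                                   max_iter = 200L) {
  stopifnot(inherits(tree, "ultrametric_tree"))
  if (is.null(start)) start <- fit_single_threshold(tree)
  stopifnot(inherits(start, "gmyc_fit"), start$method == "single")

  cur_cls <- start$classification
  cur_fit <- optimize_rates(build_intervals(cur_cls))
  seen <- new.env(parent = emptyenv())
  sig <- function(cls) paste(as.integer(cls$coal), collapse = "")
  assign(sig(cur_cls), TRUE, envir = seen)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      warning("hill climb stopped at max_iter without a local maximum")
      break
    }
    nbrs <- neighbor_classifications(cur_cls)
    best_nb <- NULL
    best_ll <- cur_fit$logLik + 1e-9 * max(1, abs(cur_fit$logLik))
    for (nb in nbrs) {
      ft <- tryCatch(optimize_rates(build_intervals(nb)),
                     error = function(e) NULL)
      if (is.null(ft)) next
      if (ft$logLik > best_ll) {
        best_ll <- ft$logLik
        best_nb <- list(cls = nb, fit = ft)
      }
    }
    if (is.null(best_nb)) break
    s <- sig(best_nb$cls)
    if (!is.null(seen[[s]])) {
      warning("cycle detected in hill climb; terminating")
      break
    }
    assign(s, TRUE, envir = seen)
    cur_cls <- best_nb$cls
    cur_fit <- best_nb$fit
  }

  asg <- extract_entities(cur_cls)
  if (is.null(df)) df <- max(1L, abs(asg$n_entities - start$n_species))
  lrt <- likelihood_ratio_test(start$logLik_mixed, cur_fit$logLik, df = df)

  n <- tree$n_tips
  div_heights <- tree$heights[(n + 1L):(2L * n - 1L)][!cur_cls$coal]
  threshold <- if (length(div_heights)) min(div_heights) else NA_real_

  null_fit <- list(logLik = start$logLik_null, lambda2 = start$null_lambda,
                   p2 = start$null_p)
  gmyc_fit_obj(tree, "multiple", cur_cls, asg, cur_fit,
               logLik_mixed = cur_fit$logLik, null_fit = null_fit, lrt = lrt,
               threshold = threshold, conf_set = start$conf_set,
               profile = start$profile, single_ref = start)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf("GMYC fit (%s-threshold)\n", x$method))
  cat(sprintf("  entities: %d (%d clusters + %d singletons)\n",
              x$n_species, x$n_clusters, x$n_singletons))
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold T: %.6g (height from tips)\n", x$threshold))
  }
  cat(sprintf("  logL mixed: %.4f   logL null: %.4f\n",
              x$logLik_mixed, x$logLik_null))
  ref <- if (x$method == "single") "null" else "single-threshold"
  cat(sprintf("  LR vs %s: %.3f (df = %d, p = %.4g)\n",
              ref, x$LR, x$df, x$p_value))
  invisible(x)
}

#' @export
summary.gmyc_fit <- function(object, ...) {
  data.frame(
    method = object$method,
    lambda1 = object$lambda1, p1 = object$p1,
    lambda2 = object$lambda2, p2 = object$p2,
    T = object$threshold,
    logL_null = object$logLik_null, logL_mixed = object$logLik_mixed,
    LR = object$LR, df = object$df, p_value = object$p_value,
    N = object$n_species, clusters = object$n_clusters,
    singletons = object$n_singletons)
}
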
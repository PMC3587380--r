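#' Edge recovery metrics
#'
#' A predicted regulation (target i, regulator j, condition c) is a true
#' positive if the corresponding true network of condition c contains it,
#' otherwise a false positive; counts are pooled over both conditions and
#' include autoloops.  Precision is TP / (TP + FP), reported as NA when no
#' edge is predicted.
#'
#' @param est,truth Lists of two [network_model()]s (or a \code{"var2_fit"}
#'   for \code{est}).
#' @return Named list: \code{tp}, \code{fp}, \code{precision}.
#' @export
edge_metrics <- function(est, truth) {
  est <- as_network_pair(est)
  check_same_shape(est, truth)
  tp <- 0L; fp <- 0L
  for (c in 1:2) {
    pred <- est[[c]]$edges == 1L
    tru <- truth[[c]]$edges == 1L
    tp <- tp + sum(pred & tru)
    fp <- fp + sum(pred & !tru)
  }
  list(tp = tp, fp = fp, precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
}

#' Change detection metrics
#'
#' An estimated change is an (off-diagonal) edge present in exactly one of
#' the two estimated networks.  It is a true positive only if the true
#' networks contain that edge in exactly the same single condition;
#' everything else — including an edge that is common in truth but
#' estimated in only one condition — counts as a false positive.
#' Autoloops are excluded: they are common by construction in the
#' benchmark, so an autoloop can never be a true change.
#'
#' @inheritParams edge_metrics
#' @return Named list: \code{tp}, \code{fp}, \code{precision}.
#' @export
change_metrics <- function(est, truth) {
  est <- as_network_pair(est)
  check_same_shape(est, truth)
  p <- nrow(est[[1]]$edges)
  offd <- diag(p) == 0
  e1 <- est[[1]]$edges == 1L; e2 <- est[[2]]$edges == 1L
  t1 <- truth[[1]]$edges == 1L; t2 <- truth[[2]]$edges == 1L
  tp <- sum(offd & e1 & !e2 & t1 & !t2) + sum(offd & e2 & !e1 & t2 & !t1)
  pred_changes <- sum(offd & xor(e1, e2))
  fp <- pred_changes - tp
  list(tp = tp, fp = fp,
       precision = if (pred_changes == 0) NA_real_ else tp / pred_changes)
}

as_network_pair <- function(x) {
  if (inherits(x, "var2_fit")) return(x$networks)
  if (is.list(x) && length(x) == 2 &&
      all(vapply(x, inherits, logical(1), "network_model"))) return(x)
  stop("expected a var2_fit or a list of two network_model objects")
}

check_same_shape <- function(est, truth) {
  truth <- as_network_pair(truth)
  dims <- vapply(c(est, truth), function(n) nrow(n$edges), integer(1))
  if (length(unique(dims)) != 1) stop("estimated and true networks differ in size")
  invisible(TRUE)
}

#' Run the Monte-Carlo benchmark
#'
#' For each replicate: generate the paired networks and both conditions'
#' series, fit the joint model by the requested method, and score edge
#' recovery and change detection against the truth.  Per-replicate counts
#' are integers; the summary row holds their means (which is why published
#' benchmark tables show fractional TP/FP).
#'
#' @param spec A [benchmark_spec()].
#' @param method \code{"anneal"} or \code{"em"}.
#' @param hyper,sched,control Passed to the fitter.
#' @param alpha0_grid Optional grid for per-replicate [select_alpha0()]
#'   (run with \code{cv_thin}-fold fold thinning); \code{NULL} keeps
#'   \code{hyper$alpha0} fixed.
#' @param cv_thin Fold thinning for the optional alpha0 selection.
#' @return List with \code{replicates} (one row per replicate) and
#'   \code{summary} (means), both data frames with edge and change columns.
#' @export
run_benchmark <- function(spec, method = c("anneal", "em"),
                          hyper = hyper_params(), sched = anneal_schedule(),
                          control = fit_control(), alpha0_grid = NULL,
                          cv_thin = 5L) {
  method <- match.arg(method)
  rows <- vector("list", spec$n_replicates)
  failures <- 0L
  for (r in seq_len(spec$n_replicates)) {
    sim <- simulate_conditions(spec, r)
    hy <- hyper
    if (!is.null(alpha0_grid)) {
      sel <- select_alpha0(sim$data, alpha0_grid, hyper = hy, sched = sched,
                           control = control, thin = cv_thin)
      hy$alpha0 <- sel$alpha0
    }
    fit <- tryCatch(
      if (method == "anneal") anneal_fit(sim$data, hy, sched, control)
      else em_fit(sim$data, hy, sched, control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(fit)))
      failures <- failures + 1L
      next
    }
    em_ <- edge_metrics(fit, sim$truth)
    cm_ <- change_metrics(fit, sim$truth)
    rows[[r]] <- data.frame(replicate = r, alpha0 = hy$alpha0,
                            edge_tp = em_$tp, edge_fp = em_$fp,
                            edge_precision = em_$precision,
                            change_tp = cm_$tp, change_fp = cm_$fp,
                            change_precision = cm_$precision)
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps)) stop("all replicates failed")
  summary <- data.frame(method = method, n_replicates = nrow(reps),
                        t(colMeans(reps[, -1, drop = FALSE], na.rm = TRUE)))
  list(replicates = reps, summary = summary, failures = failures)
}

#' Write benchmark results as TSV and JSON
#'
#' @param bench Result of [run_benchmark()].
#' @param tsv,json Output paths (either may be NULL to skip).
#' @export
write_benchmark <- function(bench, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(bench$replicates, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(summary = bench$summary,
                              replicates = bench$replicates),
                         json, dataframe = "rows", digits = NA)
  invisible(bench)
}
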
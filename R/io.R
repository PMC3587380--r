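#' Read an expression matrix with physical time stamps
#'
#' Reads a tab-separated file whose rows are genes and whose column headers
#' carry the physical observation times (e.g. hours).  Each time is mapped
#' to the latent grid as \code{round(time / interval) + 1}; the file's
#' sampling therefore need not be equally spaced.  Two observations mapping
#' to the same grid point is an error (choose a finer interval).
#'
#' @param path TSV file; first column gene identifiers, remaining column
#'   names numeric times (a leading non-numeric prefix such as \code{"t"} or
#'   \code{"X"} is tolerated).
#' @param interval Physical time per grid step (e.g. 3 for a 3-hour grid).
#' @param condition Condition label for the returned series.
#' @return An [observed_series()].
#' @examples
#' \dontrun{
#' # a 14-point series sampled at {0, 6, 9, ..., 48} h on a 3-hour grid
#' read_expression("normal.tsv", interval = 3)
#' }
#' @export
read_expression <- function(path, interval = 1, condition = 1L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values")
  times <- suppressWarnings(as.numeric(gsub("^[^0-9.+-]*", "", colnames(vals))))
  if (any(is.na(times))) stop("column names must carry numeric time stamps")
  if (any(diff(times) <= 0)) stop("time stamps must be strictly increasing")
  idx <- as.integer(round(times / interval)) + 1L
  if (anyDuplicated(idx))
    stop("two observations map to the same grid point; use a finer interval")
  rownames(vals) <- genes
  observed_series(vals, time_grid(max(idx), idx, interval), condition)
}

#' Write an observed series as TSV
#'
#' Inverse of [read_expression()]: column headers are the physical times
#' \code{(observed - 1) * interval}.  Values are written with full
#' precision so a write/read round trip is bit exact.
#'
#' @param series An [observed_series()].
#' @param path Output file.
#' @export
write_expression <- function(series, path) {
  times <- (series$grid$observed - 1) * series$grid$interval
  df <- data.frame(gene = rownames(series$values),
                   matrix(sprintf("%.17g", series$values),
                          nrow(series$values)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", format(times, trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a true or simulated network pair as an edge list
#'
#' @param g1,g2 Condition [network_model()]s.
#' @param path Output TSV: columns source, target, coefficient, condition
#'   (\code{common}, \code{1} or \code{2}).
#' @param genes Gene names (default \code{g1..gp}, matching
#'   [write_networks()]).
#' @export
write_network_pair <- function(g1, g2, path,
                               genes = paste0("g", seq_len(n_genes(g1)))) {
  rows <- network_pair_table(g1, g2)
  rows$source <- genes[rows$source]
  rows$target <- genes[rows$target]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

network_pair_table <- function(g1, g2, e1 = NULL, e2 = NULL) {
  p <- n_genes(g1)
  any_edge <- which(g1$edges == 1L | g2$edges == 1L, arr.ind = TRUE)
  if (nrow(any_edge) == 0)
    return(data.frame(source = integer(0), target = integer(0),
                      coefficient = numeric(0), condition = character(0),
                      e1 = numeric(0), e2 = numeric(0)))
  i <- any_edge[, 1]; j <- any_edge[, 2]
  in1 <- g1$edges[any_edge] == 1L; in2 <- g2$edges[any_edge] == 1L
  cond <- ifelse(in1 & in2, "common", ifelse(in1, "1", "2"))
  coef <- ifelse(in1, g1$coeff[any_edge], g2$coeff[any_edge])
  out <- data.frame(source = j, target = i, coefficient = coef,
                    condition = cond)
  if (!is.null(e1)) { out$e1 <- e1[any_edge]; out$e2 <- e2[any_edge] }
  out[order(out$target, out$source), , drop = FALSE]
}

#' Write the estimated networks of a fit
#'
#' Emits (a) one edge-list TSV per condition with posterior edge
#' probabilities and coefficients, (b) a combined list labelling every edge
#' \code{common} / \code{1} / \code{2}, and (c) a Graphviz DOT file using
#' the usual colouring: shared regulations black, condition-1-only red,
#' condition-2-only green.
#'
#' @param fit A \code{"var2_fit"}.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @param genes Optional gene names (default \code{g1..gp}).
#' @return Invisibly, the paths written.
#' @export
write_networks <- function(fit, dir, prefix = "network", genes = NULL) {
  stopifnot(inherits(fit, "var2_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- fit$p
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  paths <- character(0)
  for (c in 1:2) {
    net <- fit$networks[[c]]
    e <- if (c == 1) fit$edges$e1 else fit$edges$e2
    idx <- which(net$edges == 1L, arr.ind = TRUE)
    df <- data.frame(source = genes[idx[, 2]], target = genes[idx[, 1]],
                     coefficient = net$coeff[idx], posterior = e[idx])
    f <- file.path(dir, sprintf("%s_condition%d.tsv", prefix, c))
    utils::write.table(df[order(df$target, df$source), , drop = FALSE],
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  comb <- network_pair_table(fit$networks[[1]], fit$networks[[2]],
                             fit$edges$e1, fit$edges$e2)
  comb$source <- genes[comb$source]; comb$target <- genes[comb$target]
  f <- file.path(dir, paste0(prefix, "_combined.tsv"))
  utils::write.table(comb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  # DOT rendering with the three-colour convention
  dot <- file.path(dir, paste0(prefix, ".dot"))
  col <- c(common = "black", `1` = "red", `2` = "green")
  lines <- c("digraph regulation {",
             if (nrow(comb))
               sprintf("  \"%s\" -> \"%s\" [color=%s];",
                       comb$source, comb$target, col[comb$condition]),
             "}")
  writeLines(lines, dot)
  paths <- c(paths, dot)
  invisible(paths)
}

#' Two-stage gene screening for real-data analysis
#'
#' Stage 1 ranks genes by the coefficient of variation of their pooled
#' expression across both conditions and keeps the top \code{n_first}.
#' Stage 2 ranks the survivors by how much their expression profile differs
#' between the conditions and keeps the top \code{n_final}.  The default
#' between-condition score is the mean absolute difference of time-matched
#' profiles; \code{"max_fold"} uses the largest absolute log fold change
#' instead.  Ties (e.g. identical conditions, where every stage-2 score is
#' zero) fall back to the stage-1 order.
#'
#' @param x1,x2 Expression matrices (genes x time), same genes and
#'   time-matched columns.
#' @param n_first,n_final Stage sizes (defaults 500 and 100).
#' @param stage2 Divergence score: \code{"mean_abs_diff"} (default) or
#'   \code{"max_fold"}.
#' @return Integer indices of the selected genes, in ranked order.
#' @export
cv_screen_genes <- function(x1, x2, n_first = 500L, n_final = 100L,
                            stage2 = c("mean_abs_diff", "max_fold")) {
  stage2 <- match.arg(stage2)
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) != nrow(x2)) stop("both conditions must share the gene set")
  if (ncol(x1) != ncol(x2))
    stop("stage-2 screening needs time-matched columns")
  if (n_final > n_first) stop("'n_final' cannot exceed 'n_first'")
  pooled <- cbind(x1, x2)
  m <- rowMeans(pooled)
  s <- apply(pooled, 1, stats::sd)
  cv <- ifelse(s == 0, 0, s / abs(m))
  cv[!is.finite(cv)] <- Inf    # zero mean, non-constant: maximal variation
  stage1 <- order(cv, decreasing = TRUE)[seq_len(min(n_first, nrow(x1)))]
  score <- switch(stage2,
    mean_abs_diff = rowMeans(abs(x1[stage1, , drop = FALSE] -
                                   x2[stage1, , drop = FALSE])),
    max_fold = apply(abs(log2(abs(x1[stage1, , drop = FALSE]) + 1e-9) -
                           log2(abs(x2[stage1, , drop = FALSE]) + 1e-9)),
                     1, max))
  ord <- order(-score, seq_along(stage1))   # stage-1 order breaks ties
  stage1[ord][seq_len(min(n_final, length(stage1)))]
}
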
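# Thermal-adaptation classification from amino-acid composition:
# pairwise Welch tests per residue across cold / mesophilic / thermophilic
# panels, two-stage Benjamini-Krieger-Yekutieli FDR at Q, discriminant-axis
# selection, group centroids and nearest-centroid classification.

#' Welch two-sample t test with degenerate-case conventions
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Two degenerate cases arise with constant
#' composition samples and are resolved by convention: both samples constant
#' and equal gives p = 1 (no evidence of difference); both constant but
#' unequal gives p = 0 with `degenerate = TRUE` (infinite t).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List: `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p = 0.0214
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2")
  if (var(a) + var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t_stat = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p_value = if (same) 1 else 0,
                degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), degenerate = FALSE)
}

#' Two-stage Benjamini-Krieger-Yekutieli step-up procedure
#'
#' Adaptive linear step-up FDR control at level `q`. Stage 1 runs
#' Benjamini-Hochberg at q' = q / (1 + q) and counts r1 rejections; if
#' r1 = 0 nothing is rejected, if r1 = m everything is; otherwise the
#' number of true nulls is estimated as m0 = m - r1 and stage 2 re-runs
#' the step-up at level q' * m / m0.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level as a fraction (default 0.01, i.e. Q = 1%).
#' @return Logical rejection flags in input order.
#' @export
#' @examples
#' bky_two_stage(c(1e-4, 2e-4, 0.5, 0.8, 0.9), q = 0.01)
bky_two_stage <- function(p_values, q = 0.01) {
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  if (m == 0) return(logical(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  q1 <- q / (1 + q)
  bh <- function(lvl) p.adjust(p_values, method = "BH") <= lvl
  stage1 <- bh(q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  m0 <- m - r1
  bh(q1 * m / m0)
}

#' Pairwise per-residue group comparisons with joint FDR
#'
#' For each of the 20 residues and each unordered pair of groups, a Welch
#' test on the composition percentages; the two-stage step-up correction is
#' then applied jointly across all residue-by-pair p-values (60 for three
#' groups), as the study-wide Q is stated once for the whole analysis.
#'
#' @param groups Named list of composition matrices (one per group, rows =
#'   proteins, 20 residue columns; see [composition_matrix()]). Three
#'   groups expected, each with n >= 2.
#' @param q FDR level (default 0.01).
#' @return Data frame with one row per residue-by-pair test: `residue`,
#'   `group1`, `group2`, `t_stat`, `df`, `p_value`, `degenerate`,
#'   `rejected`.
#' @export
compare_groups <- function(groups, q = 0.01) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list of composition matrices")
  if (length(groups) < 2) stop("need at least two groups")
  groups <- lapply(groups, as.matrix)
  ns <- vapply(groups, nrow, integer(1))
  if (any(ns < 2))
    stop("group(s) with fewer than 2 proteins: ",
         paste(names(groups)[ns < 2], collapse = ", "))
  pairs <- combn(names(groups), 2)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    for (res in AA20) {
      wt <- welch_t(groups[[g1]][, res], groups[[g2]][, res])
      rows[[length(rows) + 1L]] <- data.frame(
        residue = res, group1 = g1, group2 = g2,
        t_stat = wt$t_stat, df = wt$df, p_value = wt$p_value,
        degenerate = wt$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rejected <- bky_two_stage(out$p_value, q = q)
  out
}

#' Select discriminant residues from test results
#'
#' Residues with at least one rejected pair, ordered by their smallest
#' p-value, capped for 3D plotting.
#'
#' @param results Data frame from [compare_groups()].
#' @param cap Maximum number of axes (default 3; `Inf` for no cap).
#' @return Character vector of residues in ascending-p order.
#' @export
select_axes <- function(results, cap = 3) {
  rej <- results[results$rejected, , drop = FALSE]
  if (!nrow(rej))
    stop("no residue passed the FDR threshold; use larger panels or a ",
         "higher q")
  minp <- tapply(rej$p_value, rej$residue, min)
  axes <- names(sort(minp))
  head(axes, cap)
}

#' Fit a thermal-adaptation model
#'
#' Runs the full procedure on labelled composition panels: per-group
#' summaries, pairwise Welch tests with two-stage FDR at `q`, discriminant
#' axis selection, and per-group centroids (mean composition on the axis
#' residues).
#'
#' @param groups Named list of composition matrices (see
#'   [compare_groups()]); conventional names are `cold`, `mesophilic`,
#'   `thermophilic`.
#' @param q FDR level (default 0.01).
#' @param axis_cap Maximum number of axes (default 3).
#' @param axes Optional pre-chosen axis residues; when supplied the testing
#'   and selection stages are skipped (useful for single-protein groups or
#'   for reusing published axes).
#' @return Object of class `thermal_model`: `summaries`, `tests`, `axes`,
#'   `centroids` (groups x axes matrix, %), `groups` (the input panels),
#'   `config`.
#' @export
fit_thermal_model <- function(groups, q = 0.01, axis_cap = 3, axes = NULL) {
  groups <- lapply(groups, as.matrix)
  empty <- vapply(groups, nrow, integer(1)) == 0
  if (any(empty)) stop("empty group(s): ",
                       paste(names(groups)[empty], collapse = ", "))
  tests <- NULL
  if (is.null(axes)) {
    tests <- compare_groups(groups, q = q)
    axes <- select_axes(tests, cap = axis_cap)
  } else {
    if (!all(axes %in% AA20)) stop("axes must be one-letter residue codes")
  }
  centroids <- do.call(rbind, lapply(groups, function(g)
    colMeans(g[, axes, drop = FALSE])))
  dimnames(centroids) <- list(names(groups), axes)
  summaries <- if (all(vapply(groups, nrow, integer(1)) >= 2))
    lapply(names(groups), function(g) summarize_group(groups[[g]], g))
  structure(list(summaries = summaries,
                 tests = tests, axes = axes, centroids = centroids,
                 groups = groups,
                 config = list(q = q, axis_cap = axis_cap,
                               test_variant = "welch")),
            class = "thermal_model")
}

#' @export
print.thermal_model <- function(x, ...) {
  cat("thermal_model: axes", paste(x$axes, collapse = ", "),
      "| q =", x$config$q, "\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' Classify a query protein against a fitted thermal model
#'
#' Euclidean distance in axis space to each group centroid; the label of
#' the nearest centroid is reported, with all labels reported on a tie.
#' Residues outside the model's axes never influence the result.
#'
#' @param query A `composition_vector` (from [aa_composition()]) or named
#'   numeric vector covering the model's axes.
#' @param model A fitted [fit_thermal_model()] object.
#' @return List: `label` (character, length > 1 on ties), `distances`
#'   (named numeric, one per group).
#' @export
classify_thermal <- function(query, model) {
  if (!inherits(model, "thermal_model") || !length(model$axes))
    stop("model is not a fitted thermal_model")
  q <- as.numeric(query[model$axes])
  if (any(is.na(q))) stop("query lacks axis residue(s): ",
                          paste(model$axes[is.na(q)], collapse = ", "))
  d <- apply(model$centroids, 1, function(ce) sqrt(sum((q - ce)^2)))
  list(label = names(d)[d <= min(d) + 1e-9], distances = d)
}

#' Coordinate table for the 3D composition scatter plot
#'
#' One row per panel protein (and optional query) with its group label and
#' its percentage coordinate on each model axis — plottable as-is by any
#' 3D scatter tool.
#'
#' @param model A fitted [fit_thermal_model()] object (<= 3 axes).
#' @param queries Optional composition matrix of query proteins (rownames =
#'   ids); labelled `"query"`.
#' @param path Optional TSV output path.
#' @return Data frame: `id`, `group`, one column per axis.
#' @export
scatter_table <- function(model, queries = NULL, path = NULL) {
  if (length(model$axes) > 3)
    stop("more than 3 axes; refit with axis_cap <= 3 for plotting")
  one <- function(mat, lab) data.frame(
    id = rownames(mat), group = lab,
    as.data.frame(mat[, model$axes, drop = FALSE]),
    stringsAsFactors = FALSE, check.names = FALSE)
  out <- do.call(rbind, lapply(names(model$groups), function(g)
    one(model$groups[[g]], g)))
  if (!is.null(queries)) out <- rbind(out, one(as.matrix(queries), "query"))
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
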
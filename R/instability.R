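# Relative instability scoring: per-indicator min-max scaling of outcome
# indicator magnitudes across a family of fracture models, averaged into a
# single relative instability ratio per model.

#' Fracture wall-defect variant codes
#'
#' The eight model variants: the basic fracture line alone (`BASIC`) and the
#' seven cortical wall defects — medial (`M`), anteromedial (`AM`),
#' posteromedial (`PM`), lateral (`L`), anterolateral (`AL`), posterolateral
#' (`PL`), and the posterior coronal defect (`PML`, removing the PM and PL
#' walls plus the posterior bone between them).
#'
#' @return Character vector of the eight variant codes, in enum order.
#' @export
fracture_variants <- function() {
  c("BASIC", "M", "AM", "PM", "L", "AL", "PL", "PML")
}

#' Reference instability ordering of the eight variants
#'
#' Ordering of the eight wall-defect variants from most stable to most
#' unstable, as established for PFNA-fixed trochanteric fractures: the basic
#' fracture line is the most stable construct and the full medial wall defect
#' the least stable.
#'
#' @return Character vector of variant codes ordered from most stable (first)
#'   to most unstable (last).
#' @export
reference_instability_order <- function() {
  c("BASIC", "PL", "AL", "PM", "L", "PML", "AM", "M")
}

#' Min-max relative instability ratio of one indicator across models
#'
#' Places each model's indicator magnitude on a 0--100% scale between the
#' smallest (most stable, 0%) and largest (most unstable, 100%) value across
#' the model family. If all values are equal the indicator carries no
#' instability information and every model receives 0%.
#'
#' @param values Numeric vector of one indicator's magnitudes, one per model
#'   (all finite and non-negative; at least two models).
#' @return Numeric vector of ratios in percent, same length and names as
#'   `values`.
#' @examples
#' minmax_ratio(c(10, 20, 30))  # 0, 50, 100
#' @export
minmax_ratio <- function(values) {
  check_that(length(values) >= 2, "minmax_ratio() needs at least 2 models, got %d", length(values))
  check_that(all(is.finite(values)), "minmax_ratio() requires finite values")
  lo <- min(values)
  hi <- max(values)
  out <- if (hi == lo) rep(0, length(values)) else 100 * (values - lo) / (hi - lo)
  names(out) <- names(values)
  out
}

#' Aggregate per-indicator instability ratios into a mean ratio per model
#'
#' Applies [minmax_ratio()] to every indicator column and averages the
#' per-indicator ratios (unweighted) into one mean relative instability ratio
#' per model. Indicators with no spread across models (max equals min) are
#' dropped from the mean rather than diluting it with zeros.
#'
#' The pipeline's default indicator set is: nail and blade peak von Mises
#' stress, peak tensile and compressive principal strain magnitudes, head
#' vertex displacement, and the mean fracture-surface gap.
#'
#' @param table Numeric matrix or data frame, rows = models (rownames =
#'   variant codes), columns = indicator magnitudes (all finite, `>= 0`).
#' @return An object of class `instability_result`: list with
#'   `per_indicator_ratios` (models x indicators matrix, percent),
#'   `mean_ratio` (named vector, percent), `ranking` (model codes by
#'   descending mean ratio), `dropped_indicators`.
#' @export
aggregate_instability <- function(table) {
  m <- as.matrix(table)
  check_that(is.numeric(m), "indicator table must be numeric")
  check_that(nrow(m) >= 2, "indicator table needs >= 2 models")
  check_that(ncol(m) >= 1, "indicator table needs >= 1 indicator")
  check_that(all(is.finite(m)), "indicator table must be finite")
  check_that(all(m >= 0), "indicator table must hold magnitudes (>= 0); take abs() first")
  if (is.null(rownames(m))) rownames(m) <- paste0("model", seq_len(nrow(m)))
  ratios <- m
  degenerate <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios[, j] <- minmax_ratio(m[, j])
    degenerate[j] <- max(m[, j]) == min(m[, j])
  }
  keep <- !degenerate
  mean_ratio <- if (any(keep)) rowMeans(ratios[, keep, drop = FALSE]) else {
    stats::setNames(rep(0, nrow(m)), rownames(m))
  }
  ranking <- rank_order(mean_ratio)
  structure(
    list(
      per_indicator_ratios = ratios,
      mean_ratio = mean_ratio,
      ranking = ranking,
      dropped_indicators = colnames(m)[degenerate]
    ),
    class = "instability_result"
  )
}

# Descending order of mean ratios; ties broken by variant enum order when the
# names are variant codes, otherwise by current row order.
rank_order <- function(mean_ratio) {
  nm <- names(mean_ratio)
  tie_rank <- match(nm, fracture_variants())
  tie_rank[is.na(tie_rank)] <- seq_along(nm)[is.na(tie_rank)] + length(fracture_variants())
  nm[order(-mean_ratio, tie_rank)]
}

#' Rank models by mean instability ratio and compare to a reference ordering
#'
#' @param result An `instability_result` from [aggregate_instability()].
#' @param reference Character vector of model codes ordered from most stable
#'   to most unstable; defaults to [reference_instability_order()].
#' @return List with `ranking` (most unstable first), `exact_match` (logical:
#'   ranking equals the reference reversed), and `concordance` (fraction of
#'   model pairs ordered the same way as the reference; ties in the computed
#'   mean ratios count 1/2).
#' @export
rank_models <- function(result, reference = reference_instability_order()) {
  check_that(inherits(result, "instability_result"), "result must be an instability_result")
  mr <- result$mean_ratio
  common <- intersect(reference, names(mr))
  check_that(length(common) >= 2, "reference ordering shares fewer than 2 models with the result")
  ref_rank <- stats::setNames(match(common, reference), common)  # higher = more unstable
  n <- length(common)
  concord <- 0
  npairs <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- common[i]; b <- common[j]
      npairs <- npairs + 1L
      d_ref <- sign(ref_rank[a] - ref_rank[b])
      d_obs <- sign(mr[a] - mr[b])
      concord <- concord + if (d_obs == 0) 0.5 else as.numeric(d_obs == d_ref)
    }
  }
  ranking <- result$ranking[result$ranking %in% common]
  list(
    ranking = ranking,
    exact_match = identical(unname(ranking), rev(reference[reference %in% common])),
    concordance = concord / npairs
  )
}

#' @export
print.instability_result <- function(x, ...) {
  cat("Relative instability ratios (% of min-max range, mean over",
      ncol(x$per_indicator_ratios) - length(x$dropped_indicators), "indicators)\n")
  ord <- x$ranking
  df <- data.frame(model = ord, mean_ratio = round(x$mean_ratio[ord], 1))
  print(df, row.names = FALSE)
  if (length(x$dropped_indicators)) {
    cat("dropped (no spread):", paste(x$dropped_indicators, collapse = ", "), "\n")
  }
  invisible(x)
}
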
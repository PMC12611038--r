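# TOPSIS fruit quality index: multi-criteria closeness scoring over
# SFW / TSS / FF, min-max normalization, and percent-change utilities.

#' TOPSIS closeness scores for a decision matrix
#'
#' Scores each alternative (row) by the Technique for Order Preference by
#' Similarity to Ideal Solution: criterion columns are normalized
#' (Euclidean vector normalization by default), weighted, and each
#' alternative's Euclidean distances to the ideal (per-criterion best)
#' and anti-ideal (per-criterion worst) solutions are combined into the
#' closeness coefficient `C = D- / (D+ + D-)`, in `[0, 1]`.
#'
#' Weights are used as supplied; the closeness coefficient is invariant
#' to a common scaling of the weights, so they need not sum to 1.
#'
#' @param x Numeric matrix or data.frame, alternatives x criteria; all
#'   values finite and positive.
#' @param weights Numeric vector of non-negative criterion weights.
#' @param directions Character vector per criterion, `"benefit"`
#'   (higher is better, default) or `"cost"`.
#' @param normalization `"vector"` (default) or `"minmax"`.
#' @return A data.frame with columns `fqi` (closeness), `d_plus`,
#'   `d_minus` and `rank` (1 = best), one row per alternative.
#' @examples
#' q <- verification_quality()
#' s <- topsis_score(q[, c("SFW", "TSS", "FF")], fqi_weights())
#' head(s)
#' @export
topsis_score <- function(x, weights,
                         directions = rep("benefit", ncol(x)),
                         normalization = c("vector", "minmax")) {
  normalization <- match.arg(normalization)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("TOPSIS needs at least 2 alternatives")
  if (!all(is.finite(x)) || any(x <= 0))
    stop("criteria values must be finite and positive")
  if (length(weights) != ncol(x))
    stop("need one weight per criterion")
  if (any(weights < 0)) stop("weights must be non-negative")
  directions <- match.arg(directions, c("benefit", "cost"),
                          several.ok = TRUE)
  if (length(directions) != ncol(x))
    stop("need one direction per criterion")

  norms <- switch(normalization,
    vector = {
      s <- sqrt(colSums(x^2))
      if (any(s == 0)) stop("all-zero criterion column")
      sweep(x, 2, s, "/")
    },
    minmax = {
      rng <- apply(x, 2, range)
      span <- rng[2, ] - rng[1, ]
      if (any(span == 0)) stop("constant criterion column under minmax")
      sweep(sweep(x, 2, rng[1, ], "-"), 2, span, "/")
    })
  v <- sweep(norms, 2, weights, "*")

  ideal <- anti <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    if (directions[j] == "benefit") {
      ideal[j] <- max(v[, j]); anti[j] <- min(v[, j])
    } else {
      ideal[j] <- min(v[, j]); anti[j] <- max(v[, j])
    }
  }
  d_plus <- sqrt(rowSums(sweep(v, 2, ideal, "-")^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, anti, "-")^2))
  denom <- d_plus + d_minus
  fqi <- ifelse(denom == 0, 0.5, d_minus / denom)
  if (any(denom == 0))
    warning("identical alternatives: closeness set to 0.5")
  data.frame(fqi = fqi, d_plus = d_plus, d_minus = d_minus,
             rank = rank(-fqi, ties.method = "min"))
}

#' Min-max normalization of a score vector
#'
#' Rescales scores to `[0, 1]` via `(x - min) / (max - min)`, the
#' normalization used for the normalized fruit quality index.
#'
#' @param x Numeric vector with at least 2 values, not all equal.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' round(normalize_fqi(verification_quality()$FQI), 4)
#' @export
normalize_fqi <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("all values equal: normalization undefined")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Percent change relative to a reference
#'
#' `100 * (value / reference - 1)`; the reference must be positive.
#'
#' @param value,reference Numeric vectors (recycled).
#' @return Percent change(s).
#' @examples
#' percent_change(0.6003, 0.4123)  # 45.60
#' @export
percent_change <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (value / reference - 1)
}

#' Fruit quality index for replicated quality records
#'
#' Runs TOPSIS within analysis cohorts of a quality-record table and
#' attaches the closeness score (`fqi`), its per-cohort min-max
#' normalization (`fqi_norm`) and the within-cohort rank. By default each
#' year is one cohort (scores are comparable within a season); use
#' `cohort = "pooled"` to score all records together.
#'
#' @param quality data.frame with columns `SFW`, `TSS`, `FF` and, unless
#'   pooled, `year`.
#' @param weights Criterion weights, default [fqi_weights()].
#' @param cohort `"year"` (default) or `"pooled"`.
#' @param normalization Passed to [topsis_score()].
#' @return The input with `fqi`, `fqi_norm`, `rank` columns appended.
#' @export
fqi_scores <- function(quality, weights = fqi_weights(),
                       cohort = c("year", "pooled"),
                       normalization = "vector") {
  cohort <- match.arg(cohort)
  need <- c("SFW", "TSS", "FF")
  if (!all(need %in% names(quality)))
    stop("quality table must have columns SFW, TSS, FF")
  grp <- if (cohort == "year") {
    if (!"year" %in% names(quality))
      stop("cohort = \"year\" needs a year column")
    as.character(quality$year)
  } else rep("all", nrow(quality))
  quality$fqi <- NA_real_
  quality$fqi_norm <- NA_real_
  quality$rank <- NA_integer_
  for (g in unique(grp)) {
    i <- which(grp == g)
    s <- topsis_score(quality[i, need], weights,
                      normalization = normalization)
    quality$fqi[i] <- s$fqi
    quality$fqi_norm[i] <- normalize_fqi(s$fqi)
    quality$rank[i] <- s$rank
  }
  quality
}

#' Treatment-level summary of replicated FQI scores
#'
#' Mean and SD of per-replicate scores within treatment, the aggregation
#' used for trial report tables.
#'
#' @param scored Output of [fqi_scores()] with a `treatment` column.
#' @param trait Column to summarize (default `"fqi"`).
#' @return data.frame with `treatment`, `mean`, `sd`, `n`.
#' @export
summarize_by_treatment <- function(scored, trait = "fqi") {
  if (!all(c("treatment", trait) %in% names(scored)))
    stop("need columns treatment and ", trait)
  agg <- split(scored[[trait]], scored$treatment)
  out <- data.frame(
    treatment = names(agg),
    mean = vapply(agg, mean, numeric(1)),
    sd = vapply(agg, stats::sd, numeric(1)),
    n = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(as.integer(sub("^T", "", out$treatment)))
  out[ord, , drop = FALSE]
}
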
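# The L16(4^5) orthogonal fertilization design: treatment table, dose
# lookups and balance/orthogonality checks.

#' Build the L16(4^5) orthogonal fertilization design
#'
#' Returns the 16-treatment design for the five fertilizer factors
#' (N, P2O5, K2O, CaO, MgO), each at four levels, together with the
#' annual dose (kg/hm2) attached to each factor level. Level 1 is always
#' the zero dose; levels 2-4 are 1/2x, 1x and 3/2x the reference rate.
#' Doses are stored at full definition precision (e.g. 506.25, displayed
#' elsewhere as 506.3).
#'
#' @return An object of class `l16_design`: a list with
#'   \describe{
#'     \item{factors}{character(5), the factor names (oxide basis).}
#'     \item{doses}{4 x 5 numeric matrix of annual doses (kg/hm2),
#'       rows = levels, columns = factors.}
#'     \item{treatments}{data.frame with `treatment`, `label`, one
#'       level column per factor, and one `<factor>_dose` column per
#'       factor.}
#'   }
#' @examples
#' d <- build_design()
#' d$treatments[9, ]  # T9 = N3P1K3Ca4Mg2
#' @export
build_design <- function() {
  doses <- cbind(
    N    = c(0, 187.5, 375.0, 562.5),
    P2O5 = c(0, 70.5, 141.0, 211.5),
    K2O  = c(0, 168.8, 337.5, 506.25),
    CaO  = c(0, 168.8, 337.5, 506.25),
    MgO  = c(0, 70.5, 141.0, 211.5)
  )
  rownames(doses) <- paste0("L", 1:4)
  levels <- matrix(c(
    1, 1, 1, 1, 1,
    1, 2, 2, 2, 2,
    1, 3, 3, 3, 3,
    1, 4, 4, 4, 4,
    2, 1, 2, 3, 4,
    2, 2, 1, 4, 3,
    2, 3, 4, 1, 2,
    2, 4, 3, 2, 1,
    3, 1, 3, 4, 2,
    3, 2, 4, 3, 1,
    3, 3, 1, 2, 4,
    3, 4, 2, 1, 3,
    4, 1, 4, 2, 3,
    4, 2, 3, 1, 4,
    4, 3, 2, 4, 1,
    4, 4, 1, 3, 2
  ), ncol = 5, byrow = TRUE, dimnames = list(NULL, .factors))
  tr <- data.frame(treatment = paste0("T", 1:16),
                   label = apply(levels, 1, combination_label),
                   stringsAsFactors = FALSE)
  tr <- cbind(tr, as.data.frame(levels))
  for (f in .factors) tr[[paste0(f, "_dose")]] <- doses[levels[, f], f]
  structure(list(factors = .factors, doses = doses, treatments = tr),
            class = "l16_design")
}

#' @export
print.l16_design <- function(x, ...) {
  cat("L16(4^5) orthogonal fertilization design\n")
  cat("Factors:", paste(x$factors, collapse = ", "), "(annual kg/hm2)\n\n")
  print(x$treatments[, c("treatment", "label", x$factors)], row.names = FALSE)
  invisible(x)
}

#' Compose a combination label such as "N3P1K2Ca1Mg2"
#'
#' @param levels Integer vector of 5 levels in factor order
#'   (N, P2O5, K2O, CaO, MgO).
#' @return A single label string.
#' @export
combination_label <- function(levels) {
  stopifnot(length(levels) == 5, all(levels %in% 1:4))
  paste0(.factor_codes, levels, collapse = "")
}

#' Parse a combination label into factor levels
#'
#' @param label A label such as "N3P1K2Ca1Mg2".
#' @return Named integer vector of levels (names = factor names).
#' @export
parse_combination <- function(label) {
  m <- regmatches(label,
                  regexec("^N([1-4])P([1-4])K([1-4])Ca([1-4])Mg([1-4])$",
                          label))[[1]]
  if (length(m) != 6)
    stop("cannot parse combination label: ", label)
  out <- as.integer(m[-1])
  names(out) <- .factors
  out
}

#' Look up annual doses for a factor-level combination
#'
#' @param label A combination label such as "N3P1K2Ca1Mg2".
#' @param design An `l16_design`, by default [build_design()].
#' @return Named numeric vector of annual doses (kg/hm2) in factor order.
#' @examples
#' dose_lookup("N3P1K2Ca1Mg2")  # 375.0, 0, 168.8, 0, 70.5
#' @export
dose_lookup <- function(label, design = build_design()) {
  lv <- parse_combination(label)
  out <- vapply(design$factors,
                function(f) design$doses[lv[[f]], f], numeric(1))
  names(out) <- design$factors
  out
}

#' Check L16(4^5) balance and pairwise orthogonality
#'
#' Balance: every level of every factor occurs exactly four times.
#' Orthogonality: for every ordered factor pair, each of the 16 level
#' combinations occurs exactly once.
#'
#' @param design An `l16_design`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_design <- function(design = build_design()) {
  lv <- as.matrix(design$treatments[, design$factors])
  for (f in design$factors) {
    cnt <- tabulate(lv[, f], nbins = 4)
    if (!all(cnt == 4))
      stop("factor ", f, " is unbalanced: counts ",
           paste(cnt, collapse = "/"))
  }
  pairs <- utils::combn(design$factors, 2)
  for (k in seq_len(ncol(pairs))) {
    f1 <- pairs[1, k]; f2 <- pairs[2, k]
    combo <- table(lv[, f1], lv[, f2])
    if (!all(combo == 1))
      stop("factors ", f1, " and ", f2, " are not orthogonal")
  }
  invisible(TRUE)
}
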
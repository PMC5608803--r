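#' Pairwise Welch tests with Bonferroni adjustment
#'
#' All pairwise two-sample comparisons between groups (Welch's t test on
#' the group values), with the raw p values multiplied by the number of
#' pairs and capped at 1. Significance tiers follow the conventional
#' thresholds: adjusted p < 0.05 significant, < 0.01 highly significant.
#' Groups with fewer than two values are excluded with a warning. Pair
#' labels are ordered alphabetically within each pair and rows sorted, so
#' the result is invariant to the input order of the groups.
#'
#' @param groups Named list of numeric vectors, one per group (e.g. per
#'   measurement day).
#' @param alpha,alpha_high Significance thresholds on the adjusted p.
#' @return A data frame of class `comparison_result` with columns
#'   `group1`, `group2`, `n1`, `n2`, `raw_p`, `adj_p`, `tier` (factor:
#'   `none`, `p<0.05`, `p<0.01`) and attribute `n_comparisons`.
#' @examples
#' bonferroni_pairwise(list(d1 = rnorm(5), d7 = rnorm(5, 3)))
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05, alpha_high = 0.01) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  small <- vapply(groups, length, 1L) < 2L
  if (any(small)) {
    warning("excluding groups with fewer than 2 values: ",
            paste(names(groups)[small], collapse = ", "), call. = FALSE)
    groups <- groups[!small]
  }
  if (length(groups) < 2L)
    stop("need at least 2 groups with >= 2 values each", call. = FALSE)
  pairs <- utils::combn(sort(names(groups)), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    p <- stats::t.test(groups[[g1]], groups[[g2]])$p.value
    data.frame(group1 = g1, group2 = g2,
               n1 = length(groups[[g1]]), n2 = length(groups[[g2]]),
               raw_p = p, adj_p = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group1, out$group2), , drop = FALSE]
  rownames(out) <- NULL
  out$tier <- factor(
    ifelse(out$adj_p < alpha_high, "p<0.01",
           ifelse(out$adj_p < alpha, "p<0.05", "none")),
    levels = c("none", "p<0.05", "p<0.01"))
  attr(out, "n_comparisons") <- m
  class(out) <- c("comparison_result", class(out))
  out
}

#' Longitudinal comparison report for a fitted cohort
#'
#' Applies [bonferroni_pairwise()] separately to each kinetic parameter
#' across measurement days, using one value per animal and day (the
#' per-animal ROI estimate). Non-converged fits and missing values are
#' dropped; a parameter with no usable day pair is skipped and noted.
#'
#' @param fits Data frame with columns `animal`, `day`, the value columns,
#'   and optionally `converged` (rows with `converged == FALSE` are
#'   dropped).
#' @param value_cols Parameter columns to compare; default
#'   `c("ktrans", "ve")`.
#' @param alpha,alpha_high Tier thresholds, as in [bonferroni_pairwise()].
#' @return A list of class `cohort_report`: `comparisons` (named list of
#'   `comparison_result` tables), `notes` (character), `n_per_day` table.
#' @export
cohort_report <- function(fits, value_cols = c("ktrans", "ve"),
                          alpha = 0.05, alpha_high = 0.01) {
  stopifnot(is.data.frame(fits), all(c("day") %in% names(fits)))
  if ("converged" %in% names(fits)) fits <- fits[fits$converged %in% TRUE, ]
  notes <- character(0)
  comparisons <- list()
  for (col in value_cols) {
    if (!col %in% names(fits) || all(!is.finite(fits[[col]]))) {
      notes <- c(notes, sprintf("column '%s' empty or missing; excluded", col))
      next
    }
    groups <- split(fits[[col]], paste0("day", fits$day))
    # preserve numeric day order in the names used for pairing
    res <- tryCatch(
      withCallingHandlers(
        bonferroni_pairwise(groups, alpha = alpha, alpha_high = alpha_high),
        warning = function(w) {
          notes <<- c(notes, sprintf("%s: %s", col, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notes <<- c(notes, sprintf("%s: %s", col, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) comparisons[[col]] <- res
  }
  n_per_day <- as.data.frame(table(day = fits$day),
                             responseName = "n_values")
  structure(list(comparisons = comparisons, notes = notes,
                 n_per_day = n_per_day,
                 alpha = alpha, alpha_high = alpha_high),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Longitudinal cohort comparison report\n")
  for (nm in names(x$comparisons)) {
    tab <- x$comparisons[[nm]]
    sig <- tab[tab$tier != "none", , drop = FALSE]
    cat(sprintf("  %s: %d pairwise comparisons, %d significant\n",
                nm, nrow(tab), nrow(sig)))
    if (nrow(sig)) {
      for (i in seq_len(nrow(sig)))
        cat(sprintf("    %s vs %s: adj p = %.4g (%s)\n",
                    sig$group1[i], sig$group2[i], sig$adj_p[i],
                    as.character(sig$tier[i])))
    }
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write a cohort report as tidy CSV
#'
#' One row per parameter and day pair, columns `parameter`, `group1`,
#' `group2`, `n1`, `n2`, `raw_p`, `adj_p`, `tier`.
#'
#' @param report A `cohort_report`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_cohort_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  rows <- lapply(names(report$comparisons), function(nm) {
    tab <- as.data.frame(report$comparisons[[nm]])
    tab$parameter <- nm
    tab
  })
  out <- do.call(rbind, rows)
  out <- out[, c("parameter", setdiff(names(out), "parameter"))]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
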
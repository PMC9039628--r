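# Habitat selection after Neu et al.: compare the number of relocations
# observed in each habitat with the number expected from the habitat's areal
# availability inside the home range (chi-square goodness of fit), attach
# Bonferroni-corrected confidence intervals to the usage proportions, read
# off the selection direction, and score preference with Jacobs' index
# D = (r - p) / (r + p - 2 r p).

#' Areal availability of habitats within a home range
#'
#' `p(h) = area(HR intersect h) / area(HR)`, computed by exact polygon
#' clipping. Habitats with zero availability are dropped.
#'
#' @param home_range A `home_range` object.
#' @param habitats A `habitat_map`.
#' @param coverage_tol Error if the habitat polygons cover less than this
#'   fraction of the home range (a gap in the habitat map).
#' @return Named numeric vector of availability proportions, in canonical
#'   habitat order.
#' @export
availability <- function(home_range, habitats, coverage_tol = 0.995) {
  stopifnot(inherits(home_range, "home_range"), inherits(habitats, "habitat_map"))
  hr <- home_range$polygons
  hr_area <- polygon_area(hr)
  if (hr_area <= 0) stop("home range has zero area")
  p <- vapply(habitats$habitat_order, function(nm) {
    intersection_area(hr, habitats$habitats[[nm]]) / hr_area
  }, numeric(1))
  if (sum(p) < coverage_tol) {
    stop(sprintf(
      "habitat polygons cover only %.1f%% of the home range: gap in the habitat map",
      100 * sum(p)
    ))
  }
  p[p > 0]
}

#' Relocation counts per habitat
#'
#' Point-in-polygon counts. A location on a shared boundary is assigned to
#' exactly one habitat: the first containing habitat in canonical habitat
#' order (deterministic, never double-counted).
#'
#' @param locations Data frame with columns `x`, `y` (and optionally
#'   `fix_id` used in error messages).
#' @param habitats A `habitat_map`.
#' @return Named integer vector of counts in canonical habitat order
#'   (including zeros).
#' @export
usage <- function(locations, habitats) {
  stopifnot(inherits(habitats, "habitat_map"))
  n <- nrow(locations)
  assigned <- rep(NA_character_, n)
  for (nm in habitats$habitat_order) {
    idx <- which(is.na(assigned))
    if (!length(idx)) break
    inside <- points_in_multipolygon(locations$x[idx], locations$y[idx],
                                     habitats$habitats[[nm]])
    assigned[idx[inside]] <- nm
  }
  if (anyNA(assigned)) {
    ids <- if ("fix_id" %in% names(locations)) {
      locations$fix_id[is.na(assigned)]
    } else {
      which(is.na(assigned))
    }
    stop("location(s) outside every habitat polygon: ",
         paste(ids, collapse = ", "))
  }
  counts <- table(factor(assigned, levels = habitats$habitat_order))
  stats::setNames(as.integer(counts), habitats$habitat_order)
}

#' Neu chi-square goodness-of-fit test of habitat use
#'
#' @param p Availability proportions (summing to 1 within 1e-3).
#' @param n_i Observed relocation counts, same length and order as `p`.
#' @return List with `chi2_parts`, `expected`, `chi2_total`, `df = k - 1`,
#'   `p_value` (upper tail).
#' @export
neu_chi_square <- function(p, n_i) {
  stopifnot(length(p) == length(n_i), length(p) >= 2)
  if (abs(sum(p) - 1) > 1e-3 + sqrt(.Machine$double.eps)) {
    stop("availability proportions must sum to 1 (within 1e-3)")
  }
  if (any(p < 0) || any(n_i < 0)) stop("negative availability or count")
  n <- sum(n_i)
  if (n < 1) stop("at least one relocation is required")
  if (any(p == 0 & n_i > 0)) {
    stop("observed use of a habitat with zero availability: impossible expectation")
  }
  expected <- p * n
  parts <- ifelse(expected > 0, (n_i - expected)^2 / expected, 0)
  if (any(expected < 5)) {
    warning("expected count(s) below 5: the chi-square approximation is doubtful")
  }
  chi2 <- sum(parts)
  df <- length(p) - 1L
  list(
    chi2_parts = parts, expected = expected, chi2_total = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE)
  )
}

#' Bonferroni-corrected confidence interval for a usage proportion
#'
#' The Neu et al. normal-approximation interval
#' `r +/- z_(1 - alpha/(2k)) * sqrt(r (1 - r) / n)`, with the lower bound
#' floored at 0 and the upper bound deliberately not capped at 1.
#'
#' @param r_i Usage proportion `n_i / n`.
#' @param n Total relocations.
#' @param k Number of simultaneous intervals (habitats present).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `c(low, high)`.
#' @export
bonferroni_ci <- function(r_i, n, k, alpha = 0.05) {
  stopifnot(r_i >= 0, r_i <= 1, n >= 1, k >= 1)
  z <- stats::qnorm(1 - alpha / (2 * k))
  half <- z * sqrt(r_i * (1 - r_i) / n)
  c(max(0, r_i - half), r_i + half)
}

#' Direction of habitat selection
#'
#' Availability below the CI on usage means the habitat is used more than
#' available (positive selection); above, less (negative); inside, neutral.
#'
#' @param p_i Availability proportion.
#' @param ci Confidence interval `c(low, high)` on the usage proportion.
#' @return `"positive"`, `"neutral"` or `"negative"`.
#' @export
classify_selection <- function(p_i, ci) {
  if (p_i < ci[1]) "positive" else if (p_i > ci[2]) "negative" else "neutral"
}

#' Jacobs' preference index
#'
#' `D = (r - p) / (r + p - 2 r p)`, in `[-1, 1]`; 0 indicates use in
#' proportion to availability, +1 maximal preference, -1 maximal avoidance.
#'
#' @param r_i Usage proportion.
#' @param p_i Availability proportion.
#' @return Jacobs' D.
#' @export
jacobs_index <- function(r_i, p_i) {
  stopifnot(r_i >= 0, r_i <= 1, p_i >= 0, p_i <= 1)
  if (r_i == 0 && p_i == 0) stop("Jacobs' index is undefined for r = p = 0")
  (r_i - p_i) / (r_i + p_i - 2 * r_i * p_i)
}

#' Full habitat-selection table from availability and counts
#'
#' @param p Named availability proportions (habitats present, `k >= 2`).
#' @param n_i Relocation counts in the same habitats.
#' @param alpha Family-wise error rate for the Bonferroni intervals.
#' @param individual_id Identifier carried into the table.
#' @return A `selection_table`: data frame with one row per habitat
#'   (availability, used count, usage proportion, expected count, chi-square
#'   part, CI bounds, direction, Jacobs' D) and attributes `chi2_total`,
#'   `df`, `p_value`.
#' @export
selection_from_counts <- function(p, n_i, alpha = 0.05,
                                  individual_id = NA_character_) {
  if (length(p) < 2) {
    stop("habitat selection needs at least 2 habitats in the home range")
  }
  chi <- neu_chi_square(p, n_i)
  n <- sum(n_i)
  k <- length(p)
  r <- n_i / n
  ci <- t(vapply(r, bonferroni_ci, numeric(2), n = n, k = k, alpha = alpha))
  rows <- data.frame(
    individual_id = individual_id,
    habitat = names(p),
    availability = as.numeric(p),
    used = as.integer(n_i),
    usage_prop = as.numeric(r),
    expected = as.numeric(chi$expected),
    chi2_part = as.numeric(chi$chi2_parts),
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    direction = vapply(seq_len(k), function(i) {
      classify_selection(p[i], ci[i, ])
    }, character(1)),
    jacobs = vapply(seq_len(k), function(i) {
      if (r[i] == 0 && p[i] == 0) NA_real_ else jacobs_index(r[i], p[i])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  structure(rows,
    class = c("selection_table", "data.frame"),
    chi2_total = chi$chi2_total, df = chi$df, p_value = chi$p_value,
    alpha = alpha
  )
}

#' Habitat-selection analysis for one bird
#'
#' Composes [availability()], [usage()] and [selection_from_counts()]:
#' habitats absent from the home range are excluded from the test.
#'
#' @param home_range A `home_range`.
#' @param habitats A `habitat_map`.
#' @param locations Data frame of relocations (`x`, `y`).
#' @param alpha Family-wise error rate.
#' @return A `selection_table`.
#' @export
selection_table <- function(home_range, habitats, locations, alpha = 0.05) {
  p <- availability(home_range, habitats)
  counts <- usage(locations, habitats)[names(p)]
  outside <- setdiff(names(which(usage(locations, habitats) > 0)), names(p))
  if (length(outside)) {
    stop("relocations observed in habitat(s) absent from the home range: ",
         paste(outside, collapse = ", "))
  }
  selection_from_counts(p, counts, alpha = alpha,
                        individual_id = home_range$individual_id)
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf(
    "selection_table (%s): chi2 = %.2f, df = %d, p = %.3g\n",
    x$individual_id[1], attr(x, "chi2_total"), attr(x, "df"), attr(x, "p_value")
  ))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
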
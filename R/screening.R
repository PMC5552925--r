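#' Segmented-regression screening threshold
#'
#' Finds the covariate threshold that best separates a low-detectability
#' regime from the rest of the data. Observations are binned on the covariate
#' into equal-count bins and the per-bin detection rate is computed; for each
#' candidate breakpoint (interior bin edge) a two-segment piecewise-constant
#' model (mean rate below, mean rate above) is fitted, and the breakpoint
#' minimizing the total sum of squared residuals (SSR) is returned. Ties are
#' broken toward the breakpoint retaining the larger fraction of the data
#' (`side = "lower"` screens out small covariate values, so smaller
#' breakpoints retain more; `side = "upper"` the opposite).
#'
#' With `criterion = "deviance"` the segmentation is instead performed on the
#' raw 0/1 outcomes, minimizing the two-segment binomial deviance; the binned
#' SSR criterion is the default.
#'
#' A diagnostic table of per-bin rates and the cumulative standard deviation
#' of the detection rates (ordered along the covariate) is attached for
#' plotting; threshold selection itself uses only the SSR (or deviance)
#' criterion.
#'
#' @param covariate Numeric covariate (e.g. altitude AGL or tortuosity).
#' @param detected Logical (or 0/1) detection outcomes.
#' @param side `"lower"`: threshold is a minimum acceptable value;
#'   `"upper"`: a maximum.
#' @param bins Number of equal-count bins (default 50).
#' @param criterion `"ssr"` (binned rates) or `"deviance"` (raw outcomes).
#' @param min_n Minimum number of observations required.
#' @return An object of class `threshold_fit`: list with `breakpoint`,
#'   `ssr_total`, `side`, `candidates_evaluated`, `degenerate`, and
#'   `diagnostics` (per-bin table with cumulative SD).
#' @examples
#' set.seed(1)
#' alt <- runif(2000, 0, 100)
#' det <- rbinom(2000, 1, ifelse(alt < 30, 0.1, 0.6))
#' segmented_threshold(alt, det, side = "lower")
#' @export
segmented_threshold <- function(covariate, detected, side = c("lower", "upper"),
                                bins = 50, criterion = c("ssr", "deviance"),
                                min_n = 20) {
  side <- match.arg(side)
  criterion <- match.arg(criterion)
  detected <- as.numeric(detected)
  ok <- is.finite(covariate) & is.finite(detected)
  covariate <- covariate[ok]; detected <- detected[ok]
  if (length(covariate) < min_n)
    stop("need at least ", min_n, " observations")
  if (diff(range(covariate)) == 0) stop("covariate is constant")

  edges <- unique(quantile(covariate, probs = seq(0, 1, length.out = bins + 1),
                           names = FALSE, type = 7))
  if (length(edges) < 3) stop("covariate has too few distinct values to bin")
  bin <- findInterval(covariate, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  rate <- tapply(detected, bin, mean)
  count <- tapply(detected, bin, length)
  mid <- tapply(covariate, bin, mean)
  ord <- order(as.numeric(names(rate)))
  rate <- as.numeric(rate[ord]); count <- as.numeric(count[ord])
  mid <- as.numeric(mid[ord])
  nb <- length(rate)
  cand_edges <- edges[2:(length(edges) - 1)]        # interior bin edges
  cand_idx <- seq_len(nb - 1)                       # split after bin k

  degenerate <- var(detected) == 0
  ssr_split <- function(k) {
    lo <- rate[seq_len(k)]; hi <- rate[(k + 1):nb]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }
  dev_split <- function(k) {
    below <- bin <= k
    dev_part <- function(y) {
      p <- mean(y)
      if (p <= 0 || p >= 1) return(0)
      -2 * sum(y * log(p) + (1 - y) * log(1 - p))
    }
    dev_part(detected[below]) + dev_part(detected[!below])
  }
  score <- vapply(cand_idx, if (criterion == "ssr") ssr_split else dev_split, 0)

  tol <- max(1e-12, 1e-9 * max(score))
  best <- which(score <= min(score) + tol)
  # ties: retain the most data
  pick <- if (side == "lower") best[1] else best[length(best)]
  if (degenerate) {
    # no detection-rate signal: breakpoint at the data boundary
    bp <- if (side == "lower") edges[1] else edges[length(edges)]
  } else {
    bp <- cand_edges[pick]
  }
  diagnostics <- data.frame(
    bin = seq_len(nb), mid = mid, n = count, rate = rate,
    cum_sd = vapply(seq_len(nb), function(i) if (i == 1) 0 else sd(rate[1:i]), 0)
  )
  structure(list(breakpoint = unname(bp), ssr_total = min(score), side = side,
                 candidates_evaluated = length(cand_idx),
                 degenerate = degenerate, criterion = criterion,
                 diagnostics = diagnostics),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("Segmented %s threshold (%s): %.4g (criterion %.4g over %d candidates)%s\n",
              x$side, x$criterion, x$breakpoint, x$ssr_total,
              x$candidates_evaluated,
              if (x$degenerate) " [degenerate: no rate signal]" else ""))
  invisible(x)
}

#' Apply altitude and tortuosity exclusion rules
#'
#' Drops observations flying below the minimum altitude or turning more
#' sharply than the maximum tortuosity before detection modelling.
#' Observations with undefined tortuosity (track ends) are retained, as are
#' observations with unknown altitude. The report gives per-rule counts and
#' the overall excluded fraction.
#'
#' @param observations Paired-observation data frame (columns `alt`,
#'   `tortuosity`).
#' @param alt_min Minimum altitude AGL in metres (use `-Inf` to disable).
#' @param tort_max Maximum tortuosity in `[0, 1]` (use `1` to disable... a
#'   value of 1 still excludes nothing since tortuosity <= 1).
#' @return List with `retained` (data frame) and `report` (list:
#'   `n_total`, `n_below_alt`, `n_above_tort`, `n_excluded`, `fraction`).
#' @export
apply_exclusions <- function(observations, alt_min, tort_max) {
  stopifnot(is.finite(alt_min) || alt_min == -Inf, is.finite(tort_max))
  bad_alt <- !is.na(observations$alt) & observations$alt < alt_min
  bad_tort <- !is.na(observations$tortuosity) &
    observations$tortuosity > tort_max
  bad <- bad_alt | bad_tort
  list(
    retained = observations[!bad, , drop = FALSE],
    report = list(
      n_total = nrow(observations),
      n_below_alt = sum(bad_alt),
      n_above_tort = sum(bad_tort),
      n_excluded = sum(bad),
      fraction = if (nrow(observations)) sum(bad) / nrow(observations) else 0,
      alt_min = alt_min, tort_max = tort_max
    )
  )
}
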
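## Death classification and proportion statistics.
##
## A larva counts as dead only when all four behavioral criteria -- no
## activity of any kind, loss of equilibrium, no operculum movement, no
## startle response -- hold both directly after exposure (t0) and after the
## 30 min recovery period (t30). Cardiac arrest is deliberately not a
## criterion: larvae survive on cutaneous oxygen diffusion after the heart
## stops.

#' Death criteria and observation time points
#'
#' @return `deathCriteria()` returns the four behavioral criterion names;
#'   `assessmentColumns()` the eight `timepoint_criterion` flag columns an
#'   assessment record table must carry.
#' @rdname deathCriteria
#' @export
deathCriteria <- function() {
  c("no_activity", "loss_of_equilibrium", "no_operculum_movement",
    "no_startle_response")
}

#' @rdname deathCriteria
#' @export
assessmentColumns <- function() {
  as.vector(outer(c("t0", "t30"), deathCriteria(), paste, sep = "_"))
}

.checkRecords <- function(records) {
  cols <- assessmentColumns()
  missingCols <- setdiff(cols, names(records))
  if (length(missingCols))
    stop("incomplete assessment records: missing ",
         paste(missingCols, collapse = ", "))
  flags <- records[cols]
  if (any(vapply(flags, function(x) any(is.na(x)), logical(1))))
    stop("incomplete assessment records: NA criterion flags")
  flags
}

#' Classify larvae as dead
#'
#' TRUE if and only if all four criteria are met at both observation time
#' points (the full logical matrix); any single unmet criterion at either
#' time point classifies the larva as alive.
#'
#' @param records data.frame of assessment records, one row per larva, with
#'   the eight logical columns named by [assessmentColumns()].
#' @return Logical vector, one element per record.
#' @examples
#' rec <- simulateMortalityRecords(5, pDeath = 1, seed = 1)
#' classifyDead(rec)  # all TRUE
#' @export
classifyDead <- function(records) {
  flags <- .checkRecords(records)
  rowSums(as.matrix(flags)) == length(assessmentColumns())
}

#' Wilson score interval for a binomial proportion
#'
#' @param deaths number of successes (deaths).
#' @param n number of trials (larvae).
#' @param conf confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`, clipped to `[0, 1]`.
#' @export
wilsonInterval <- function(deaths, n, conf = 0.95) {
  if (n <= 0) stop("'n' must be positive")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- deaths / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  halfw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  pmin(1, pmax(0, c(centre - halfw, centre + halfw)))
}

#' Mortality rate with Wilson confidence interval
#'
#' @param group a [MortalityGroup], or the number of deaths if `n` is given.
#' @param n number of larvae (when `group` is a count).
#' @param conf confidence level (default 0.95, as in the published envelopes).
#' @return List with `rate` (deaths/n) and `ci` (Wilson interval).
#' @examples
#' mortalityRate(mortalityGroup(20, 20))
#' @export
mortalityRate <- function(group, n = NULL, conf = 0.95) {
  if (is(group, "MortalityGroup")) {
    deaths <- group@deaths; n <- group@n
  } else {
    deaths <- group
    if (is.null(n)) stop("'n' is required when 'group' is a count")
  }
  if (n <= 0) stop("'n' must be positive")
  list(rate = deaths / n, ci = wilsonInterval(deaths, n, conf))
}

## pooled two-proportion z statistic and two-sided p, no continuity
## correction; z^2 equals Pearson's chi-square on the 2x2 table
.pooledZ <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = if (z == 0) 1 else 2 * pnorm(-abs(z)))
}

#' Pairwise two-proportion z-tests with Bonferroni correction
#'
#' Two-sided pooled-variance z-test for every pair of groups (no continuity
#' correction), with Bonferroni-adjusted p-values
#' `p_adj = min(1, familySize * p)`. The family size defaults to the number
#' of pairs but can be supplied to match a wider comparison family.
#'
#' @param groups list of [MortalityGroup] objects (each `n > 0`).
#' @param familySize Bonferroni family size `m` (default: number of pairs).
#' @return data.frame with columns `group1`, `group2`, `z`, `p`,
#'   `p_adjusted`, `family_size`.
#' @examples
#' g <- list(mortalityGroup(20, 20, "AC 32s"), mortalityGroup(3, 20, "AC 2s"))
#' compareProportions(g)
#' @export
compareProportions <- function(groups, familySize = NULL) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, is, logical(1), "MortalityGroup")))
  pairs <- utils::combn(length(groups), 2)
  m <- if (is.null(familySize)) ncol(pairs) else familySize
  if (m < ncol(pairs))
    stop("'familySize' must cover all reported comparisons")
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- groups[[pairs[1, k]]]; b <- groups[[pairs[2, k]]]
    if (identical(a, b))
      warning("degenerate comparison of a group with itself")
    zt <- .pooledZ(a@deaths, a@n, b@deaths, b@n)
    data.frame(group1 = a@label, group2 = b@label, z = zt$z, p = zt$p)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- pmin(1, m * res$p)
  res$family_size <- m
  res
}

#' Generate synthetic assessment records
#'
#' Each larva is independently dead (all eight criterion flags TRUE) with
#' probability `pDeath`; otherwise at least one criterion is left unmet
#' (flags drawn independently, with one random flag forced FALSE if all came
#' up TRUE). Seed-reproducible.
#'
#' @param n number of larvae.
#' @param pDeath death probability in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with `larva_id` and the eight columns of
#'   [assessmentColumns()].
#' @export
simulateMortalityRecords <- function(n, pDeath, seed = NULL) {
  if (pDeath < 0 || pDeath > 1) stop("'pDeath' must be in [0, 1]")
  cols <- assessmentColumns()
  .withSeed(seed, {
    dead <- runif(n) < pDeath
    flags <- matrix(TRUE, n, length(cols), dimnames = list(NULL, cols))
    for (i in which(!dead)) {
      f <- runif(length(cols)) < 0.5
      if (all(f)) f[sample.int(length(cols), 1)] <- FALSE
      flags[i, ] <- f
    }
    data.frame(larva_id = sprintf("larva%03d", seq_len(n)), flags)
  })
}
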
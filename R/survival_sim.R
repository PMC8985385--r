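# Binomial split-survival simulation: splits initial barcode abundances
# into two differentiation wells, thins each side by a loss coefficient,
# calibrates that coefficient to an observed survival proportion, and tests
# whether observed between-split barcode overlap is compatible with random
# (non-heritable) survival.

as_initial <- function(initial) {
  if (is.data.frame(initial)) {
    stopifnot(all(c("barcode", "umis") %in% names(initial)))
    x <- stats::setNames(as.integer(initial$umis), initial$barcode)
  } else {
    x <- stats::setNames(as.integer(initial), names(initial))
    if (is.null(names(x))) names(x) <- sprintf("bc%04d", seq_along(x))
  }
  if (any(is.na(x)) || any(x < 1L)) stop("initial abundances must be >= 1")
  x
}

#' Simulate one binomial split with loss
#'
#' Each barcode's initial abundance `n_i` (pseudo-UMI count, a proxy for
#' initial cell number) is split between wells A and B by a fair binomial,
#' then each side is thinned by the loss coefficient `s` (per-unit survival
#' probability). A barcode is scored present in a well when its surviving
#' count reaches `presence_threshold`.
#'
#' @param initial Named integer vector of initial abundances per barcode,
#'   or a data.frame with columns `barcode`, `umis`.
#' @param s Loss coefficient (survival probability) in `[0, 1]`.
#' @param presence_threshold Minimum surviving units to call a barcode
#'   present (default 1).
#' @param seed Integer seed (optional; inherit the caller's RNG when NULL).
#' @return List with `present_A`, `present_B` (character vectors of barcode
#'   names) and `counts` (data.frame `barcode`, `a`, `b`, `a_surv`,
#'   `b_surv`).
#' @export
simulate_split <- function(initial, s, presence_threshold = 1L, seed = NULL) {
  n <- as_initial(initial)
  stopifnot_scalar_prob(s, "s")
  presence_threshold <- check_count(presence_threshold, "presence_threshold")
  local_seed(seed, {
    a <- rbinom(length(n), n, 0.5)
    b <- n - a
    a_surv <- rbinom(length(n), a, s)
    b_surv <- rbinom(length(n), b, s)
    list(
      present_A = names(n)[a_surv >= presence_threshold],
      present_B = names(n)[b_surv >= presence_threshold],
      counts = data.frame(barcode = names(n), a = a, b = b,
                          a_surv = a_surv, b_surv = b_surv,
                          stringsAsFactors = FALSE)
    )
  })
}

#' Barcode overlap fractions between two splits
#'
#' @param set_A,set_B Character vectors of barcodes present in each split.
#' @return List with `fraction_A` (`|A n B| / |A|`), `fraction_B`
#'   (`|A n B| / |B|`), `n_overlap`, `n_A`, `n_B`. An empty split yields
#'   fraction 0 with a warning.
#' @export
overlap_fraction <- function(set_A, set_B) {
  ov <- length(intersect(set_A, set_B))
  fa <- if (length(set_A) == 0L) {
    warning("split A is empty; overlap fraction set to 0"); 0
  } else ov / length(set_A)
  fb <- if (length(set_B) == 0L) {
    warning("split B is empty; overlap fraction set to 0"); 0
  } else ov / length(set_B)
  list(fraction_A = fa, fraction_B = fb, n_overlap = ov,
       n_A = length(set_A), n_B = length(set_B))
}

# Expected fraction of initial barcodes present in one split at loss s.
# Binomial thinning composes: a unit ends up surviving in well A with
# probability s/2 independently, so P(present) = P(Binom(n_i, s/2) >= t).
expected_survival_proportion <- function(n, s, presence_threshold = 1L) {
  mean(1 - pbinom(presence_threshold - 1L, n, s / 2))
}

#' Calibrate the loss coefficient to an observed survival proportion
#'
#' Finds the loss coefficient `s` at which the expected fraction of initial
#' barcodes recovered in one differentiated split (the survival proportion)
#' matches the observed value. Binomial thinning makes this expectation
#' available in closed form — a unit survives into a given well with
#' probability `s/2` — so the calibration bisects a deterministic monotone
#' function rather than a noisy simulated one.
#'
#' @inheritParams simulate_split
#' @param observed_survival_proportion Observed fraction of initial
#'   barcodes found in a differentiated split, in `(0, 1]`.
#' @param tol Calibration tolerance on the survival proportion
#'   (default 0.005).
#' @return List with `s` (calibrated loss coefficient), `achieved`
#'   (expected survival proportion at `s`), `target`, and `range`
#'   (achievable proportions at `s = 0` and `s = 1`).
#' @export
calibrate_loss <- function(initial, observed_survival_proportion,
                           presence_threshold = 1L, tol = 0.005) {
  n <- as_initial(initial)
  target <- observed_survival_proportion
  if (!is.numeric(target) || length(target) != 1L || target <= 0 ||
      target > 1) {
    stop("`observed_survival_proportion` must be in (0, 1]")
  }
  presence_threshold <- check_count(presence_threshold, "presence_threshold")
  f <- function(s) expected_survival_proportion(n, s, presence_threshold)
  lo_val <- f(0); hi_val <- f(1)
  if (target > hi_val + tol) {
    stop(sprintf(
      "target %.3f unattainable: achievable survival proportion range is [%.3f, %.3f]",
      target, lo_val, hi_val))
  }
  lo <- 0; hi <- 1
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  s <- (lo + hi) / 2
  list(s = s, achieved = f(s), target = target, range = c(lo_val, hi_val))
}

#' Test observed between-split overlap against random survival
#'
#' Simulates `n_simulations` binomial splits with loss from the initial
#' abundances and compares the observed per-split overlap fractions with
#' the simulated null distribution. Clone-heritable survival (whole clones
#' living or dying together) inflates between-split overlap above this
#' null; random per-unit survival does not.
#'
#' @inheritParams simulate_split
#' @param set_A,set_B Character vectors of barcodes observed in each
#'   differentiated split (names must match `initial`).
#' @param n_simulations Number of null simulations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `split_overlap_test`: list with
#'   `observed` (overlap fractions, see [overlap_fraction()]),
#'   `simulated_fraction_A`, `simulated_fraction_B` (numeric vectors of
#'   length `n_simulations`), `quantile_A`, `quantile_B` (empirical
#'   position of each observed fraction within its null), `flagged`
#'   (TRUE when either observed fraction falls outside the central 95% of
#'   its null), `s`, `n_simulations`, and observed/simulated survival
#'   proportions.
#' @export
survival_randomness_test <- function(initial, set_A, set_B, s,
                                     n_simulations = 1000L,
                                     presence_threshold = 1L, seed = 1L) {
  n <- as_initial(initial)
  stopifnot_scalar_prob(s, "s")
  n_simulations <- check_count(n_simulations, "n_simulations")
  observed <- overlap_fraction(set_A, set_B)
  obs_surv <- c(A = length(intersect(set_A, names(n))) / length(n),
                B = length(intersect(set_B, names(n))) / length(n))
  local_seed(seed, {
    sim_a <- numeric(n_simulations)
    sim_b <- numeric(n_simulations)
    sim_surv <- numeric(n_simulations)
    for (k in seq_len(n_simulations)) {
      sp <- simulate_split(n, s, presence_threshold)
      ov <- length(intersect(sp$present_A, sp$present_B))
      sim_a[k] <- if (length(sp$present_A)) ov / length(sp$present_A) else 0
      sim_b[k] <- if (length(sp$present_B)) ov / length(sp$present_B) else 0
      sim_surv[k] <- length(sp$present_A) / length(n)
    }
    qa <- mean(sim_a < observed$fraction_A) +
      0.5 * mean(sim_a == observed$fraction_A)
    qb <- mean(sim_b < observed$fraction_B) +
      0.5 * mean(sim_b == observed$fraction_B)
    flagged <- qa < 0.025 || qa > 0.975 || qb < 0.025 || qb > 0.975
    structure(list(
      observed = observed,
      simulated_fraction_A = sim_a,
      simulated_fraction_B = sim_b,
      quantile_A = qa,
      quantile_B = qb,
      flagged = flagged,
      s = s,
      n_simulations = n_simulations,
      observed_survival_proportion = obs_surv,
      simulated_survival_proportion = mean(sim_surv)
    ), class = "split_overlap_test")
  })
}
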
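# Ground-truth PTT <-> BP law. One transit time per task must be consistent
# with all three per-component linear models BP_c = K1_c/PTT + K2_c, so the
# law is parameterized by the component coefficient pairs plus the per-task
# PTT; the pressure triples are derived from the shared PTT.

#' Ground-truth calibration law for the simulator
#'
#' @param K1 Named numeric vector `c(DBP=, MAP=, SBP=)` of slope
#'   coefficients in mm Hg s; must satisfy `K1["DBP"] <= K1["MAP"] <=
#'   K1["SBP"]` so that DBP <= MAP <= SBP at every transit time.
#' @param K2 Named numeric vector of intercepts in mm Hg, same ordering
#'   requirement.
#' @param task_ptt Named numeric vector: true pulse transit time (s) per
#'   task, each in (0.05, 0.5).
#' @param pep_s Pre-ejection period in seconds (constant within a session).
#' @return An object of class `ptt_law` with the derived per-task pressure
#'   table (`$tasks`: task, ptt_s, DBP, MAP, SBP, PAT).
#' @seealso [law_from_map_targets()], [default_law()], [random_law()]
#' @export
bp_law <- function(K1, K2, task_ptt, pep_s = 0.06) {
  comp <- c("DBP", "MAP", "SBP")
  stopifnot(all(comp %in% names(K1)), all(comp %in% names(K2)),
            length(task_ptt) >= 1, !is.null(names(task_ptt)))
  K1 <- K1[comp]; K2 <- K2[comp]
  if (any(K1 <= 0)) stop("K1 must be positive for every component")
  if (is.unsorted(K1) || is.unsorted(K2)) {
    stop("K1 and K2 must be non-decreasing in the order DBP, MAP, SBP")
  }
  if (any(task_ptt <= 0.05 | task_ptt >= 0.5)) {
    stop("task PTT values must lie in (0.05, 0.5) s")
  }
  tasks <- data.frame(task = names(task_ptt), ptt_s = unname(task_ptt),
                      stringsAsFactors = FALSE)
  for (cc in comp) tasks[[cc]] <- K1[[cc]] / tasks$ptt_s + K2[[cc]]
  for (cc in comp) {   # PTT = K1/(BP - K2) must stay positive and finite
    if (K2[[cc]] >= min(tasks[[cc]])) {
      stop("K2 must be below the smallest task pressure for component ", cc)
    }
  }
  tasks$PAT <- pep_s + tasks$ptt_s
  structure(list(K1 = K1, K2 = K2, pep_s = pep_s, tasks = tasks),
            class = "ptt_law")
}

#' Build a law from per-task MAP targets
#'
#' Derives the per-task transit time from the MAP law,
#' `PTT = K1_MAP / (MAP - K2_MAP)`, then the remaining components from
#' theirs. Calibration is well-conditioned when the MAP targets span at
#' least ~25 mm Hg.
#'
#' @inheritParams bp_law
#' @param map_targets Named numeric vector of true MAP (mm Hg) per task.
#' @return A `ptt_law`.
#' @export
law_from_map_targets <- function(K1, K2, map_targets, pep_s = 0.06) {
  ptt <- K1[["MAP"]] / (map_targets - K2[["MAP"]])
  bp_law(K1, K2, ptt, pep_s = pep_s)
}

#' Default ground-truth law
#'
#' Coefficients in the physiological range reported for PTT-based
#' calibration (K1 of order 2-5 mm Hg s, K2 anchored near resting DBP), with
#' MAP targets for the seven measurement segments of the protocol spanning
#' 26 mm Hg so the per-participant fit is well-conditioned.
#'
#' @inheritParams bp_law
#' @return A `ptt_law`.
#' @export
default_law <- function(pep_s = 0.06) {
  law_from_map_targets(
    K1 = c(DBP = 2.0, MAP = 3.0, SBP = 4.5),
    K2 = c(DBP = 64, MAP = 75, SBP = 96),
    map_targets = c(sit_baseline = 88, stand_baseline = 93, rest = 90,
                    mental_arithmetic = 100, cold_pressor = 108,
                    recovery_early = 114, recovery_late = 91),
    pep_s = pep_s)
}

#' Draw a random ground-truth law
#'
#' Stress-testing sampler: component-ordered K1 in [1, 3] mm Hg s and K2 in
#' [50, 75] mm Hg, with a transit-time grid constructed so the task MAP
#' values span at least ~25 mm Hg while every PTT stays inside (0.05, 0.5) s
#' (feasible only for K1_MAP above ~1.5, hence its narrower range).
#'
#' @param n_tasks Number of tasks (5-7; labelled from the default protocol).
#' @param pep_s Pre-ejection period (s).
#' @return A `ptt_law`.
#' @export
random_law <- function(n_tasks = 7, pep_s = 0.06) {
  stopifnot(n_tasks >= 5, n_tasks <= 7)
  # component gaps keep the MAP fraction (MAP-DBP)/(SBP-DBP) near the
  # physiological third at every transit time
  dm <- stats::runif(1, 0.3, 0.5)
  k1m <- stats::runif(1, 1.7, 2.2)
  k1d <- k1m - dm
  k1s <- k1m + stats::runif(1, 1.4, 1.6) * dm
  k2d <- stats::runif(1, 50, 62)
  om <- stats::runif(1, 3, 5)
  k2m <- k2d + om
  k2s <- k2m + stats::runif(1, 1.5, 1.8) * om
  inv_ptt <- seq(3.5, 3.5 + 25.5 / k1m, length.out = n_tasks)
  labs <- c("sit_baseline", "stand_baseline", "rest", "mental_arithmetic",
            "cold_pressor", "recovery_early", "recovery_late")[seq_len(n_tasks)]
  ptt <- 1 / inv_ptt
  names(ptt) <- labs
  bp_law(K1 = c(DBP = k1d, MAP = k1m, SBP = k1s),
         K2 = c(DBP = k2d, MAP = k2m, SBP = k2s),
         task_ptt = ptt, pep_s = pep_s)
}
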
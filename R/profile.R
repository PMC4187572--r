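#' Ground-truth oxygenation dynamics for one muscle
#'
#' Parameterises the injectable percent-change R2* response of a phantom
#' muscle: peak amplitude `A` (maximal change, % of baseline R2*), recovery
#' deficit `D` (% of baseline actually recovered during the recovery
#' window, `0 <= D <= A`) and the recovery time constant `tau` (s).
#'
#' @param maximal_change Peak amplitude A in % of baseline R2*; >= 0.
#' @param recovery_deficit Amount D recovered exponentially during the
#'   recovery block, in % of baseline; `0 <= D <= A`.
#' @param tau Recovery time constant in seconds; > 0.
#' @return An object of class `oxygenation_truth`.
#' @export
oxygenation_truth <- function(maximal_change, recovery_deficit = maximal_change / 2,
                              tau = 40) {
  stopifnot(maximal_change >= 0, recovery_deficit >= 0,
            recovery_deficit <= maximal_change, tau > 0)
  structure(list(maximal_change = maximal_change,
                 recovery_deficit = recovery_deficit, tau = tau),
            class = "oxygenation_truth")
}

#' Default injected dynamics for the phantom muscles
#'
#' Soleus amplitude 5.12% and gastrocnemius (both heads) 6.04% of baseline
#' R2*, with recovery deficit A/2 and tau 40 s — amplitudes representative
#' of the 15% MVC workload under control conditions.
#'
#' @param soleus,medial_gastrocnemius,lateral_gastrocnemius
#'   [oxygenation_truth()] objects per muscle.
#' @return Named list of `oxygenation_truth`, class `ground_truth`.
#' @export
ground_truth <- function(soleus = oxygenation_truth(5.12),
                         medial_gastrocnemius = oxygenation_truth(6.04),
                         lateral_gastrocnemius = oxygenation_truth(6.04)) {
  structure(list(soleus = soleus,
                 medial_gastrocnemius = medial_gastrocnemius,
                 lateral_gastrocnemius = lateral_gastrocnemius),
            class = "ground_truth")
}

#' Ground truth as a data frame
#' @param truth A [ground_truth()] list.
#' @return Data frame with columns muscle, maximal_change, recovery_deficit, tau.
#' @export
truth_table <- function(truth) {
  data.frame(muscle = names(truth),
             maximal_change = vapply(truth, `[[`, numeric(1), "maximal_change"),
             recovery_deficit = vapply(truth, `[[`, numeric(1), "recovery_deficit"),
             tau = vapply(truth, `[[`, numeric(1), "tau"),
             row.names = NULL)
}

#' Injected percent-change R2* profile
#'
#' The canonical cycle response: during baseline the profile is 0; during
#' each exercise block it ramps linearly to the peak amplitude `A`; during
#' recovery it decays as `(A - D) + D * exp(-t_rec / tau)` where `t_rec` is
#' the time since the end of exercise. Each cycle's ramp starts from the
#' previous cycle's end value, so the profile is cycle-periodic from cycle
#' 2 onward (cycle 1 starts from `start_offset`, default 0 — a first-cycle
#' transient that the analysis discards). Times at or beyond the paradigm
#' end return 0.
#'
#' @param times Sorted times in seconds.
#' @param paradigm An [exercise_paradigm()] object.
#' @param truth An [oxygenation_truth()] object.
#' @param start_offset Profile value (%) at the start of the first
#'   exercise block; default 0 (fresh muscle).
#' @return Percent-change values, same length as `times`.
#' @export
#' @examples
#' p <- exercise_paradigm()
#' tr <- oxygenation_truth(5, 4, 40)
#' # end of a recovery block: (5-4) + 4*exp(-120/40)
#' percent_change_profile(60 + 210 - 1e-9, p, tr)
percent_change_profile <- function(times, paradigm, truth, start_offset = 0) {
  A <- truth$maximal_change
  D <- truth$recovery_deficit
  tau <- truth$tau
  base <- paradigm$baseline_duration
  ex <- paradigm$exercise_duration
  cyc <- cycle_duration(paradigm)
  end_val <- (A - D) + D * exp(-paradigm$recovery_duration / tau)
  out <- numeric(length(times))
  in_cycles <- times >= base & times < total_duration(paradigm)
  tc <- times[in_cycles] - base
  k <- floor(tc / cyc)
  within <- tc - k * cyc
  start <- ifelse(k == 0, start_offset, end_val)
  val <- ifelse(within < ex,
                start + (A - start) * within / ex,
                (A - D) + D * exp(-(within - ex) / tau))
  out[in_cycles] <- val
  out
}
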
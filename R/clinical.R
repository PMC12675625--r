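#' Left-right gait asymmetry (percent)
#'
#' `asymmetry = (right - left) / max(right, left) * 100`. The sign marks
#' the larger side (positive = right larger); values lie in [-100, 100]
#' for non-negative inputs and `asymmetry(a, b) = -asymmetry(b, a)`.
#'
#' @param right,left Positive scalars or vectors (any gait parameter:
#'   arm-swing amplitude, stride length, stride time, velocity...).
#' @return Asymmetry in percent; NA (with a warning) where both sides
#'   are zero.
#' @examples
#' asymmetry_percent(2, 1)  # 50
#' asymmetry_percent(1, 2)  # -50
#' @export
asymmetry_percent <- function(right, left) {
  mx <- pmax(right, left)
  bad <- mx <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("asymmetry undefined where max(right, left) <= 0; returning NA")
  }
  out <- (right - left) / mx * 100
  out[bad] <- NA_real_
  out
}

#' Dual-task cost (percent)
#'
#' `DTcost = (dual_task - single_task) / single_task * 100`: the percent
#' change of a motor measure under a concurrent cognitive task. Negative
#' values (improvement under dual task) are representable.
#'
#' @param dual_task,single_task Positive scalars or vectors;
#'   `single_task` must be strictly positive.
#' @return Dual-task cost in percent (>= -100 for non-negative inputs).
#' @examples
#' dual_task_cost_percent(1.2, 1.0)  # 20
#' dual_task_cost_percent(0.9, 1.0)  # -10
#' @export
dual_task_cost_percent <- function(dual_task, single_task) {
  if (any(single_task <= 0, na.rm = TRUE)) {
    stop("single_task must be strictly positive")
  }
  (dual_task - single_task) / single_task * 100
}

#' Add gait-derived metrics to a subject table
#'
#' For each named measure, computes `<measure>_asym` from columns
#' `<measure>_right` / `<measure>_left` and/or `<measure>_dtcost` from
#' `<measure>_dt` / `<measure>_st` (single/dual task), following the
#' asymmetry and dual-task-cost formulas above.
#'
#' @param data Data frame of per-subject gait parameters.
#' @param measures Character vector of measure stems.
#' @return The input as a tibble with the derived columns appended.
#' @export
add_gait_metrics <- function(data, measures) {
  out <- tibble::as_tibble(data)
  for (m in measures) {
    r <- paste0(m, "_right"); l <- paste0(m, "_left")
    st <- paste0(m, "_st"); dt <- paste0(m, "_dt")
    if (all(c(r, l) %in% names(out))) {
      out[[paste0(m, "_asym")]] <- asymmetry_percent(out[[r]], out[[l]])
    }
    if (all(c(st, dt) %in% names(out))) {
      out[[paste0(m, "_dtcost")]] <- dual_task_cost_percent(out[[dt]], out[[st]])
    }
    if (!any(c(r, l, st, dt) %in% names(out))) {
      stop("no right/left or st/dt columns found for measure: ", m)
    }
  }
  out
}
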
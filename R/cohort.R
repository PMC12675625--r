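#' Default clinical variable registry
#'
#' One row per cohort-table variable: its type (continuous / binary),
#' the control-population mean and SD (continuous) or probability
#' (binary), whether higher values are clinically worse, the planted
#' patient-vs-control shift and the additional subgroup-B shift (in SD
#' units for continuous variables, probability units for binary ones),
#' and whether the variable enters the phenotype-clustering distance.
#' The inventory mirrors a prodromal-synucleinopathy work-up: sleep
#' questionnaires (RBDSQ, PSQI, ESS), MDS-UPDRS parts, timed motor tests
#' (9-hole peg, 10 m walk, five-time sit-to-stand), gait parameters with
#' dual-task variants, a neuropsychological battery, and binary non-motor
#' features. Subgroup B is planted as the older, globally worse
#' phenotype; the shifts are simulation configuration, not claims about
#' any real cohort.
#'
#' @return A tibble registry; see column descriptions above.
#' @export
default_variable_registry <- function() {
  cont <- tibble::tribble(
    ~variable, ~mean, ~sd, ~higher_is_worse, ~patient_shift, ~b_shift, ~use_in_clustering,
    "age",                  66,   6,   NA,    0.0, 1.5, TRUE,
    "disease_duration_y",    6,   4,   TRUE,  0.0, 1.0, TRUE,
    "rbdsq",                 2, 1.5,   TRUE,  2.5, 1.5, TRUE,
    "psqi",                  4,   2,   TRUE,  1.0, 2.5, TRUE,
    "ess",                   6,   3,   TRUE,  0.5, 1.5, TRUE,
    "updrs_i",             1.5, 1.5,   TRUE,  1.0, 2.5, TRUE,
    "updrs_ii",              1,   1,   TRUE,  0.8, 2.5, TRUE,
    "updrs_iii",             2,   2,   TRUE,  1.0, 3.0, TRUE,
    "ninehpt_s",            20,   3,   TRUE,  0.5, 2.5, TRUE,
    "tenmwt_s",              8, 1.5,   TRUE,  0.4, 2.5, TRUE,
    "ftsts_s",              10,   2,   TRUE,  0.4, 2.5, TRUE,
    "tug_dtcost_pct",        7,  12,   TRUE,  0.3, 2.5, TRUE,
    "digit_span_backward",   5,   1,   FALSE, 0.3, 1.5, TRUE,
    "rey_immediate",        45,   8,   FALSE, 0.4, 2.5, TRUE,
    "rey_delayed",           9,   3,   FALSE, 0.4, 2.5, TRUE,
    "raven",                30,   4,   FALSE, 0.3, 1.5, TRUE,
    "token_test",           33,   2,   FALSE, 0.2, 1.5, TRUE,
    "stride_length_cm",    130,  15,   FALSE, 0.4, 2.5, TRUE,
    "velocity_ms",         1.2, 0.15,  FALSE, 0.3, 2.5, TRUE,
    "arm_swing_asym_pct",   10,   8,   TRUE,  0.5, 2.5, TRUE
  )
  cont$type <- "continuous"
  bin <- tibble::tribble(
    ~variable, ~mean, ~patient_shift, ~b_shift, ~use_in_clustering,
    "sex",                    0.6, 0.00, 0.00, TRUE,
    "olfactory_loss",         0.05, 0.25, 0.55, TRUE,
    "constipation",           0.10, 0.15, 0.55, TRUE,
    "urinary_dysfunction",    0.10, 0.10, 0.55, TRUE,
    "orthostatic_hypotension", 0.05, 0.10, 0.55, TRUE,
    "depressive_symptoms",    0.10, 0.15, 0.55, TRUE
  )
  bin$type <- "binary"
  bin$sd <- NA_real_
  bin$higher_is_worse <- TRUE
  raw <- tibble::tibble(
    variable = c("arm_swing_right", "arm_swing_left", "tug_s_st", "tug_s_dt"),
    mean = NA_real_, sd = NA_real_, higher_is_worse = NA,
    patient_shift = NA_real_, b_shift = NA_real_,
    use_in_clustering = FALSE, type = "continuous"
  )
  dplyr::bind_rows(cont, bin, raw)[, c("variable", "type", "mean", "sd",
                                       "higher_is_worse", "patient_shift",
                                       "b_shift", "use_in_clustering")]
}

#' Synthesize a mixed-type clinical cohort table
#'
#' Generates per-subject records for `n_controls` healthy controls and
#' `n_patients` patients split into two planted subgroups ("A", the
#' milder phenotype, and "B", the older and globally worse one) in the
#' given proportions. Continuous variables are Gaussian around planted
#' means (control mean, shifted for patients and again for subgroup B in
#' the clinically worse direction); binary variables are Bernoulli.
#' Timed measures are truncated at a small positive floor. Raw gait
#' columns (`arm_swing_right`/`_left`, `tug_s_st`/`_dt`) are generated
#' consistently with the planted asymmetry and dual-task-cost values, and
#' the derived metrics are recomputed from them via [add_gait_metrics()]
#' — so the printed `arm_swing_asym_pct` and `tug_dtcost_pct` columns
#' satisfy their defining formulas exactly.
#'
#' `truth_cluster` records the planted subgroup for every patient and is
#' `NA` for controls; `disease_duration_y` is likewise patient-only.
#'
#' @param n_controls,n_patients Cohort sizes (defaults 52 / 44).
#' @param subgroup_fractions Two non-negative fractions summing to 1
#'   (default `c(0.57, 0.43)`).
#' @param effect_profile Optional named vector overriding the registry's
#'   subgroup-B shifts (`b_shift`; SD units for continuous, probability
#'   units for binary). Names must be registered variables. An all-zero
#'   profile makes the two subgroups exchangeable.
#' @param registry Variable registry, default
#'   [default_variable_registry()].
#' @param seed Integer seed; output is deterministic given it.
#' @return A `cohort_table` tibble (`id`, `group`, `truth_cluster`, then
#'   one column per registered variable) with attributes `registry` and
#'   `planted` (the per-subgroup planted means).
#' @export
make_clinical_table <- function(n_controls = 52, n_patients = 44,
                                subgroup_fractions = c(0.57, 0.43),
                                effect_profile = NULL,
                                registry = default_variable_registry(),
                                seed = 1L) {
  if (n_controls < 0 || n_patients < 0) stop("cohort sizes must be non-negative")
  if (length(subgroup_fractions) != 2L ||
      abs(sum(subgroup_fractions) - 1) > 1e-8 || any(subgroup_fractions < 0)) {
    stop("subgroup_fractions must be two non-negative values summing to 1")
  }
  if (!is.null(effect_profile)) {
    bad <- setdiff(names(effect_profile), registry$variable)
    if (length(bad)) stop("unknown variable in effect_profile: ",
                          paste(bad, collapse = ", "))
    registry$b_shift[match(names(effect_profile), registry$variable)] <-
      unname(effect_profile)
  }
  set.seed(as.integer(seed))
  n_b <- round(n_patients * subgroup_fractions[2])
  n_a <- n_patients - n_b
  grp <- c(rep("control", n_controls), rep("patient", n_patients))
  cl <- c(rep(NA_character_, n_controls), rep("A", n_a), rep("B", n_b))
  n <- n_controls + n_patients
  out <- tibble::tibble(
    id = c(sprintf("HC%03d", seq_len(n_controls)),
           sprintf("RBD%03d", seq_len(n_patients))),
    group = grp, truth_cluster = cl
  )

  timed <- c("ninehpt_s", "tenmwt_s", "ftsts_s", "stride_length_cm",
             "velocity_ms", "disease_duration_y")
  planted <- list()
  gen <- registry[!registry$variable %in%
                    c("arm_swing_right", "arm_swing_left",
                      "tug_s_st", "tug_s_dt"), ]
  for (r in seq_len(nrow(gen))) {
    v <- gen[r, ]
    if (v$type == "continuous") {
      dir <- if (isTRUE(v$higher_is_worse)) 1 else if (isFALSE(v$higher_is_worse)) -1 else 1
      m_c <- v$mean
      m_a <- m_c + dir * v$patient_shift * v$sd
      m_b <- m_a + dir * v$b_shift * v$sd
      mu <- ifelse(grp == "control", m_c, ifelse(cl == "B", m_b, m_a))
      x <- stats::rnorm(n, mu, v$sd)
      if (v$variable %in% timed) x <- pmax(x, 0.1)
      if (v$variable == "disease_duration_y") x[grp == "control"] <- NA_real_
      out[[v$variable]] <- x
      planted[[v$variable]] <- c(control = m_c, A = m_a, B = m_b)
    } else {
      p_c <- v$mean
      p_a <- min(1, p_c + v$patient_shift)
      p_b <- min(1, p_a + v$b_shift)
      pr <- ifelse(grp == "control", p_c, ifelse(cl == "B", p_b, p_a))
      out[[v$variable]] <- stats::rbinom(n, 1, pr)
      planted[[v$variable]] <- c(control = p_c, A = p_a, B = p_b)
    }
  }

  # raw gait pairs consistent with the planted derived metrics
  a_pct <- out$arm_swing_asym_pct
  left <- pmax(stats::rnorm(n, 30, 4), 5)
  right <- ifelse(a_pct >= 0, left / pmax(1 - a_pct / 100, 0.05),
                  left * (1 + a_pct / 100))
  out$arm_swing_left <- left
  out$arm_swing_right <- pmax(right, 0.1)
  st <- pmax(stats::rnorm(n, 10, 1.5), 2)
  out$tug_s_st <- st
  out$tug_s_dt <- st * (1 + out$tug_dtcost_pct / 100)
  out$arm_swing_asym_pct <- NULL
  out$tug_dtcost_pct <- NULL
  out <- add_gait_metrics(out, c("arm_swing", "tug_s"))
  names(out)[names(out) == "arm_swing_asym"] <- "arm_swing_asym_pct"
  names(out)[names(out) == "tug_s_dtcost"] <- "tug_dtcost_pct"

  attr(out, "registry") <- registry
  attr(out, "planted") <- planted
  class(out) <- c("cohort_table", class(out))
  out
}
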
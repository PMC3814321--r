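#' Ordered developmental stage paths
#'
#' A stage path is a tibble of ordered developmental stages, each with the
#' number of divisions occurring within it. Division counts per stage are
#' configuration inputs, not estimates: the shipped defaults are illustrative
#' values chosen to reproduce the qualitative orderings seen along lymphocyte
#' maturation (no labeling before the first Cre-active proliferative stage;
#' no further rise across non-proliferative stages; CD8 single-positive cells
#' roughly twice the CD4 single-positive fraction) and are meant to be
#' overridden with whatever counts a user believes.
#'
#' @param name Character vector of stage names, in maturation order.
#' @param divisions Non-negative divisions per stage (recycled if scalar).
#' @return A tibble (`stage`, `divisions`, `order`) of class `tlox_stages`.
#' @examples
#' b_cell_stages()
#' t_cell_stages()
#' stage_path(c("HSC", "MPP"), divisions = c(1, 3))
#' @export
stage_path <- function(name, divisions) {
  if (length(name) == 0 || anyDuplicated(name)) {
    abort_config("Stage names must be non-empty and unique.")
  }
  divisions <- rep_len(divisions, length(name))
  if (any(!is.finite(divisions)) || any(divisions < 0)) {
    abort_config("Stage `divisions` must be non-negative numbers.")
  }
  out <- tibble::tibble(
    stage = as.character(name), divisions = as.numeric(divisions),
    order = seq_along(name)
  )
  class(out) <- c("tlox_stages", class(out))
  out
}

#' @rdname stage_path
#' @export
b_cell_stages <- function() {
  stage_path(c("proB", "preB", "matureB"), divisions = c(2, 2, 0))
}

#' @rdname stage_path
#' @export
t_cell_stages <- function() {
  stage_path(c("DN3", "DN4", "DP", "CD4SP", "CD8SP"),
             divisions = c(0, 2, 0, 0, 1))
}

#' Cre drivers with a developmental onset
#'
#' A Cre driver is active from its onset stage onward (continuous
#' expression). `missed_fraction` models a driver switching on part-way
#' through the onset stage: that share of the onset stage's divisions happens
#' before Cre is active and cannot label. The shipped drivers: `mb1_cre()`
#' (pro-B onward), `lck_cre()` (DN3 onward) and `cd4_cre()`, whose onset
#' falls between DN3 and DN4 and is modeled as missing half of the DN4
#' divisions by default.
#'
#' @param name Driver label.
#' @param onset_stage First stage with Cre activity.
#' @param missed_fraction Fraction of the onset stage's divisions occurring
#'   before Cre turns on, in \[0, 1\].
#' @return A `tlox_driver` list.
#' @export
cre_driver <- function(name, onset_stage, missed_fraction = 0) {
  if (!rlang::is_scalar_character(name) ||
      !rlang::is_scalar_character(onset_stage)) {
    abort_config("`name` and `onset_stage` must be single strings.")
  }
  check_scalar_number(missed_fraction, "missed_fraction", lower = 0, upper = 1)
  structure(
    list(name = name, onset_stage = onset_stage,
         missed_fraction = missed_fraction),
    class = "tlox_driver"
  )
}

#' @rdname cre_driver
#' @export
mb1_cre <- function() cre_driver("mb1Cre", "proB")

#' @rdname cre_driver
#' @export
lck_cre <- function() cre_driver("LckCre", "DN3")

#' @rdname cre_driver
#' @param phi For `cd4_cre()`: share of DN4 divisions missed, default 0.5.
#' @export
cd4_cre <- function(phi = 0.5) cre_driver("CD4Cre", "DN4", missed_fraction = phi)

#' Predicted labeled fraction along a developmental path
#'
#' Counts Cre-active divisions cumulatively along the stage path — stages
#' before the driver's onset contribute nothing, the onset stage contributes
#' `divisions * (1 - missed_fraction)`, later stages contribute fully — and
#' maps the running total through the cumulative labeling model. Predictions
#' are therefore non-decreasing along the path, flat across stages with no
#' divisions, and exactly 0 at any stage the driver has not yet labeled
#' through a division (e.g. DN3 under an Lck-driven Cre, where DN3 cells do
#' not divide).
#'
#' @param stages A [stage_path()] tibble.
#' @param driver A [cre_driver()].
#' @param params A [tlox_params()] object. Fractional cumulative divisions
#'   require the simplified variant.
#' @return A tibble of class `tlox_stage_prediction`: `stage`, `order`,
#'   `divisions`, `active_divisions`, `cumulative_divisions`, `driver`,
#'   `predicted_fraction`.
#' @examples
#' predict_stage_fractions(t_cell_stages(), lck_cre())
#' @export
predict_stage_fractions <- function(stages, driver, params = tlox_params()) {
  stages <- as_stage_path(stages)
  if (!inherits(driver, "tlox_driver")) {
    abort_config("`driver` must come from cre_driver().")
  }
  params <- as_tlox_params(params)
  onset <- match(driver$onset_stage, stages$stage)
  if (is.na(onset)) {
    abort_config(sprintf(
      "Driver onset stage '%s' is not on the stage path (%s).",
      driver$onset_stage, paste(stages$stage, collapse = " > ")
    ))
  }
  active <- dplyr::case_when(
    stages$order < onset ~ 0,
    stages$order == onset ~ stages$divisions * (1 - driver$missed_fraction),
    TRUE ~ stages$divisions
  )
  cum <- cumsum(active)
  out <- dplyr::mutate(
    stages,
    active_divisions = active,
    cumulative_divisions = cum,
    driver = driver$name,
    predicted_fraction = cumulative_label_fraction(cum, params)
  )
  class(out) <- c("tlox_stage_prediction", setdiff(class(out), "tlox_stages"))
  out
}

as_stage_path <- function(stages) {
  if (inherits(stages, "tlox_stages")) return(stages)
  if (is.data.frame(stages) && all(c("stage", "divisions") %in% names(stages))) {
    return(stage_path(stages$stage, stages$divisions))
  }
  abort_config("`stages` must be a stage_path() tibble.")
}

#' Compare two Cre drivers along the same stage path
#'
#' A driver with a strictly later (or partial) onset can only miss labeling
#' opportunities, so its predicted fraction is less than or equal to the
#' earlier driver's at every stage, and the deficit persists through
#' post-proliferative stages — the signature distinguishing a cycle-coupled
#' reporter from a conventional flox-stop reporter.
#'
#' @param stages A [stage_path()] tibble.
#' @param driver_a,driver_b Two [cre_driver()] objects.
#' @param params A [tlox_params()] object.
#' @return A tibble: `stage`, `order`, `fraction_a`, `fraction_b`,
#'   `difference` (`a - b`), with driver names as attributes.
#' @examples
#' compare_drivers(t_cell_stages(), lck_cre(), cd4_cre())
#' @export
compare_drivers <- function(stages, driver_a, driver_b,
                            params = tlox_params()) {
  pa <- predict_stage_fractions(stages, driver_a, params)
  pb <- predict_stage_fractions(stages, driver_b, params)
  out <- tibble::tibble(
    stage = pa$stage, order = pa$order,
    fraction_a = pa$predicted_fraction,
    fraction_b = pb$predicted_fraction,
    difference = pa$predicted_fraction - pb$predicted_fraction
  )
  attr(out, "drivers") <- c(a = driver_a$name, b = driver_b$name)
  out
}

#' BrdU pulse parameters
#'
#' @param cycling_fraction Fraction of the population in cycle, \[0, 1\].
#' @param t_cycle Cell-cycle length, hours.
#' @param t_s S-phase length, hours; must satisfy `0 < t_s < t_cycle`.
#' @param t_pulse Pulse window, hours (a 4 h i.p. pulse is typical in mice).
#' @return A `tlox_brdu` list.
#' @export
brdu_params <- function(cycling_fraction, t_cycle = 24, t_s = 8,
                        t_pulse = 4) {
  check_scalar_number(cycling_fraction, "cycling_fraction", lower = 0, upper = 1)
  check_scalar_number(t_cycle, "t_cycle")
  check_scalar_number(t_s, "t_s")
  check_scalar_number(t_pulse, "t_pulse", lower = 0)
  if (!(t_s > 0 && t_s < t_cycle)) {
    abort_model("Need 0 < t_s < t_cycle.")
  }
  structure(
    list(cycling_fraction = cycling_fraction, t_cycle = t_cycle,
         t_s = t_s, t_pulse = t_pulse),
    class = "tlox_brdu"
  )
}

#' Expected BrdU-positive fraction after a short pulse
#'
#' An asynchronously cycling cell is scored BrdU+ if it spends any time in S
#' phase during the pulse, which happens with probability
#' `min(1, (t_s + t_pulse) / t_cycle)`; quiescent cells never label. Label
#' dilution and re-entry are ignored, adequate when the pulse is much shorter
#' than the cycle. BrdU measures the instantaneous proliferation *rate* of a
#' population — in contrast to the cumulative, heritable Tlox label, which
#' records proliferative *history* — and the two can disagree.
#'
#' @param p A [brdu_params()] object.
#' @return Expected BrdU-positive fraction.
#' @examples
#' brdu_fraction(brdu_params(cycling_fraction = 1, t_cycle = 24, t_s = 8, t_pulse = 4))
#' @export
brdu_fraction <- function(p) {
  if (!inherits(p, "tlox_brdu")) {
    if (is.list(p)) p <- do.call(brdu_params, p)
    else abort_config("`p` must come from brdu_params().")
  }
  p$cycling_fraction * min(1, (p$t_s + p$t_pulse) / p$t_cycle)
}
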
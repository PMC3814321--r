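#' Configuration for a synthetic cohort
#'
#' Describes one or more groups of mice whose cells carry the tandem-lox
#' reporter. Per group: the true proliferative history `k`, the per-division
#' activation probability `p`, and BrdU pulse parameters. Cohort-wide: the
#' number of mice and cells per mouse, the mouse-to-mouse overdispersion
#' `rho` (intra-class correlation of mouse-level labeled fractions; the
#' default 0.02 gives standard errors of the order seen across 3-mouse
#' cohorts in vivo, a few percentage points), and a log-normal intensity
#' model for the fluorescence channels.
#'
#' @param groups A data frame with columns `group`, `k`, `p`, and optionally
#'   `cycling_fraction`, `t_cycle`, `t_s`, `t_pulse`, `n_mice`, `n_cells`
#'   (per-group overrides of the cohort-wide values).
#' @param n_mice Mice per group (default 3, a typical cohort).
#' @param n_cells Cells recorded per mouse.
#' @param rho Intra-class correlation of mouse-level labeled fractions,
#'   in \[0, 1).
#' @param intensity An [intensity_model()].
#' @return A `tlox_cohort_config` list.
#' @seealso [scenario_b_path()], [scenario_vg11_liver_node()],
#'   [scenario_id3_contrast()] for ready-made configurations.
#' @export
cohort_config <- function(groups, n_mice = 3, n_cells = 3000, rho = 0.02,
                          intensity = intensity_model()) {
  if (!is.data.frame(groups) || nrow(groups) == 0 ||
      !all(c("group", "k", "p") %in% names(groups))) {
    abort_config("`groups` must be a data frame with columns group, k, p.")
  }
  if (anyDuplicated(groups$group)) abort_config("Group names must be unique.")
  if (any(groups$k < 0)) abort_config("`k` must be non-negative.")
  if (any(groups$p <= 0 | groups$p >= 1)) {
    abort_config("`p` must lie strictly in (0, 1).")
  }
  check_scalar_number(n_mice, "n_mice", lower = 1, integer = TRUE)
  check_scalar_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar_number(rho, "rho", lower = 0, upper = 1, closed_upper = FALSE)
  defaults <- list(cycling_fraction = 0.1, t_cycle = 24, t_s = 8, t_pulse = 4,
                   n_mice = n_mice, n_cells = n_cells)
  for (nm in names(defaults)) {
    if (!nm %in% names(groups)) groups[[nm]] <- defaults[[nm]]
  }
  if (!inherits(intensity, "tlox_intensity")) {
    abort_config("`intensity` must come from intensity_model().")
  }
  structure(
    list(groups = tibble::as_tibble(groups), rho = rho,
         intensity = intensity),
    class = "tlox_cohort_config"
  )
}

#' Log-normal fluorescence intensity model
#'
#' Each channel is a two-component log-normal mixture. The tdTomato channel
#' separates labeled from unlabeled cells by `td_meanlog_pos - td_meanlog_neg`
#' log units. Misclassification at the midpoint threshold is the Gaussian
#' overlap `pnorm(-separation / (2 * sdlog))`: the default 6-sd separation
#' (about a 400-fold intensity shift, typical for a bright reporter) keeps it
#' near 0.1%, while 3 sd would already misgate ~7% of cells. GFP
#' marks all cassette carriers, with a modest upshift in labeled cells
#' (removal of the translational stop stabilizes the transcript).
#' Cytometer spillover/compensation is not modeled.
#'
#' @param td_meanlog_neg,td_meanlog_pos,td_sdlog tdTomato mixture parameters
#'   (log scale).
#' @param gfp_meanlog,gfp_sdlog,gfp_label_shift GFP parameters.
#' @return A `tlox_intensity` list.
#' @export
intensity_model <- function(td_meanlog_neg = 2, td_meanlog_pos = 8,
                            td_sdlog = 1, gfp_meanlog = 4, gfp_sdlog = 0.5,
                            gfp_label_shift = 0.5) {
  if (td_sdlog <= 0 || gfp_sdlog <= 0) {
    abort_config("Intensity sdlog parameters must be positive.")
  }
  if (td_meanlog_pos <= td_meanlog_neg) {
    abort_config("td_meanlog_pos must exceed td_meanlog_neg.")
  }
  structure(
    list(td_meanlog_neg = td_meanlog_neg, td_meanlog_pos = td_meanlog_pos,
         td_sdlog = td_sdlog, gfp_meanlog = gfp_meanlog,
         gfp_sdlog = gfp_sdlog, gfp_label_shift = gfp_label_shift),
    class = "tlox_intensity"
  )
}

#' Generate a synthetic flow-cytometry cohort
#'
#' For each mouse, a true labeled fraction is drawn from a beta distribution
#' with mean `1 - (1 - p)^k` and intra-class correlation `rho`; each cell's
#' label is Bernoulli at the mouse's fraction, BrdU positivity is Bernoulli
#' at the group's [brdu_fraction()], and channel intensities follow the
#' log-normal mixture conditional on the true label. The returned event
#' table stands in for gated FACS events; the attached manifest records
#' every true parameter and per-mouse fraction so downstream estimators can
#' be checked against ground truth.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return A tibble of class `tlox_cohort`, one row per cell: `group`,
#'   `mouse`, `gfp_intensity`, `tdtomato_intensity`, `brdu_status`,
#'   `true_label`. The manifest is available via [cohort_manifest()].
#' @examples
#' cfg <- cohort_config(tibble::tibble(group = "g", k = 2, p = 0.1),
#'                      n_mice = 3, n_cells = 500)
#' events <- generate_cohort(cfg, seed = 1)
#' cohort_manifest(events)$mouse_fractions
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "tlox_cohort_config")) {
    abort_config("`config` must come from cohort_config().")
  }
  local_seed_if(seed)
  rho <- config$rho
  im <- config$intensity

  per_group <- purrr::pmap(config$groups, function(group, k, p,
                                                   cycling_fraction, t_cycle,
                                                   t_s, t_pulse, n_mice,
                                                   n_cells, ...) {
    f_true <- 1 - (1 - p)^k
    bp <- brdu_fraction(brdu_params(cycling_fraction, t_cycle, t_s, t_pulse))
    f_mouse <- if (rho == 0 || f_true == 0) {
      rep(f_true, n_mice)
    } else {
      shape <- (1 - rho) / rho
      stats::rbeta(n_mice, f_true * shape, (1 - f_true) * shape)
    }
    cells <- purrr::map(seq_len(n_mice), function(m) {
      lab <- stats::runif(n_cells) < f_mouse[m]
      tibble::tibble(
        group = group,
        mouse = sprintf("%s_m%d", group, m),
        gfp_intensity = stats::rlnorm(
          n_cells, im$gfp_meanlog + lab * im$gfp_label_shift, im$gfp_sdlog
        ),
        tdtomato_intensity = stats::rlnorm(
          n_cells,
          ifelse(lab, im$td_meanlog_pos, im$td_meanlog_neg), im$td_sdlog
        ),
        brdu_status = stats::runif(n_cells) < bp,
        true_label = lab
      )
    })
    list(
      events = dplyr::bind_rows(cells),
      fractions = tibble::tibble(
        group = group, mouse = sprintf("%s_m%d", group, seq_len(n_mice)),
        true_fraction = f_mouse, expected_fraction = f_true,
        expected_brdu = bp, k = k, p = p
      )
    )
  })

  events <- dplyr::bind_rows(purrr::map(per_group, "events"))
  manifest <- list(
    config = config,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    mouse_fractions = dplyr::bind_rows(purrr::map(per_group, "fractions"))
  )
  attr(events, "manifest") <- manifest
  class(events) <- c("tlox_cohort", class(events))
  events
}

#' @rdname generate_cohort
#' @param events A `tlox_cohort` table.
#' @export
cohort_manifest <- function(events) {
  m <- attr(events, "manifest", exact = TRUE)
  if (is.null(m)) {
    abort_data("No manifest attached; was this table made by generate_cohort()?")
  }
  m
}

#' Ready-made synthetic scenarios
#'
#' Configurations mirroring the in vivo settings the pipeline is designed
#' for, with the activation probability and division counts chosen so pooled
#' expectations land near the observed percentages:
#'
#' * `scenario_b_path()` — B-cell maturation under an mb1-driven Cre; 4
#'   cumulative divisions across the pro-B/pre-B windows with `p` solved
#'   from a mature-B labeled fraction of 0.43.
#' * `scenario_vg11_liver_node()` — liver-resident versus circulating
#'   (lymph-node) Vγ1.1 γδ T cells: same activation probability, histories
#'   of 6 versus 2 effective divisions; 3 mice by 3000 cells per group.
#' * `scenario_id3_contrast()` — neonate/adult pairs on wild-type and
#'   Id3-deficient backgrounds: neonates differ in instantaneous cycling
#'   (BrdU) but not history; adults differ in history but cycle less —
#'   the discordance [history_vs_rate_report()] is built to expose.
#'
#' @param n_mice,n_cells Cohort dimensions.
#' @param rho Mouse-level overdispersion.
#' @return A [cohort_config()].
#' @export
scenario_b_path <- function(n_mice = 3, n_cells = 3000, rho = 0.02) {
  k <- sum(b_cell_stages()$divisions) # 4 divisions across proB + preB
  p <- 1 - (1 - 0.43)^(1 / k)
  cohort_config(
    tibble::tibble(group = "matureB", k = k, p = p,
                   cycling_fraction = 0.02),
    n_mice = n_mice, n_cells = n_cells, rho = rho
  )
}

#' @rdname scenario_b_path
#' @export
scenario_vg11_liver_node <- function(n_mice = 3, n_cells = 3000,
                                     rho = 0.02) {
  cohort_config(
    tibble::tibble(
      group = c("liver", "node"), k = c(6, 2), p = 0.1,
      cycling_fraction = c(0.05, 0.05)
    ),
    n_mice = n_mice, n_cells = n_cells, rho = rho
  )
}

#' @rdname scenario_b_path
#' @export
scenario_id3_contrast <- function(n_mice = 3, n_cells = 3000, rho = 0.02) {
  cohort_config(
    tibble::tibble(
      group = c("neonate_wt", "neonate_id3ko", "adult_wt", "adult_id3ko"),
      k = c(4, 4, 3, 6),
      p = 0.1,
      cycling_fraction = c(0.15, 0.30, 0.15, 0.05)
    ),
    n_mice = n_mice, n_cells = n_cells, rho = rho
  )
}
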
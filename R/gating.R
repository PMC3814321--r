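#' Gate an event table into per-mouse labeled-cell counts
#'
#' Thresholds a fluorescence channel on the log scale and tallies positive
#' cells per mouse — the in-silico analogue of drawing a region gate on a
#' FACS plot. Threshold policies:
#'
#' * `"midpoint"` (default) — midpoint of the two mixture component log-means
#'   recorded in the cohort's manifest; falls back to Otsu when no manifest
#'   is attached.
#' * `"otsu"` — Otsu's between-class variance maximization on the log
#'   intensities (no ground-truth knowledge used).
#' * a number — explicit threshold on the raw intensity scale.
#'
#' When the mixture components are poorly separated (under 2 standard
#' deviations between log-means) a classed warning
#' (`tlox_separability_warning`) is raised, since gate placement then
#' materially affects the counts. If the table carries `true_label`, the
#' achieved misclassification rate is reported in the gate summary.
#'
#' @param events An event table from [generate_cohort()] (or any data frame
#'   with `group`, `mouse` and the intensity column).
#' @param policy `"midpoint"`, `"otsu"`, or a numeric threshold.
#' @param channel Intensity column to gate on; default
#'   `"tdtomato_intensity"`.
#' @return A tibble of per-mouse counts (`group`, `mouse`, `n_labeled`,
#'   `n_total`) of class `tlox_gates`; diagnostics via [gate_summary()].
#' @examples
#' cfg <- cohort_config(tibble::tibble(group = "g", k = 2, p = 0.25),
#'                      n_mice = 3, n_cells = 500)
#' gates <- gate_events(generate_cohort(cfg, seed = 1))
#' gate_summary(gates)
#' @export
gate_events <- function(events, policy = "midpoint",
                        channel = "tdtomato_intensity") {
  if (!is.data.frame(events) || nrow(events) == 0) {
    abort_data("`events` must be a non-empty data frame.")
  }
  if (!channel %in% names(events)) {
    abort_data(sprintf("Intensity column `%s` is missing.", channel))
  }
  if (!all(c("group", "mouse") %in% names(events))) {
    abort_data("`events` needs `group` and `mouse` columns.")
  }
  if (any(events[[channel]] <= 0)) {
    abort_data("Intensities must be positive (log-scale gating).")
  }
  logx <- log(events[[channel]])

  manifest <- attr(events, "manifest", exact = TRUE)
  if (is.numeric(policy)) {
    threshold_log <- log(policy)
    policy_used <- "manual"
  } else {
    policy_used <- rlang::arg_match0(policy, c("midpoint", "otsu"))
    if (policy_used == "midpoint" && is.null(manifest)) policy_used <- "otsu"
    threshold_log <- if (policy_used == "midpoint") {
      im <- manifest$config$intensity
      (im$td_meanlog_neg + im$td_meanlog_pos) / 2
    } else {
      otsu_threshold(logx)
    }
  }

  if (!is.null(manifest)) {
    im <- manifest$config$intensity
    sep <- (im$td_meanlog_pos - im$td_meanlog_neg) / im$td_sdlog
    if (sep < 2) {
      warn_tlox(sprintf(
        "Mixture components are only %.2f log-sd apart; gating is unreliable.",
        sep
      ), class = "tlox_separability_warning")
    }
  }

  pos <- logx > threshold_log
  tallies <- tibble::tibble(
    group = events$group, mouse = events$mouse, pos = pos
  )
  out <- dplyr::summarise(
    dplyr::group_by(tallies, .data$group, .data$mouse),
    n_labeled = sum(.data$pos),
    n_total = dplyr::n(),
    .groups = "drop"
  )
  error_rate <- if ("true_label" %in% names(events)) {
    mean(pos != events$true_label)
  } else {
    NA_real_
  }
  attr(out, "gate") <- list(
    channel = channel, policy = policy_used,
    threshold = exp(threshold_log), threshold_log = threshold_log,
    error_rate = error_rate
  )
  class(out) <- c("tlox_gates", class(out))
  out
}

#' @rdname gate_events
#' @param gates A `tlox_gates` table.
#' @export
gate_summary <- function(gates) {
  g <- attr(gates, "gate", exact = TRUE)
  if (is.null(g)) abort_data("No gate metadata attached.")
  g
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}
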
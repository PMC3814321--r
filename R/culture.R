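#' Division schedule for asynchronous culture
#'
#' Describes an unsynchronized culture growing exponentially: each cell
#' divides after an exponential waiting time with mean
#' `doubling_time / ln 2`, so the population doubles every `doubling_time`
#' hours on average and cells accumulate fractional expected generations.
#' Cre becomes active at `cre_start` hours; divisions completed before that
#' can never activate the reporter (e.g. the lag between viral transduction
#' and Cre expression).
#'
#' @param doubling_time Population doubling time in hours (> 0); 17 h is a
#'   typical figure for NIH3T3 fibroblasts.
#' @param duration Length of the culture in hours.
#' @param cre_start Time at which Cre activity begins, hours.
#' @return A `tlox_schedule` list.
#' @export
division_schedule <- function(doubling_time = 17, duration = 48,
                              cre_start = 0) {
  check_scalar_number(doubling_time, "doubling_time")
  if (doubling_time <= 0) abort_model("`doubling_time` must be positive.")
  check_scalar_number(duration, "duration", lower = 0)
  check_scalar_number(cre_start, "cre_start", lower = 0)
  structure(
    list(doubling_time = doubling_time, duration = duration,
         cre_start = cre_start),
    class = "tlox_schedule"
  )
}

#' Simulate labeling kinetics in an asynchronous culture
#'
#' Event-driven branching process: division events occur at total rate
#' `N * ln(2) / doubling_time`; the dividing cell is chosen uniformly, and
#' its daughters' states are drawn from the division model (crossover only
#' once Cre is active). Tracks the joint distribution of array size (or
#' label flag) and generation number, so the emitted time series carries both
#' the labeled fraction and the mean generation.
#'
#' @param schedule A [division_schedule()].
#' @param params A [tlox_params()] object.
#' @param n_cells Initial number of (unlabeled) cells.
#' @param sample_times Times (hours) at which to record the population;
#'   defaults to hourly from 0 to `duration`.
#' @param seed Optional integer seed.
#' @return A tibble of class `tlox_culture` with columns `time_h`,
#'   `generation` (population mean), `n_cells`, `n_labeled`,
#'   `labeled_fraction`.
#' @examples
#' sched <- division_schedule(doubling_time = 17, duration = 48)
#' simulate_culture(sched, tlox_params("exact", c = 1), n_cells = 500, seed = 1)
#' @export
simulate_culture <- function(schedule, params = tlox_params(),
                             n_cells = 1000, sample_times = NULL,
                             seed = NULL) {
  if (!inherits(schedule, "tlox_schedule")) {
    if (is.list(schedule)) schedule <- do.call(division_schedule, schedule)
    else abort_config("`schedule` must come from division_schedule().")
  }
  params <- as_tlox_params(params)
  check_scalar_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  if (is.null(sample_times)) {
    sample_times <- seq(0, schedule$duration, by = 1)
  }
  sample_times <- sort(unique(c(0, sample_times[sample_times <= schedule$duration],
                                schedule$duration)))
  local_seed_if(seed)

  rate <- log(2) / schedule$doubling_time
  n_states <- if (params$variant == "exact") params$n_max else 2L
  M_on <- if (params$variant == "exact") {
    multiplicity_transition_matrix(params$c, params$n_max)
  } else NULL

  # counts[state, generation + 1]; grown columnwise as generations appear
  counts <- matrix(0, nrow = n_states, ncol = 1L)
  start_state <- if (params$variant == "exact") 2L else 2L # state 1 = labeled
  counts[start_state, 1L] <- n_cells

  t <- 0
  out <- vector("list", length(sample_times))
  next_sample <- 1L

  record_upto <- function(time_now) {
    while (next_sample <= length(sample_times) &&
           sample_times[next_sample] <= time_now + 1e-12) {
      N <- sum(counts)
      lab <- sum(counts[1L, ])
      gens <- seq_len(ncol(counts)) - 1L
      out[[next_sample]] <<- tibble::tibble(
        time_h = sample_times[next_sample],
        generation = sum(colSums(counts) * gens) / N,
        n_cells = N, n_labeled = lab, labeled_fraction = lab / N
      )
      next_sample <<- next_sample + 1L
    }
  }

  repeat {
    N <- sum(counts)
    dt <- stats::rexp(1L, rate * N)
    t_next <- t + dt
    if (t_next > schedule$duration) {
      record_upto(schedule$duration)
      break
    }
    record_upto(t_next - 1e-9)
    t <- t_next
    cre_on <- t >= schedule$cre_start

    idx <- sample.int(length(counts), 1L, prob = as.numeric(counts))
    s <- (idx - 1L) %% n_states + 1L
    g <- (idx - 1L) %/% n_states + 1L
    if (g + 1L > ncol(counts)) counts <- cbind(counts, 0)
    counts[s, g] <- counts[s, g] - 1

    if (params$variant == "exact") {
      if (s == 1L || !cre_on) {
        d <- c(s, s)
      } else {
        d <- sample.int(n_states, 2L, replace = TRUE, prob = M_on[s, ])
      }
    } else {
      if (s == 1L) {
        d <- c(1L, 1L)
      } else if (cre_on) {
        d <- ifelse(stats::runif(2L) < params$p, 1L, 2L)
      } else {
        d <- c(2L, 2L)
      }
    }
    counts[d[1L], g + 1L] <- counts[d[1L], g + 1L] + 1
    counts[d[2L], g + 1L] <- counts[d[2L], g + 1L] + 1
  }

  res <- dplyr::bind_rows(out)
  attr(res, "params") <- params
  attr(res, "schedule") <- schedule
  class(res) <- c("tlox_culture", class(res))
  res
}
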
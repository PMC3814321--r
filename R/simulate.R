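#' Divide a table of cells one generation forward
#'
#' Takes a tibble of cells and returns the tibble of their daughters (two rows
#' per parent, linked by `parent_id`). In the exact variant each parent's
#' sisters recombine with probability `c` at a uniformly chosen pairing and
#' the two (anti-correlated) products are assigned to the daughters at
#' random; a labeled parent (single loxP) breeds true. In the simplified
#' variant each daughter of an unlabeled parent is labeled independently with
#' probability `p`; labeled parents yield labeled daughters. Labeling never
#' reverts in either variant.
#'
#' @param cells A tibble with columns `lox_count`, `labeled`, `generation`
#'   (as produced by [new_cells()] or a previous call). Extra columns are
#'   dropped.
#' @param params A [tlox_params()] object.
#' @param seed Optional integer seed (scoped; the caller's RNG stream is
#'   restored afterwards).
#' @return A tibble of daughters: `parent_id`, `lox_count`, `labeled`,
#'   `generation`.
#' @examples
#' simulate_division(new_cells(5), tlox_params("exact", c = 1), seed = 1)
#' @export
simulate_division <- function(cells, params = tlox_params(), seed = NULL) {
  params <- as_tlox_params(params)
  if (!is.data.frame(cells) || nrow(cells) == 0) {
    abort_data("`cells` must be a non-empty data frame.")
  }
  needed <- c("lox_count", "labeled", "generation")
  if (!all(needed %in% names(cells))) {
    abort_data("`cells` needs columns lox_count, labeled, generation.")
  }
  if (any(cells$lox_count < 1)) abort_data("lox_count must be >= 1.")
  local_seed_if(seed)

  n <- nrow(cells)
  parent_id <- rep(seq_len(n), each = 2L)
  gen <- rep(cells$generation + 1L, each = 2L)

  if (params$variant == "simplified") {
    lab_parent <- rep(cells$labeled, each = 2L)
    lab <- lab_parent | (stats::runif(2L * n) < params$p)
    daughters <- tibble::tibble(
      parent_id = parent_id,
      lox_count = rep(cells$lox_count, each = 2L),
      labeled = lab,
      generation = gen
    )
    return(daughters)
  }

  s <- cells$lox_count
  cross <- stats::runif(n) < params$c & s > 1L
  # uniform pairing (i, j) on 1..s x 1..s for parents that recombine
  i <- ifelse(cross, 1L + floor(stats::runif(n) * s), NA_integer_)
  j <- ifelse(cross, 1L + floor(stats::runif(n) * s), NA_integer_)
  d1 <- ifelse(cross, i + s - j, s)
  d2 <- ifelse(cross, j + s - i, s)
  swap <- stats::runif(n) < 0.5
  first <- ifelse(swap, d2, d1)
  second <- ifelse(swap, d1, d2)
  lox <- as.integer(rbind(first, second))
  tibble::tibble(
    parent_id = parent_id,
    lox_count = lox,
    labeled = lox == 1L,
    generation = gen
  )
}

#' Fresh unlabeled cells carrying the tandem cassette
#'
#' @param n Number of cells.
#' @param lox_count Initial array size (default 2, the Tlox cassette).
#' @return A tibble usable with [simulate_division()].
#' @export
new_cells <- function(n, lox_count = 2L) {
  check_scalar_number(n, "n", lower = 1, integer = TRUE)
  check_scalar_number(lox_count, "lox_count", lower = 1, integer = TRUE)
  tibble::tibble(
    lox_count = rep(as.integer(lox_count), n),
    labeled = lox_count == 1L,
    generation = 0L
  )
}

#' Simulate label accumulation across synchronous generations
#'
#' Branching-process simulation of a population of initially unlabeled cells
#' dividing `k` times with Cre active throughout. Two engines are provided
#' and agree on population-level fractions:
#'
#' * `"population"` — tracks only counts per array-size state and samples
#'   each daughter's size from the marginal distribution (daughters' fates
#'   are exchangeable, so population fractions are unaffected by dropping
#'   the sister pairing). Memory is O(`n_max`), so 10^5+ cells are cheap.
#' * `"tree"` — tracks explicit cells with anti-correlated sister products,
#'   for lineage-level statistics. Populations double every generation, so
#'   `"auto"` (the default) uses the tree engine only while the final
#'   population stays below `tree_limit` and otherwise switches to the
#'   population engine.
#'
#' @param n_cells Initial population size.
#' @param k Number of generations.
#' @param params A [tlox_params()] object.
#' @param mode `"auto"`, `"population"` or `"tree"`.
#' @param tree_limit Cell-count ceiling for the tree engine.
#' @param seed Optional integer seed.
#' @return A tibble of class `tlox_sim`, one row per generation `0..k`:
#'   `generation`, `n_cells`, `n_labeled`, `labeled_fraction`, and (exact
#'   variant) a list-column `lox_hist` of array-size histograms whose counts
#'   sum to `n_cells`. The analytic expectation is attached as attribute
#'   `expected` for plotting.
#' @examples
#' simulate_population(1e4, 3, tlox_params("exact", c = 1), seed = 1)
#' @export
simulate_population <- function(n_cells, k, params = tlox_params(),
                                mode = c("auto", "population", "tree"),
                                tree_limit = 2e4, seed = NULL) {
  check_scalar_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_scalar_number(k, "k", lower = 0, integer = TRUE)
  params <- as_tlox_params(params)
  mode <- rlang::arg_match(mode)
  local_seed_if(seed)
  k <- as.integer(k)
  n_cells <- as.integer(n_cells)

  final_n <- n_cells * 2^k
  if (mode == "auto") {
    mode <- if (final_n <= tree_limit) "tree" else "population"
  } else if (mode == "tree" && final_n > tree_limit) {
    warn_tlox(
      sprintf(
        "Final population (%.3g cells) exceeds tree_limit; switching to the population engine.",
        final_n
      ),
      class = "tlox_overflow_warning"
    )
    mode <- "population"
  }

  if (mode == "tree") {
    out <- sim_tree(n_cells, k, params)
  } else {
    out <- sim_counts(n_cells, k, params)
  }
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  attr(out, "expected") <- cumulative_label_fraction(0:k, params)
  class(out) <- c("tlox_sim", class(out))
  out
}

sim_tree <- function(n_cells, k, params) {
  cells <- new_cells(n_cells)
  rows <- vector("list", k + 1L)
  rows[[1]] <- summarize_cells(cells, 0L, params)
  g <- 0L
  while (g < k) {
    cells <- simulate_division(cells, params)
    cells$generation <- g + 1L
    g <- g + 1L
    rows[[g + 1L]] <- summarize_cells(cells, g, params)
  }
  dplyr::bind_rows(rows)
}

summarize_cells <- function(cells, generation, params) {
  n <- nrow(cells)
  lab <- sum(cells$labeled)
  row <- tibble::tibble(
    generation = generation, n_cells = n, n_labeled = lab,
    labeled_fraction = lab / n
  )
  if (params$variant == "exact") {
    tab <- table(cells$lox_count)
    row$lox_hist <- list(tibble::tibble(
      lox_count = as.integer(names(tab)), n = as.integer(tab)
    ))
  }
  row
}

sim_counts <- function(n_cells, k, params) {
  if (params$variant == "simplified") {
    U <- n_cells
    L <- 0
    rows <- vector("list", k + 1L)
    rows[[1]] <- tibble::tibble(
      generation = 0L, n_cells = U + L, n_labeled = L,
      labeled_fraction = L / (U + L)
    )
    for (g in seq_len(k)) {
      newly <- stats::rbinom(1L, 2 * U, params$p)
      L <- 2 * L + newly
      U <- 2 * U - newly
      rows[[g + 1L]] <- tibble::tibble(
        generation = g, n_cells = U + L, n_labeled = L,
        labeled_fraction = L / (U + L)
      )
    }
    return(dplyr::bind_rows(rows))
  }

  M <- multiplicity_transition_matrix(params$c, params$n_max)
  counts <- numeric(params$n_max)
  counts[2] <- n_cells
  rows <- vector("list", k + 1L)
  rows[[1]] <- summarize_counts(counts, 0L)
  for (g in seq_len(k)) {
    nxt <- numeric(params$n_max)
    for (s in which(counts > 0)) {
      if (s == 1L) {
        nxt[1] <- nxt[1] + 2 * counts[s]
      } else {
        nxt <- nxt + as.numeric(stats::rmultinom(1L, 2 * counts[s], M[s, ]))
      }
    }
    counts <- nxt
    rows[[g + 1L]] <- summarize_counts(counts, g)
  }
  dplyr::bind_rows(rows)
}

summarize_counts <- function(counts, generation) {
  n <- sum(counts)
  keep <- which(counts > 0)
  tibble::tibble(
    generation = generation, n_cells = n, n_labeled = counts[1],
    labeled_fraction = counts[1] / n,
    lox_hist = list(tibble::tibble(lox_count = keep, n = counts[keep]))
  )
}
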
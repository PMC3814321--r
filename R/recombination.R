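#' Products of one Cre-mediated crossover between sister chromatids
#'
#' After replication, both sister chromatids carry the same `n`-unit tandem
#' loxP array. A single Cre-mediated crossover joins unit `i` on one sister to
#' unit `j` on the other, producing recombinant arrays of `i + n - j` and
#' `j + n - i` units. Equal exchange (`i == j`) leaves both sisters at `n`;
#' unequal exchange produces one shorter and one longer array. Total loxP
#' units are conserved: the two products always sum to `2n`. Intra-array
#' (cis) recombination cannot occur — recombination needs a Cre tetramer
#' bridging two sites, which the overlapping tandem design precludes on a
#' single chromatid — so `n` can never drop to 0.
#'
#' @param n Parental array size (number of tandem loxP units), `n >= 1`.
#' @param i Crossover unit index on sister A, in `1..n`.
#' @param j Crossover unit index on sister B, in `1..n`.
#' @return Integer vector of length 2: the two product array sizes.
#' @examples
#' crossover_products(2, 1, 2)  # unequal: one single-loxP, one triple-loxP
#' crossover_products(5, 3, 3)  # equal exchange: both sisters unchanged
#' @export
crossover_products <- function(n, i, j) {
  check_scalar_number(n, "n", lower = 1, integer = TRUE)
  check_scalar_number(i, "i", integer = TRUE)
  check_scalar_number(j, "j", integer = TRUE)
  if (i < 1 || i > n) {
    abort_model(sprintf("Crossover index i = %d out of range 1..%d.", i, n))
  }
  if (j < 1 || j > n) {
    abort_model(sprintf("Crossover index j = %d out of range 1..%d.", j, n))
  }
  as.integer(c(i + n - j, j + n - i))
}

# Marginal daughter-size distribution as a dense vector over sizes 1..(2n-1).
# P(n + d) = c * (n - |d|) / n^2 for 1 <= |d| <= n - 1; P(n) = (1 - c) + c/n.
daughter_pmf_vec <- function(n, c) {
  probs <- numeric(2L * n - 1L)
  d <- seq_len(max(n - 1L, 0L))
  probs[n] <- (1 - c) + c / n
  if (n > 1L) {
    probs[n - d] <- c * (n - d) / n^2
    probs[n + d] <- c * (n - d) / n^2
  }
  probs
}

#' Marginal distribution of a daughter's loxP array size after one division
#'
#' With probability `1 - c` no crossover occurs and the daughter keeps the
#' parental `n`-unit array. With probability `c` one crossover happens at a
#' pairing `(i, j)` uniform over the `n^2` possibilities, and the daughter
#' inherits either product with probability 1/2. The closed form is
#' `P(n + d) = c (n - |d|) / n^2` for `1 <= |d| <= n - 1` and
#' `P(n) = (1 - c) + c / n`; the support is contained in `1..(2n - 1)` and a
#' size-1 array (reporter ON) arises with probability `c / n^2`.
#'
#' @inheritParams crossover_products
#' @param c Crossover probability per division, in \[0, 1\].
#' @return A tibble with columns `lox_count` and `prob` (zero-probability
#'   sizes omitted), sorted by `lox_count`.
#' @examples
#' daughter_size_pmf(2, c = 1)  # {1: 1/4, 2: 1/2, 3: 1/4}
#' @export
daughter_size_pmf <- function(n, c) {
  check_scalar_number(n, "n", lower = 1, integer = TRUE)
  check_scalar_number(c, "c", lower = 0, upper = 1)
  probs <- daughter_pmf_vec(as.integer(n), c)
  keep <- probs > 0
  tibble::tibble(lox_count = which(keep), prob = probs[keep])
}

#' Probability that one daughter turns the reporter on in a single division
#'
#' Equals the daughter-size distribution evaluated at size 1, i.e. `c / n^2`:
#' only the pairing joining the first unit of one sister to the last unit of
#' the other yields a single-loxP product, and the daughter must inherit it.
#' For the 2-unit cassette at full Cre activity this is 1/4 — the 25%
#' first-cycle ceiling on labeling.
#'
#' @param n Parental array size, `n >= 2` (a size-1 array is already labeled).
#' @param c Crossover probability per division, in \[0, 1\].
#' @return A single probability.
#' @examples
#' activation_probability(2, c = 1)  # 0.25
#' activation_probability(3, c = 1)  # 1/9
#' @export
activation_probability <- function(n, c) {
  check_scalar_number(n, "n", lower = 1, integer = TRUE)
  check_scalar_number(c, "c", lower = 0, upper = 1)
  if (n < 2) {
    abort_model("`n` must be >= 2: a single-loxP array is already labeled.")
  }
  c / n^2
}

#' Transition matrix over loxP array sizes across one division
#'
#' Row `n` is the marginal daughter-size distribution for a parent of size
#' `n`, with probability mass beyond the truncation bound `n_max` accumulated
#' onto state `n_max` (rows remain stochastic; nothing is renormalized away).
#' State 1 — the labeled state — is absorbing: once the array is a single
#' loxP, replication gives two identical single-unit sisters whose only
#' pairing is equal exchange.
#'
#' @param c Crossover probability per division, in \[0, 1\].
#' @param n_max Truncation bound, `>= 3`.
#' @return An `n_max` by `n_max` row-stochastic matrix.
#' @export
multiplicity_transition_matrix <- function(c, n_max = 32L) {
  check_scalar_number(c, "c", lower = 0, upper = 1)
  check_scalar_number(n_max, "n_max", lower = 3, integer = TRUE)
  n_max <- as.integer(n_max)
  M <- matrix(0, n_max, n_max, dimnames = list(seq_len(n_max), seq_len(n_max)))
  M[1, 1] <- 1
  for (n in 2:n_max) {
    probs <- daughter_pmf_vec(n, c)
    upto <- min(length(probs), n_max)
    M[n, seq_len(upto)] <- probs[seq_len(upto)]
    if (length(probs) > n_max) {
      M[n, n_max] <- M[n, n_max] + sum(probs[(n_max + 1L):length(probs)])
    }
  }
  M
}

#' Cumulative labeled fraction after a number of divisions
#'
#' Fraction of a population that has turned the reporter on after `k`
#' Cre-active divisions, starting from unlabeled cells carrying the 2-unit
#' tandem cassette.
#'
#' * Simplified variant: `1 - (1 - p)^k`. `k` may be fractional (effective
#'   generations, e.g. culture time divided by doubling time).
#' * Exact variant: the array-size chain is iterated `k` steps from all mass
#'   on state 2 and the absorbed mass in state 1 is returned; `k` must be a
#'   non-negative integer here.
#'
#' Both variants return 0 at `k = 0` and are non-decreasing in `k` and in the
#' activation parameter.
#'
#' @param k Number of divisions (vectorized).
#' @param params A [tlox_params()] object.
#' @return Numeric vector of labeled fractions, same length as `k`.
#' @examples
#' cumulative_label_fraction(1:2, tlox_params("simplified", p = 0.25))
#' cumulative_label_fraction(2, tlox_params("exact", c = 1))  # 29/72
#' @export
cumulative_label_fraction <- function(k, params = tlox_params()) {
  params <- as_tlox_params(params)
  if (length(k) == 0) return(numeric(0))
  if (any(!is.finite(k)) || any(k < 0)) {
    abort_model("`k` must be non-negative and finite.")
  }
  if (params$variant == "simplified") {
    return(1 - (1 - params$p)^k)
  }
  if (any(k != round(k))) {
    abort_model("The exact variant requires integer division counts `k`.")
  }
  M <- multiplicity_transition_matrix(params$c, params$n_max)
  k <- as.integer(k)
  out <- numeric(length(k))
  ord <- order(k)
  v <- numeric(params$n_max)
  v[2] <- 1
  step <- 0L
  for (idx in ord) {
    while (step < k[idx]) {
      v <- as.numeric(v %*% M)
      step <- step + 1L
    }
    out[idx] <- v[1]
  }
  out
}

#' Analytic labeling curve over divisions
#'
#' Convenience wrapper evaluating [cumulative_label_fraction()] on `0:k_max`
#' and returning a tidy table, ready for plotting or joining against
#' simulation output.
#'
#' @param k_max Largest division count to evaluate.
#' @param params A [tlox_params()] object.
#' @return A tibble with columns `generation`, `fraction`, `variant`, of
#'   class `tlox_curve`.
#' @export
label_curve <- function(k_max, params = tlox_params()) {
  check_scalar_number(k_max, "k_max", lower = 0, integer = TRUE)
  params <- as_tlox_params(params)
  out <- tibble::tibble(
    generation = 0:k_max,
    fraction = cumulative_label_fraction(0:k_max, params),
    variant = params$variant
  )
  class(out) <- c("tlox_curve", class(out))
  out
}
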
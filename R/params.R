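#' Model parameters for Tlox labeling
#'
#' Bundles the parameters governing reporter activation by sister-chromatid
#' exchange. Two model variants are supported and deliberately kept apart:
#'
#' * `"simplified"` — each daughter of an unlabeled dividing cell becomes
#'   labeled independently with probability `p` per division, and labeling is
#'   permanent. This is the per-cycle bookkeeping commonly used for tandem-lox
#'   reporters: the cumulative labeled fraction after `k` divisions is
#'   `1 - (1 - p)^k`, giving 25% after one cycle and 43.75% (reported as 44%)
#'   after two at the maximal `p = 1/4`.
#' * `"exact"` — the full crossover combinatorics on the tandem array: a
#'   2-unit array activates a daughter with probability `c/4` in one division,
#'   but unequal exchange also creates 3-unit (and longer) arrays whose
#'   activation probability per division is lower (`c/n^2`), so the exact
#'   two-cycle maximum is 29/72 ≈ 40.3%, not 43.75%. The two variants bracket
#'   the intended biology and are never collapsed.
#'
#' @param variant `"simplified"` or `"exact"`.
#' @param p Per-daughter activation probability per division (simplified
#'   variant). Bounded above by 1/4 biologically; default `0.25`, the maximum
#'   reachable when Cre is fully active in every S/G2/M.
#' @param c Crossover probability per division given active Cre (exact
#'   variant), in \[0, 1\]. An effective parameter absorbing Cre level,
#'   cassette accessibility and S/G2 duration.
#' @param n_max Truncation bound for the array-length state space of the exact
#'   variant. Mass that would land beyond `n_max` is accumulated onto `n_max`
#'   (rows stay stochastic). The default 32 keeps the truncated mass below
#'   1e-9 for `c = 1` out to 20 divisions.
#' @param seed Optional integer seed recorded alongside the parameters; used
#'   by simulation wrappers when no explicit seed is passed.
#'
#' @return An object of class `tlox_params`.
#' @examples
#' tlox_params()                      # simplified, p = 1/4
#' tlox_params("exact", c = 1)        # full combinatorics, maximal Cre
#' @export
tlox_params <- function(variant = c("simplified", "exact"),
                        p = 0.25, c = 1, n_max = 32L, seed = NULL) {
  variant <- rlang::arg_match(variant)
  check_scalar_number(p, "p", lower = 0, upper = 1, closed_upper = FALSE)
  check_scalar_number(c, "c", lower = 0, upper = 1)
  check_scalar_number(n_max, "n_max", lower = 3, integer = TRUE)
  if (!is.null(seed)) check_scalar_number(seed, "seed", integer = TRUE)
  structure(
    list(variant = variant, p = p, c = c, n_max = as.integer(n_max),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "tlox_params"
  )
}

#' @export
print.tlox_params <- function(x, ...) {
  cat("<tlox_params>\n")
  cat("  variant:", x$variant, "\n")
  if (x$variant == "simplified") {
    cat("  p (per-daughter activation / division):", x$p, "\n")
  } else {
    cat("  c (crossover probability / division):", x$c, "\n")
    cat("  n_max (array-length truncation):", x$n_max, "\n")
  }
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

as_tlox_params <- function(x) {
  if (inherits(x, "tlox_params")) return(x)
  if (is.list(x)) return(do.call(tlox_params, x))
  abort_config("Model parameters must be a `tlox_params` object or a list.")
}
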
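# Classed conditions shared across the package. The command-line wrapper maps
# these onto exit codes, so every user-facing validation failure must go
# through one of them.

abort_config <- function(message, ...) {
  rlang::abort(message, class = "tlox_config_error", ...)
}

abort_data <- function(message, ...) {
  rlang::abort(message, class = "tlox_data_error", ...)
}

abort_model <- function(message, ...) {
  rlang::abort(message, class = "tlox_model_error", ...)
}

warn_tlox <- function(message, class) {
  rlang::warn(message, class = class)
}

# Scoped seeding: functions that take `seed = NULL` leave the caller's RNG
# stream alone when no seed is given, and restore it afterwards otherwise.
local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!rlang::is_scalar_integerish(seed)) {
      abort_config("`seed` must be a single integer or NULL.")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE, closed_upper = TRUE) {
  if (!rlang::is_scalar_double(x) && !rlang::is_scalar_integerish(x)) {
    abort_config(sprintf("`%s` must be a single number.", name))
  }
  if (!is.finite(x)) abort_config(sprintf("`%s` must be finite.", name))
  if (integer && x != round(x)) {
    abort_config(sprintf("`%s` must be an integer.", name))
  }
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (x < lower || !hi_ok) {
    abort_config(sprintf(
      "`%s` must be in [%s, %s%s.", name, format(lower), format(upper),
      if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_count_table <- function(counts, name = "counts",
                              label_col = "n_labeled") {
  if (!is.data.frame(counts) || nrow(counts) == 0) {
    abort_data(sprintf("`%s` must be a non-empty data frame.", name))
  }
  needed <- c("mouse", label_col, "n_total")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    abort_data(sprintf(
      "`%s` is missing column(s): %s.", name, paste(missing, collapse = ", ")
    ))
  }
  if (any(counts$n_total <= 0)) {
    abort_data(sprintf("`%s`: n_total must be positive.", name))
  }
  if (any(counts[[label_col]] < 0 | counts[[label_col]] > counts$n_total)) {
    abort_data(sprintf(
      "`%s`: %s must lie in [0, n_total].", name, label_col
    ))
  }
  invisible(counts)
}
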
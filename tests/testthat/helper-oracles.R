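# Independent brute-force oracles. These deliberately construct recombinant
# arrays by explicit index surgery on unit vectors (mimicking the physical
# exchange of chromatid segments) rather than reusing any closed form from
# the package, so they can serve as a genuinely independent reference.

# One crossover joining unit i of sister A to unit j of sister B: the first
# product is A[1..i] followed by B[(j+1)..n], the second is B[1..j] followed
# by A[(i+1)..n]. Returns the two product sizes.
oracle_crossover_sizes <- function(n, i, j) {
  a <- seq_len(n)
  b <- seq_len(n)
  prod1 <- c(a[seq_len(i)], if (j < n) b[(j + 1):n])
  prod2 <- c(b[seq_len(j)], if (i < n) a[(i + 1):n])
  c(length(prod1), length(prod2))
}

# Marginal daughter-size distribution by exhaustive enumeration of the n^2
# pairings x 2 segregations, plus the no-crossover branch.
oracle_daughter_pmf <- function(n, c) {
  probs <- numeric(2 * n)
  probs[n] <- probs[n] + (1 - c)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sizes <- oracle_crossover_sizes(n, i, j)
      for (s in sizes) {
        probs[s] <- probs[s] + c / n^2 / 2
      }
    }
  }
  keep <- probs > 0
  tibble::tibble(lox_count = which(keep), prob = probs[keep])
}

# Labeled fraction of the four grandchildren of one 2-loxP cell after two
# Cre-active divisions, by exhaustive enumeration of every lineage outcome
# (crossover yes/no, pairing, segregation, at both generations).
oracle_two_cycle_fraction <- function(c) {
  # returns list of (prob, daughter sizes) for one division of a size-n cell
  division_outcomes <- function(n) {
    out <- list(list(prob = 1 - c, d = c(n, n)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        sizes <- oracle_crossover_sizes(n, i, j)
        # two segregation orders, each 1/2
        out <- c(out,
                 list(list(prob = c / n^2 / 2, d = sizes),
                      list(prob = c / n^2 / 2, d = rev(sizes))))
      }
    }
    out
  }
  total <- 0
  for (o1 in division_outcomes(2)) {
    if (o1$prob == 0) next
    # expected labeled fraction among each daughter's two children
    frac <- vapply(o1$d, function(m) {
      if (m == 1) return(1) # labeled cells breed true
      acc <- 0
      for (o2 in division_outcomes(m)) {
        acc <- acc + o2$prob * mean(o2$d == 1)
      }
      acc
    }, numeric(1))
    total <- total + o1$prob * mean(frac)
  }
  total
}

# Per-mouse count tables for inference tests.
make_counts <- function(fractions, n_total = 1000, prefix = "m") {
  tibble::tibble(
    mouse = paste0(prefix, seq_along(fractions)),
    n_labeled = round(fractions * n_total),
    n_total = n_total
  )
}
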
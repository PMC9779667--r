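# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-statements of the definitions, kept free of any
# package code paths.

# Benjamini-Hochberg step-up, straight from the definition: sort ascending,
# multiply p_(i) by m/i, enforce monotonicity from the largest rank down,
# cap at 1, return in input order.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Isodiametric run from the QC: walk until the first cell longer than wide.
iso_brute_force <- function(lengths, widths) {
  n <- 0L
  for (i in seq_along(lengths)) {
    if (lengths[i] > widths[i]) break
    n <- n + 1L
  }
  n
}

# Transition span: first longer-than-wide cell, extended while each next
# cell is under 150% of its predecessor.
transition_brute_force <- function(lengths, widths, factor = 1.5) {
  start <- 0L
  for (i in seq_along(lengths)) {
    if (lengths[i] > widths[i]) { start <- i; break }
  }
  if (start == 0L) return(0L)
  n <- 1L
  i <- start + 1L
  while (i <= length(lengths) && lengths[i] < factor * lengths[i - 1L]) {
    n <- n + 1L
    i <- i + 1L
  }
  n
}

# Random cell file for the scan oracles: lengths/widths drawn so both
# isodiametric and elongated cells are common.
random_cell_file <- function(n) {
  list(lengths = stats::runif(n, 2, 20), widths = stats::runif(n, 4, 12))
}

# Standard small screen: one wild type plus one mutant of the given class.
screen_pair <- function(class, n_per_group = 40, seed = 1, mutant_id = "mut") {
  gts <- list(
    genotype_spec("wt", "wt", "normal"),
    genotype_spec(mutant_id, "wt", class)
  )
  generate_screen_dataset(gts, n_per_group = n_per_group, seed = seed)
}
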
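# Independent brute-force oracles. These deliberately avoid the package's
# evaluator/detector code paths: everything is explicit enumeration.

# Naive rule evaluator over a token vector: terms by linear scan, phrases by
# trying every start position, AND/OR by collecting child values.
oracle_eval <- function(node, toks) {
  if (node$kind == "term") {
    found <- FALSE
    for (i in seq_along(toks)) {
      if (identical(toks[[i]], node$token)) found <- TRUE
    }
    return(found)
  }
  if (node$kind == "phrase") {
    k <- length(node$tokens)
    n <- length(toks)
    i <- 1L
    while (i + k - 1L <= n) {
      same <- TRUE
      for (j in seq_len(k)) {
        if (!identical(toks[[i + j - 1L]], node$tokens[[j]])) same <- FALSE
      }
      if (same) return(TRUE)
      i <- i + 1L
    }
    return(FALSE)
  }
  vals <- logical(0)
  for (ch in node$children) vals <- c(vals, oracle_eval(ch, toks))
  if (node$kind == "and") all(vals) else any(vals)
}

FUZZ_ALPHABET <- c("a", "b", "c", "d", "e", "f")

# Random rule AST, depth-limited; leaves drawn from a small alphabet so that
# matches and non-matches both occur often.
random_rule <- function(depth = 3L) {
  kind <- if (depth <= 0L) {
    sample(c("term", "phrase"), 1L)
  } else {
    sample(c("term", "phrase", "and", "or"), 1L, prob = c(0.3, 0.2, 0.25, 0.25))
  }
  if (kind == "term") {
    return(structure(list(kind = "term", token = sample(FUZZ_ALPHABET, 1L)),
                     class = "mce_rule"))
  }
  if (kind == "phrase") {
    k <- sample(1:3, 1L)
    return(structure(
      list(kind = "phrase", tokens = sample(FUZZ_ALPHABET, k, replace = TRUE)),
      class = "mce_rule"))
  }
  n_children <- sample(2:3, 1L)
  ch <- lapply(seq_len(n_children), function(i) random_rule(depth - 1L))
  structure(list(kind = kind, children = ch), class = "mce_rule")
}

random_tokens <- function(max_len = 12L) {
  n <- sample(0:max_len, 1L)
  if (n == 0L) character(0) else sample(FUZZ_ALPHABET, n, replace = TRUE)
}

# Linear-scan detector oracle: walk the counts, fire at the first bin whose
# count reaches the threshold; NA when none does.
oracle_first_crossing <- function(counts, threshold) {
  for (m in seq_along(counts)) {
    if (counts[[m]] >= threshold) return(m)
  }
  NA_integer_
}

# Fine-grained Riemann-sum oracle for the expected count of bin m under a
# burst spec's intensity function.
riemann_bin_mass <- function(spec, m, steps = 20000L) {
  t <- seq(m - 1, m, length.out = steps + 1L)
  lam <- intensity(t, spec)
  sum((lam[-1L] + lam[-length(lam)]) / 2) * (1 / steps)
}

riemann_first_crossing <- function(spec, threshold) {
  for (m in seq_len(floor(spec$duration))) {
    if (riemann_bin_mass(spec, m) >= threshold) return(m)
  }
  NA_integer_
}

# Brute-force milestone scan: first minute whose cumulative count reaches
# p% of the 60-minute total.
oracle_milestone <- function(counts60, percent) {
  total <- 0L
  for (m in 1:60) total <- total + counts60[[m]]
  if (total == 0L) return(NA_integer_)
  run <- 0
  for (m in 1:60) {
    run <- run + counts60[[m]]
    if (run >= percent / 100 * total) return(m)
  }
  NA_integer_
}
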
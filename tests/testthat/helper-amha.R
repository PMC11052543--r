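# shared fixtures and independent oracles, all built in code

# minimal two-wave panel over persons a..d
tiny_panel <- function() {
  recs <- expand.grid(person_id = c("a", "b", "c", "d"), wave = 1:2,
                      stringsAsFactors = FALSE)
  recs$midpoint_year <- 1980 + (recs$wave - 1) * 4
  recs$sex <- c(a = "female", b = "male", c = "female", d = "male")[recs$person_id]
  recs$age <- 40
  # a: A->A, b: M->H, c: H->M, d: M->M
  drinks <- rbind(c(a = 0, b = 5, c = 20, d = 3),
                  c(a = 0, b = 30, c = 5, d = 4))
  recs$drinks_per_week <-
    drinks[cbind(recs$wave, match(recs$person_id, colnames(drinks)))]
  state_panel(recs)
}

tiny_network <- function(relations = NULL) {
  edges <- data.frame(source = c("a", "b", "c"),
                      target = c("b", "c", "d"),
                      stringsAsFactors = FALSE)
  if (!is.null(relations)) edges$relation <- relations
  social_network(edges)
}

# a small evolved scenario shared by several files (cached per session)
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_scenario(scenario_config(n_persons = 600, n_waves = 5,
                                               seed = 42))
    cache
  }
})

# all permutations of 1..n (n <= 7), for exhaustive label-shuffle oracles
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force expected same/cross-state edge counts under exhaustive label
# permutation (fixed graph); integer-coded for speed so n = 8 stays cheap
brute_expected_counts <- function(el, labels) {
  n <- length(labels)
  states <- c("A", "M", "H")
  lab_int <- match(labels, states)
  perms <- permutations(n)
  acc9 <- numeric(9)
  for (r in seq_len(nrow(perms))) {
    lab <- lab_int[perms[r, ]]
    a <- lab[el[, 1]]; b <- lab[el[, 2]]
    code <- (pmin(a, b) - 1L) * 3L + pmax(a, b)
    acc9 <- acc9 + tabulate(code, 9)
  }
  tab <- matrix(acc9 / nrow(perms), 3, 3, byrow = TRUE,
                dimnames = list(states, states))   # tab[lo, hi]
  sym <- tab + t(tab); diag(sym) <- diag(tab)
  sym
}

# closed-form OLS on (x, y): returns c(intercept, slope)
ols_closed_form <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(mean(y) - sl * mean(x), sl)
}

# direct textbook chi-squared statistic on a contingency table
chisq_formula <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# build an amha_transitions data.frame by hand
make_transitions <- function(from, to, n_A = 0, n_M = 0, n_H = 0,
                             wave = 1, interval = 4) {
  df <- data.frame(person_id = sprintf("x%04d", seq_along(from)),
                   wave = wave, wave_next = wave + 1,
                   from_state = from, to_state = to,
                   n_A = n_A, n_M = n_M, n_H = n_H,
                   interval_years = interval, stringsAsFactors = FALSE)
  structure(df, n_skipped = 0L, class = c("amha_transitions", "data.frame"))
}
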
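# shared fixtures: tiny hand-built parameter sets and traces, all generated
# in code at test time

mk1 <- function(v) matrix(v, 1, 1)

# one orbital per base, levels spaced for easy discrimination
single_level_params <- function(levels = c(A = -5.0, C = -5.2, G = -4.8, T = -5.4),
                                coupling = 0.05) {
  onsite <- lapply(levels, mk1)
  keys <- c("A:A", "A:C", "A:G", "A:T", "C:C", "C:G", "C:T", "G:G", "G:T", "T:T")
  coup <- setNames(lapply(keys, function(k) mk1(coupling)), keys)
  fragment_parameter_set("DNA", onsite, coup)
}

# A and C electronically identical in isolation, distinguished only through
# their very different coupling to G -- the constructed worst case for
# single-current calling that pair correlations resolve
degenerate_ac_params <- function() {
  onsite <- list(A = mk1(-5.3), C = mk1(-5.3), G = mk1(-5.0), T = mk1(-5.7))
  coup <- list("A:A" = mk1(0.05), "A:C" = mk1(0.05), "A:G" = mk1(0.25),
               "A:T" = mk1(0.05), "C:C" = mk1(0.05), "C:G" = mk1(0.02),
               "C:T" = mk1(0.05), "G:G" = mk1(0.05), "G:T" = mk1(0.05),
               "T:T" = mk1(0.05))
  fragment_parameter_set("DNA", onsite, coup)
}

# a current trace without running transport (for counting/IO logic)
fake_trace <- function(symbols, currents = 10^runif(length(symbols), -8, -6)) {
  tr <- data.frame(site = seq_along(symbols), base = symbols,
                   current = currents, stringsAsFactors = FALSE)
  attr(tr, "electrode") <- electrode_pair("Al")
  attr(tr, "bias") <- bias_spec(0.1)
  attr(tr, "sequence_id") <- "fake"
  class(tr) <- c("current_trace", "data.frame")
  tr
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nucleotide_sequence(sample(c("A", "C", "G", "T"), n, replace = TRUE))
}

expect_symmetric <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
}
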
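# training-set generation, symmetry-class counting and density estimation

test_that("reversal-class counting gives the combinatorial class numbers", {
  expect_identical(count_independent_pdfs(1), 4L)
  expect_identical(count_independent_pdfs(2), 10L)
  expect_identical(count_independent_pdfs(3), 40L)
  expect_identical(count_independent_pdfs(2, alphabet_size = 1), 1L)
  expect_identical(count_independent_pdfs(3, alphabet_size = 2), 6L)
  expect_error(count_independent_pdfs(4), "unsupported order")
})

test_that("training sequences follow the calibration protocol", {
  cfg <- calibration_config(seed = 11)
  seqs <- generate_training_sequences(cfg)
  expect_length(seqs, 150)
  expect_true(all(vapply(seqs, length, integer(1)) == 200))
  polys <- Filter(Negate(is.null), lapply(seqs, attr, "polyx"))
  expect_length(polys, 30)
  runs <- vapply(polys, `[[`, integer(1), "length")
  expect_true(all(runs >= 3 & runs <= 20))
  # poly base cycles over the alphabet
  expect_equal(sort(unique(vapply(polys, `[[`, character(1), "base"))),
               c("A", "C", "G", "T"))
  # seeded determinism
  seqs2 <- generate_training_sequences(calibration_config(seed = 11))
  expect_identical(lapply(seqs, `[[`, "symbols"), lapply(seqs2, `[[`, "symbols"))
  # uniform composition: each base frequency within 3 sigma of 1/4
  tab <- table(unlist(lapply(seqs, `[[`, "symbols")))
  n <- 150 * 200
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(tab - n / 4) < 3 * sigma))
})

test_that("observation counting and symmetry pooling are exact", {
  s <- nucleotide_sequence("GAC")
  tr <- fake_trace(s$symbols, c(1e-7, 2e-7, 3e-7))
  store <- collect_observations(list(s), list(tr))
  expect_equal(store$counts$singles, 3L)
  expect_equal(store$counts$pairs, 2L)
  expect_equal(store$counts$triples, 1L)

  # (G,A) reading (i1, i2) lands in the class of (A,G) reading (i2, i1)
  s1 <- nucleotide_sequence("GA"); t1 <- fake_trace(s1$symbols, c(1e-7, 2e-7))
  s2 <- nucleotide_sequence("AG"); t2 <- fake_trace(s2$symbols, c(2e-7, 1e-7))
  st <- collect_observations(list(s1, s2), list(t1, t2))
  expect_named(st$pairs, "AG")
  expect_equal(st$pairs$AG[1, ], st$pairs$AG[2, ])

  # homopairs contribute the mirrored reading too
  s3 <- nucleotide_sequence("AA"); t3 <- fake_trace(s3$symbols, c(1e-7, 4e-7))
  st3 <- collect_observations(list(s3), list(t3))
  expect_equal(nrow(st3$pairs$AA), 2)
  expect_equal(st3$pairs$AA[1, ], rev(st3$pairs$AA[2, ]))

  # palindromic triples mirrored as well; reversed triples share a class
  s4 <- nucleotide_sequence("GAG"); t4 <- fake_trace(s4$symbols, c(1e-7, 2e-7, 3e-7))
  st4 <- collect_observations(list(s4), list(t4))
  expect_named(st4$triples, "GAG")
  expect_equal(nrow(st4$triples$GAG), 2)

  expect_error(collect_observations(list(s), list(fake_trace(c("G", "A")))),
               "length mismatch")
})

test_that("the full protocol yields 30,000 single observations (counting logic)", {
  cfg <- calibration_config(seed = 11)
  seqs <- generate_training_sequences(cfg)
  traces <- lapply(seqs, function(s) fake_trace(s$symbols))
  store <- collect_observations(seqs, traces)
  expect_identical(store$counts$singles, 30000L)
  expect_identical(store$counts$singles, cfg$n_sequences * cfg$sequence_length)
  # every pair/triple class is populated and counts match site combinatorics
  expect_length(store$pairs, 10)
  expect_length(store$triples, 40)
})

test_that("densities are normalized, floored and deterministic", {
  set.seed(5)
  seqs <- lapply(1:6, function(i) random_dna(40))
  traces <- lapply(seqs, function(s) fake_trace(s$symbols))
  store <- collect_observations(seqs, traces)
  pdfs <- build_pdfs(store, grid = list(min_count = 1))
  for (o in 1:3) {
    dens <- switch(o, pdfs$p1, pdfs$p2, pdfs$p3)
    w <- diff(pdfs$edges[[o]][1:2])
    for (d in dens) {
      expect_equal(sum(d) * w^o, 1, tolerance = 1e-6)
      expect_true(all(d >= pdfs$floor * (1 - 1e-9)))
    }
  }
  pdfs2 <- build_pdfs(store, grid = list(min_count = 1))
  expect_identical(pdfs, pdfs2)
})

test_that("a delta-like sample smooths into a single normalized peak", {
  store <- structure(
    list(singles = list(A = rep(-7, 30), C = rep(-6.5, 30),
                        G = rep(-6, 30), T = rep(-5.5, 30)),
         pairs = list(), triples = list(),
         counts = list(singles = 120L, pairs = 0L, triples = 0L),
         alphabet_kind = "DNA"),
    class = "observation_store")
  pdfs <- build_pdfs(store, grid = list(min_count = 1))
  w <- diff(pdfs$edges[[1]][1:2])
  pg <- pdfs$p1$G
  expect_equal(sum(pg) * w, 1, tolerance = 1e-6)
  expect_equal(which.max(pg),
               findInterval(-6, pdfs$edges[[1]], all.inside = TRUE))
})

test_that("under-populated classes are reported by name", {
  s <- nucleotide_sequence("GACT")
  store <- collect_observations(list(s), list(fake_trace(s$symbols)))
  expect_error(build_pdfs(store), "under-populated")
})

test_that("marginalizing a pair density reproduces the raw first-coordinate density", {
  al <- electrode_pair("Al"); bi <- bias_spec(0.1)
  cfg <- calibration_config(8, 60, 2, seed = 3)
  train <- generate_training_sequences(cfg)
  p <- generate_parameter_set("DNA", m = 2, seed = 1)
  traces <- lapply(train, function(s) scan_chain(build_chain(s, p), al, bi))
  store <- collect_observations(train, traces)
  pdfs <- build_pdfs(store, grid = list(min_count = 1))
  gauss_kernel <- function(nb, sig) {
    k <- outer(1:nb, 1:nb, function(i, j) exp(-(i - j)^2 / (2 * sig^2)))
    sweep(k, 2, colSums(k), "/")
  }
  for (key in c("AC", "AG", "CT")) {
    obs <- store$pairs[[key]]
    ed <- pdfs$edges[[2]]; nb <- length(ed) - 1; w <- diff(ed[1:2])
    marg <- rowSums(pdfs$p2[[key]]) * w
    cnt <- hist(obs[, 1], breaks = ed, plot = FALSE)$counts
    bw <- max(sd(obs[, 1]) * nrow(obs)^(-1 / 6) / w, 1)
    oracle <- as.vector(gauss_kernel(nb, bw) %*% cnt)
    oracle <- oracle / (sum(oracle) * w)
    tv <- 0.5 * sum(abs(marg - oracle)) * w
    expect_lt(tv, 0.01)
  }
})

test_that("tunneling median currents follow the HOMO ordering", {
  p <- generate_parameter_set("DNA", m = 5, seed = 1)
  al <- electrode_pair("Al"); bi <- bias_spec(0.1)
  cfg <- calibration_config(6, 60, 0, seed = 7)
  train <- generate_training_sequences(cfg)
  traces <- lapply(train, function(s) scan_chain(build_chain(s, p), al, bi))
  store <- collect_observations(train, traces)
  med <- median_log_currents(store)
  expect_gt(med[["G"]], med[["A"]])
  expect_gt(med[["A"]], med[["T"]])
})
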
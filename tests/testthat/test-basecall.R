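# maximum-likelihood calling, joint-density refinement, fidelity scoring

# deterministic base -> current map turned into a calibration library
separable_library <- function(centers = c(A = -8, C = -7.5, G = -7, T = -6.5),
                              n_train = 40, len = 20, seed = 2) {
  set.seed(seed)
  seqs <- lapply(seq_len(n_train), function(i) random_dna(len))
  traces <- lapply(seqs, function(s) fake_trace(s$symbols, 10^centers[s$symbols]))
  build_pdfs(collect_observations(seqs, traces), grid = list(min_count = 1))
}

test_that("disjoint single-current peaks are recovered exactly", {
  centers <- c(A = -8, C = -7.5, G = -7, T = -6.5)
  pdfs <- separable_library(centers)
  truth <- nucleotide_sequence("GATTACA")
  tr <- fake_trace(truth$symbols, 10^centers[truth$symbols])
  res <- call_p1(tr, pdfs)
  expect_equal(res$called$symbols, truth$symbols)
  expect_equal(res$refinement_order, 1L)
  expect_false(any(res$certain_flags))
  expect_error(call_p1(fake_trace(character(0), numeric(0)), pdfs), "empty")
})

test_that("exact density ties resolve to the alphabetically first base", {
  set.seed(3)
  seqs <- lapply(1:20, function(i) random_dna(10))
  # A and C produce identical currents: their densities coincide exactly
  centers <- c(A = -7.5, C = -7.5, G = -7, T = -6.5)
  traces <- lapply(seqs, function(s) fake_trace(s$symbols, 10^centers[s$symbols]))
  pdfs <- build_pdfs(collect_observations(seqs, traces),
                     grid = list(min_count = 1))
  tr <- fake_trace("C", 10^-7.5)
  expect_equal(call_p1(tr, pdfs)$called$symbols, "A")
})

test_that("P1 calling equals the exhaustive per-site argmax", {
  pdfs <- separable_library()
  set.seed(9)
  tr <- fake_trace(random_dna(30)$symbols, 10^runif(30, -8.4, -6.1))
  res <- call_p1(tr, pdfs)
  alphabet <- c("A", "C", "G", "T")
  oracle <- vapply(log10(tr$current), function(x) {
    dens <- vapply(alphabet, function(b) pdf_eval(pdfs, 1L, b, x), numeric(1))
    alphabet[which.max(dens)]
  }, character(1))
  expect_equal(res$called$symbols, oracle)
})

test_that("a self-consistent call is a refinement fixed point with all sites certain", {
  centers <- c(A = -8, C = -7.5, G = -7, T = -6.5)
  pdfs <- separable_library(centers)
  truth <- nucleotide_sequence("GATCGTA")
  tr <- fake_trace(truth$symbols, 10^centers[truth$symbols])
  p1 <- call_p1(tr, pdfs)
  for (ord in 2:3) {
    res <- refine(tr, pdfs, p1, order = ord)
    expect_equal(res$called$symbols, truth$symbols)
    expect_true(all(res$certain_flags))
    expect_equal(res$iteration_log[1], 0L)
    expect_equal(res$refinement_order, ord)
  }
})

test_that("pair correlations resolve bases that single currents cannot", {
  # A and C are electronically identical in isolation; only their coupling
  # to G differs.  Calibrate with real transport, call a planted 5-mer.
  toy <- degenerate_ac_params()
  al <- electrode_pair("Al"); bi <- bias_spec(0.1)
  set.seed(99)
  train <- lapply(1:80, function(i) random_dna(12))
  traces <- lapply(train, function(s) scan_chain(build_chain(s, toy), al, bi))
  pdfs <- build_pdfs(collect_observations(train, traces),
                     grid = list(min_count = 3))
  truth <- nucleotide_sequence("GACAG")
  tr <- scan_chain(build_chain(truth, toy), al, bi)
  p1 <- call_p1(tr, pdfs)
  expect_lt(fidelity(p1, truth)$fidelity, 1)
  res <- refine(tr, pdfs, p1, order = 2)
  expect_equal(res$called$symbols, truth$symbols)

  # brute-force oracle: enumerate all 4^5 sequences, maximize the summed
  # log pair density over the sliding windows
  alphabet <- c("A", "C", "G", "T")
  li <- log10(tr$current)
  combos <- expand.grid(rep(list(alphabet), 5), stringsAsFactors = FALSE)
  tuple_class <- function(bases) {
    fwd <- paste(bases, collapse = ""); bwd <- paste(rev(bases), collapse = "")
    if (fwd <= bwd) list(key = fwd, flip = FALSE) else list(key = bwd, flip = TRUE)
  }
  score <- apply(combos, 1, function(r) {
    sym <- as.character(r)
    s <- 0
    for (k in 1:4) {
      cl <- tuple_class(sym[k:(k + 1)])
      x <- if (cl$flip) li[c(k + 1, k)] else li[k:(k + 1)]
      s <- s + log(pdf_eval(pdfs, 2L, cl$key, x))
    }
    s
  })
  best <- as.character(unlist(combos[which.max(score), ]))
  expect_equal(res$called$symbols, best)
})

test_that("refinement requires the matching joint densities", {
  pdfs <- separable_library()
  tr <- fake_trace(c("G", "A"), c(1e-7, 1e-8))
  p1 <- call_p1(tr, pdfs)
  pdfs_no3 <- pdfs
  pdfs_no3$p3 <- list()
  expect_error(refine(tr, pdfs_no3, p1, order = 3), "lacks order-3")
})

test_that("fidelity counts matches, masks restrict the sum, confusion rows sum to truth", {
  truth <- nucleotide_sequence("GGGA")
  called <- nucleotide_sequence("GGGA")
  expect_equal(fidelity(called, truth)$fidelity, 1.0)
  called2 <- nucleotide_sequence("GGGT")
  rep2 <- fidelity(called2, truth)
  expect_equal(rep2$fidelity, 0.75)
  expect_equal(rep2$fidelity, 1 - (1 - rep2$fidelity))  # complement = error rate
  expect_equal(rowSums(rep2$per_base_confusion)[["G"]], 3)
  expect_equal(rep2$per_base_confusion["A", "T"], 3 - 2)

  # mask over a planted triplet only
  truth3 <- nucleotide_sequence("AGGGA")
  called3 <- nucleotide_sequence("ATTTA")
  expect_equal(fidelity(called3, truth3, mask = 2:4)$fidelity, 0.0)
  expect_equal(fidelity(called3, truth3)$fidelity, 0.4)
  expect_error(fidelity(nucleotide_sequence("AG"), truth3), "length mismatch")
  expect_error(fidelity(called3, truth3, mask = 4:6), "outside")
})

test_that("BED masks convert 0-based half-open intervals to 1-based sites", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("seq1\t2\t5", "seq1\t7\t8"), path)
  expect_equal(read_bed_mask(path), c(3L, 4L, 5L, 8L))
})

test_that("shifting a base's levels away from the pack raises its recall", {
  al <- electrode_pair("Al"); bi <- bias_spec(0.1)
  recalls <- vapply(c(-5.62, -5.78, -5.95), function(t_level) {
    regime <- default_regime()
    regime$homo_levels[["T"]] <- t_level
    p <- generate_parameter_set("DNA", m = 1, seed = 31, regime = regime)
    set.seed(17)
    train <- lapply(1:12, function(i) random_dna(30))
    traces <- lapply(train, function(s) scan_chain(build_chain(s, p), al, bi))
    pdfs <- build_pdfs(collect_observations(train, traces),
                       grid = list(min_count = 2))
    test_s <- random_dna(60, seed = 18)
    tr <- scan_chain(build_chain(test_s, p), al, bi)
    rep <- fidelity(call_p1(tr, pdfs), test_s)
    conf <- rep$per_base_confusion
    conf["T", "T"] / sum(conf["T", ])
  }, numeric(1))
  expect_gt(recalls[3], recalls[1])
  expect_true(all(diff(recalls) >= -0.05))
})
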
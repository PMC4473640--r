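# Calibration: generate training chains, collect per-base log-current
# observations, and build the non-parametric single/pair/triple joint
# densities (P1, P2, P3) with reading-direction symmetry reduction.
# All densities live on log10-current grids because the structural noise
# spreads the currents over many orders of magnitude.

#' Calibration protocol configuration
#'
#' Defaults follow the calibration protocol: 150 random sequences of 200
#' nucleotides with uniform base composition, 30 of which carry one inserted
#' poly(X) run of length 3-20 to teach the densities about repeats.
#'
#' @param n_sequences Number of training sequences.
#' @param sequence_length Length of each sequence (nt).
#' @param n_polyx_sequences How many sequences receive a poly(X) insertion.
#' @param polyx_length_range Integer pair, inclusive run-length range.
#' @param seed Integer seed for sequence generation.
#' @param alphabet_kind `"DNA"` or `"RNA"`.
#' @param electrode,bias Optional `electrode_pair` / `bias_spec` carried as
#'   provenance.
#' @return A `calibration_config` object.
#' @export
calibration_config <- function(n_sequences = 150L, sequence_length = 200L,
                               n_polyx_sequences = 30L,
                               polyx_length_range = c(3L, 20L),
                               seed = 11L, alphabet_kind = "DNA",
                               electrode = NULL, bias = NULL) {
  stopifnot(n_sequences >= 1, sequence_length >= 1,
            n_polyx_sequences <= n_sequences, n_polyx_sequences >= 0,
            polyx_length_range[1] >= 1,
            polyx_length_range[2] >= polyx_length_range[1])
  if (polyx_length_range[2] > sequence_length) {
    stop("poly(X) run length range exceeds the sequence length")
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         sequence_length = as.integer(sequence_length),
         n_polyx_sequences = as.integer(n_polyx_sequences),
         polyx_length_range = as.integer(polyx_length_range),
         seed = as.integer(seed), alphabet_kind = alphabet_kind,
         electrode = electrode, bias = bias),
    class = "calibration_config"
  )
}

#' Generate the training sequences of the calibration protocol
#'
#' Bases are drawn uniformly; the first `n_polyx_sequences` sequences each
#' receive one poly(X) run at a uniform random position, with X cycling over
#' the alphabet and run length uniform in `polyx_length_range` (the run
#' replaces the bases in place, preserving length).  Deterministic for a
#' fixed seed.
#'
#' @param config A `calibration_config`.
#' @return List of `nucleotide_sequence` objects; sequences with an
#'   insertion carry a `polyx` attribute `list(base, start, length)`.
#' @export
generate_training_sequences <- function(config) {
  alphabet <- tb_alphabet(config$alphabet_kind)
  set.seed(config$seed)
  n <- config$n_sequences
  len <- config$sequence_length
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sym <- sample(alphabet, len, replace = TRUE)
    polyx <- NULL
    if (i <= config$n_polyx_sequences) {
      base <- alphabet[(i - 1L) %% length(alphabet) + 1L]
      run <- sample(seq(config$polyx_length_range[1],
                        config$polyx_length_range[2]), 1L)
      start <- sample(seq_len(len - run + 1L), 1L)
      sym[start:(start + run - 1L)] <- base
      polyx <- list(base = base, start = start, length = run)
    }
    s <- nucleotide_sequence(sym, config$alphabet_kind,
                             id = sprintf("train_%03d", i))
    attr(s, "polyx") <- polyx
    out[[i]] <- s
  }
  out
}

## ---- symmetry classes ----------------------------------------------------

# canonical reading-direction class of an ordered base tuple: the
# lexicographic minimum of the tuple and its reversal.  flip says whether
# the observed orientation had to be reversed to match the canonical one.
tuple_class <- function(bases) {
  fwd <- paste(bases, collapse = "")
  rev_ <- paste(rev(bases), collapse = "")
  if (fwd <= rev_) list(key = fwd, flip = FALSE) else list(key = rev_, flip = TRUE)
}

#' Number of independent joint PDFs under reading-direction reversal
#'
#' Counts equivalence classes of ordered base tuples when a tuple and its
#' reversal are identified (Burnside: (k^n + k^ceil(n/2)) / 2).
#'
#' @param order Tuple length, 1, 2 or 3.
#' @param alphabet_size Number of base symbols (default 4).
#' @return Integer class count (4, 10 and 40 for orders 1-3 over a 4-letter
#'   alphabet).
#' @export
count_independent_pdfs <- function(order, alphabet_size = 4L) {
  if (!order %in% 1:3) stop("unsupported order: ", order)
  k <- alphabet_size
  as.integer((k^order + k^ceiling(order / 2)) / 2)
}

#' Collect per-base current observations into symmetry classes
#'
#' One single observation per site, one pair per adjacent site pair and one
#' triple per adjacent site triple, each in log10 current.  Pair and triple
#' observations are pooled into reading-direction classes (XY with YX
#' reversed, XYZ with ZYX reversed); observations whose orientation is
#' reversed relative to the canonical class orientation are flipped, and
#' palindromic tuples additionally contribute their mirrored reading, so
#' every class density is reversal symmetric.
#'
#' @param sequences List of `nucleotide_sequence` objects.
#' @param traces List of matching `current_trace`s (same order, same
#'   lengths).
#' @return An `observation_store` with fields `singles` (base -> numeric),
#'   `pairs` (class -> 2-column matrix), `triples` (class -> 3-column
#'   matrix), `counts`, `alphabet_kind`.
#' @export
collect_observations <- function(sequences, traces) {
  if (length(sequences) != length(traces)) {
    stop("need one trace per sequence (", length(sequences), " vs ",
         length(traces), ")")
  }
  singles <- list(); pairs <- list(); triples <- list()
  add <- function(store, key, row) {
    store[[key]] <- rbind(store[[key]], row)
    store
  }
  for (i in seq_along(sequences)) {
    sym <- sequences[[i]]$symbols
    tr <- traces[[i]]
    if (length(sym) != nrow(tr)) {
      stop("length mismatch at record ", i, ": sequence ", length(sym),
           " nt vs trace ", nrow(tr), " sites")
    }
    li <- log10(tr$current)
    for (k in seq_along(sym)) {
      singles[[sym[k]]] <- c(singles[[sym[k]]], li[k])
    }
    if (length(sym) >= 2) {
      for (k in seq_len(length(sym) - 1)) {
        cl <- tuple_class(sym[k:(k + 1)])
        obs <- if (cl$flip) li[c(k + 1, k)] else li[k:(k + 1)]
        pairs <- add(pairs, cl$key, obs)
        if (sym[k] == sym[k + 1]) pairs <- add(pairs, cl$key, rev(obs))
      }
    }
    if (length(sym) >= 3) {
      for (k in seq_len(length(sym) - 2)) {
        cl <- tuple_class(sym[k:(k + 2)])
        obs <- if (cl$flip) li[c(k + 2, k + 1, k)] else li[k:(k + 2)]
        triples <- add(triples, cl$key, obs)
        if (sym[k] == sym[k + 2]) triples <- add(triples, cl$key, rev(obs))
      }
    }
  }
  structure(
    list(singles = singles, pairs = pairs, triples = triples,
         counts = list(
           singles = sum(lengths(singles)),
           pairs = sum(vapply(pairs, nrow, integer(1))),
           triples = sum(vapply(triples, nrow, integer(1)))),
         alphabet_kind = sequences[[1]]$alphabet_kind),
    class = "observation_store"
  )
}

## ---- histogram + kernel smoothing ----------------------------------------

# mass-preserving Gaussian smoothing kernel along one grid axis
smoothing_kernel <- function(n_bins, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n_bins))
  k <- outer(seq_len(n_bins), seq_len(n_bins),
             function(i, j) exp(-(i - j)^2 / (2 * sigma_bins^2)))
  sweep(k, 2, colSums(k), "/")     # columns sum to 1: no mass leaks at edges
}

# per-dimension kernel bandwidth: Silverman for d = 1, Scott's
# d-dimensional rate n^(-1/(d+4)) for the joint densities
kde_bandwidth <- function(x, d) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1e-3   # degenerate (delta-like) sample
  fac <- if (d == 1) 1.06 else 1
  fac * s * n^(-1 / (d + 4))
}

smooth_array <- function(arr, kernels) {
  d <- length(dim(arr))
  if (d == 0 || is.null(dim(arr))) return(as.vector(kernels[[1]] %*% arr))
  for (ax in seq_len(d)) {
    perm <- c(ax, setdiff(seq_len(d), ax))
    a <- aperm(arr, perm)
    sh <- dim(a)
    a <- matrix(a, nrow = sh[1])
    a <- kernels[[ax]] %*% a
    dim(a) <- sh
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Build the smoothed joint PDF library from an observation store
#'
#' Each class density is a fine histogram on a shared log10-current grid,
#' smoothed with a Gaussian kernel of Silverman bandwidth per dimension,
#' floored at a small positive constant and normalized to integrate to 1.
#' The 1-D grid spans the observed log-current range padded by `pad`
#' decades; 2-D and 3-D densities share the same span on coarser grids.
#'
#' @param store An `observation_store`.
#' @param grid List of grid settings: `bins` (per-dimension bin counts for
#'   orders 1-3, default `c(200, 200, 120)`), `pad` (decades of padding,
#'   default 0.5), `floor` (density floor, default 1e-12), `min_count`
#'   (minimum observations per class, default 25).
#' @return A `pdf_library` with fields `p1`, `p2`, `p3` (class -> density
#'   array), `edges` (per order), `floor`, `alphabet_kind`.
#' @export
build_pdfs <- function(store, grid = list()) {
  g <- utils::modifyList(
    list(bins = c(200L, 200L, 120L), pad = 0.5, floor = 1e-12, min_count = 25L),
    grid)
  all_obs <- unlist(store$singles, use.names = FALSE)
  rng <- range(all_obs) + c(-g$pad, g$pad)

  short <- c(lapply(store$singles, length),
             lapply(store$pairs, nrow), lapply(store$triples, nrow))
  bad <- short[unlist(short) < g$min_count]
  if (length(bad) > 0) {
    stop("under-populated PDF classes (need >= ", g$min_count, "): ",
         paste(sprintf("%s (%d)", names(bad), unlist(bad)), collapse = ", "))
  }

  edges <- lapply(1:3, function(o) seq(rng[1], rng[2], length.out = g$bins[o] + 1L))

  density_of <- function(x, order) {
    x <- as.matrix(x)
    nb <- g$bins[order]
    ed <- edges[[order]]
    width <- diff(ed[1:2])
    idx <- apply(x, 2, function(col) {
      pmin(pmax(findInterval(col, ed, all.inside = TRUE), 1L), nb)
    })
    idx <- matrix(idx, ncol = order)
    lin <- idx[, 1]
    if (order >= 2) lin <- lin + (idx[, 2] - 1L) * nb
    if (order >= 3) lin <- lin + (idx[, 3] - 1L) * nb * nb
    counts <- tabulate(lin, nbins = nb^order)
    arr <- array(counts, dim = rep(nb, order))
    kernels <- lapply(seq_len(order), function(ax) {
      # joint densities get a one-bin bandwidth floor: their per-class
      # samples are sparse spikes narrower than the grid, which would
      # otherwise stay unsmoothed so that unseen neighbor contexts
      # evaluate at the floor
      sigma_bins <- kde_bandwidth(x[, ax], order) / width
      if (order > 1) sigma_bins <- max(sigma_bins, 1)
      smoothing_kernel(nb, sigma_bins)
    })
    arr <- smooth_array(arr, kernels)
    vol <- width^order
    arr <- arr / (sum(arr) * vol)
    arr <- pmax(arr, g$floor)
    arr <- arr / (sum(arr) * vol)
    array(pmax(arr, g$floor), dim = rep(nb, order))
  }

  p1 <- lapply(store$singles, density_of, order = 1L)
  p2 <- lapply(store$pairs, density_of, order = 2L)
  p3 <- lapply(store$triples, density_of, order = 3L)

  structure(
    list(p1 = p1, p2 = p2, p3 = p3, edges = edges, floor = g$floor,
         bins = g$bins, alphabet_kind = store$alphabet_kind),
    class = "pdf_library"
  )
}

#' Evaluate a class density at a point
#'
#' Nearest-bin lookup on the library grid; points outside the grid are
#' floored onto the edge bins.
#'
#' @param pdfs A `pdf_library`.
#' @param order 1, 2 or 3.
#' @param key Class key (base symbol for order 1, canonical tuple string
#'   otherwise).
#' @param x Numeric vector of length `order`: log10 currents in reading
#'   order matching the canonical class orientation.
#' @return Density value (>= the library floor).
#' @export
pdf_eval <- function(pdfs, order, key, x) {
  dens <- switch(order, pdfs$p1, pdfs$p2, pdfs$p3)[[key]]
  if (is.null(dens)) stop("no order-", order, " density for class ", key)
  nb <- pdfs$bins[order]
  ed <- pdfs$edges[[order]]
  idx <- pmin(pmax(findInterval(x, ed, all.inside = TRUE), 1L), nb)
  dens[matrix(idx, nrow = 1)]
}

#' Pairwise overlap coefficient of the standardized single-current densities
#'
#' Pools all single log10-current observations, standardizes them jointly
#' (removing the overall scale that e.g. the escape rate sets), estimates
#' one density per base on a common grid, and returns the mean pairwise
#' overlap coefficient \eqn{\int \min(p_i, p_j)}.  Larger values mean less
#' distinguishable bases.
#'
#' @param store An `observation_store`.
#' @param n_grid Grid resolution.
#' @return Mean pairwise overlap in `[0, 1]`.
#' @export
p1_overlap_coefficient <- function(store, n_grid = 512L) {
  pooled <- unlist(store$singles, use.names = FALSE)
  mu <- mean(pooled); sdev <- stats::sd(pooled)
  if (sdev == 0) return(1)
  bases <- names(store$singles)
  zs <- lapply(store$singles, function(x) (x - mu) / sdev)
  lo <- min(unlist(zs)) - 1; hi <- max(unlist(zs)) + 1
  grid <- seq(lo, hi, length.out = n_grid)
  dens <- lapply(zs, function(z) {
    d <- stats::density(z, bw = "nrd0", from = lo, to = hi, n = n_grid)
    d$y / (sum(d$y) * diff(grid[1:2]))
  })
  pairs <- utils::combn(seq_along(bases), 2)
  ov <- apply(pairs, 2, function(ij) {
    sum(pmin(dens[[ij[1]]], dens[[ij[2]]])) * diff(grid[1:2])
  })
  mean(ov)
}

#' Median current per base from an observation store
#'
#' @param store An `observation_store`.
#' @return Named numeric vector of median log10 currents.
#' @export
median_log_currents <- function(store) {
  vapply(store$singles, stats::median, numeric(1))
}
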
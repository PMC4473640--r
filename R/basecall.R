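# Base calling from a current trace: per-site maximum likelihood on the
# single-current densities (P1), then iterative conditional maximization on
# the pair/triple joint densities with a certainty/collapse rule, plus
# fidelity scoring.

alphabet_of_library <- function(pdfs) tb_alphabet(pdfs$alphabet_kind)

# density of the local window around site k when site k is hypothesized to
# be `base` and all neighbors carry the identities in `assign`
window_density <- function(pdfs, li, assign, k, base, order) {
  n <- length(li)
  if (order >= 3 && k > 1 && k < n) {
    bases <- c(assign[k - 1], base, assign[k + 1])
    cl <- tuple_class(bases)
    x <- li[(k - 1):(k + 1)]
    if (cl$flip) x <- rev(x)
    return(pdf_eval(pdfs, 3L, cl$key, x))
  }
  if (order >= 2 && n >= 2) {
    if (k < n) { idx <- c(k, k + 1); bases <- c(base, assign[k + 1]) }
    else       { idx <- c(k - 1, k); bases <- c(assign[k - 1], base) }
    cl <- tuple_class(bases)
    x <- li[idx]
    if (cl$flip) x <- rev(x)
    return(pdf_eval(pdfs, 2L, cl$key, x))
  }
  pdf_eval(pdfs, 1L, base, li[k])
}

#' Maximum-likelihood base calling from single-current densities
#'
#' Each site is assigned the base maximizing \eqn{P_X(\log_{10} I_k)}; ties
#' are broken by alphabet order.
#'
#' @param trace A `current_trace`.
#' @param pdfs A `pdf_library`.
#' @return A `call_result` with fields `called` (a `nucleotide_sequence`),
#'   `per_site_scores`, `certain_flags` (all `FALSE` at order 1),
#'   `refinement_order = 1`, `iteration_log`.
#' @export
call_p1 <- function(trace, pdfs) {
  if (nrow(trace) == 0) stop("empty trace")
  alphabet <- alphabet_of_library(pdfs)
  li <- log10(trace$current)
  scores <- vapply(alphabet, function(b) {
    vapply(li, function(x) pdf_eval(pdfs, 1L, b, x), numeric(1))
  }, numeric(length(li)))
  scores <- matrix(scores, nrow = length(li),
                   dimnames = list(NULL, alphabet))
  pick <- apply(scores, 1, which.max)   # first max: lexicographic tie-break
  called <- alphabet[pick]
  structure(
    list(called = nucleotide_sequence(called, pdfs$alphabet_kind,
                                      id = attr(trace, "sequence_id") %||% ""),
         per_site_scores = scores[cbind(seq_along(pick), pick)],
         certain_flags = rep(FALSE, length(pick)),
         refinement_order = 1L,
         iteration_log = integer(0)),
    class = "call_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative joint-density Bayesian refinement of a base call
#'
#' Starting from an initial call, sweeps left to right re-assigning each
#' site to the base maximizing the joint density of the local current
#' window (pair `(I_k, I_{k+1})` at order 2, triple `(I_{k-1}, I_k,
#' I_{k+1})` at order 3; boundary sites fall back to the highest available
#' order) with the neighbor identities fixed to the previous sweep's guess.
#' A site whose guess agrees with the previous sweep is marked certain and
#' frozen -- the collapse rule: its density is treated as a point mass on
#' the agreed base thereafter.  Sweeping stops when a sweep changes nothing
#' or after `max_sweeps`.
#'
#' @param trace A `current_trace`.
#' @param pdfs A `pdf_library` containing the requested order.
#' @param initial A `call_result` (normally from [call_p1()]).
#' @param order 2 or 3.
#' @param max_sweeps Sweep cap.
#' @return A `call_result`; `iteration_log` holds the per-sweep change
#'   counts.
#' @export
refine <- function(trace, pdfs, initial, order = 3L, max_sweeps = 10L) {
  stopifnot(order %in% c(2L, 3L))
  if ((order == 2L && length(pdfs$p2) == 0) ||
      (order == 3L && length(pdfs$p3) == 0)) {
    stop("PDF library lacks order-", order, " densities")
  }
  alphabet <- alphabet_of_library(pdfs)
  li <- log10(trace$current)
  n <- length(li)
  prev <- initial$called$symbols
  certain <- rep(FALSE, n)
  log_changes <- integer(0)
  if (n == 1) {
    res <- initial
    res$refinement_order <- order
    res$certain_flags <- rep(TRUE, 1)
    return(res)
  }
  for (sweep in seq_len(max_sweeps)) {
    new <- prev
    for (k in seq_len(n)) {
      if (certain[k]) next
      dens <- vapply(alphabet, function(b) {
        window_density(pdfs, li, prev, k, b, order)
      }, numeric(1))
      # an observation off every candidate's density support carries no
      # information about this site: keep the current guess rather than
      # letting the tie-break overwrite it
      if (max(dens) > pdfs$floor * (1 + 1e-9)) {
        new[k] <- alphabet[which.max(dens)]
      }
    }
    certain <- certain | (new == prev)
    changes <- sum(new != prev)
    log_changes <- c(log_changes, changes)
    prev <- new
    if (changes == 0) break
  }
  scores <- vapply(seq_len(n), function(k) {
    window_density(pdfs, li, prev, k, prev[k], order)
  }, numeric(1))
  structure(
    list(called = nucleotide_sequence(prev, pdfs$alphabet_kind,
                                      id = initial$called$id),
         per_site_scores = scores,
         certain_flags = certain,
         refinement_order = order,
         iteration_log = log_changes),
    class = "call_result"
  )
}

#' Base-calling fidelity
#'
#' Fraction of sites where the called base equals the true base,
#' \eqn{f = N^{-1}\sum_k (\tilde X_k == X_k)}; the complement is the error
#' rate.  A mask restricts the sum to a site subset (partial fidelity, e.g.
#' over a repeat run).
#'
#' @param called A `call_result` or `nucleotide_sequence`.
#' @param truth A `nucleotide_sequence` (same length).
#' @param mask Optional integer vector of 1-based sites.
#' @return A `fidelity_report` with fields `fidelity`, `n_sites`, `mask`,
#'   `per_base_confusion` (rows = truth, columns = called).
#' @export
fidelity <- function(called, truth, mask = NULL) {
  if (inherits(called, "call_result")) called <- called$called
  stopifnot(inherits(called, "nucleotide_sequence"),
            inherits(truth, "nucleotide_sequence"))
  if (length(called) != length(truth)) {
    stop("length mismatch: called ", length(called), " vs truth ",
         length(truth))
  }
  n <- length(truth)
  if (is.null(mask)) mask <- seq_len(n)
  if (any(mask < 1 | mask > n)) stop("mask contains sites outside 1..", n)
  alphabet <- tb_alphabet(truth$alphabet_kind)
  conf <- table(factor(truth$symbols[mask], levels = alphabet),
                factor(called$symbols[mask], levels = alphabet))
  structure(
    list(fidelity = mean(called$symbols[mask] == truth$symbols[mask]),
         n_sites = length(mask), mask = mask,
         per_base_confusion = unclass(conf)),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> f = %.4f over %d site(s)\n",
              x$fidelity, x$n_sites))
  print(x$per_base_confusion)
  invisible(x)
}

#' Read a BED mask into a 1-based site vector
#'
#' BED intervals are 0-based half-open; a record `chr 2 5` selects 1-based
#' sites 3, 4, 5.
#'
#' @param path BED file (first three columns used).
#' @return Sorted integer vector of 1-based sites.
#' @export
read_bed_mask <- function(path) {
  bed <- utils::read.table(path, stringsAsFactors = FALSE)
  sites <- unlist(lapply(seq_len(nrow(bed)), function(i) {
    seq(bed[i, 2] + 1L, bed[i, 3])
  }))
  sort(unique(as.integer(sites)))
}
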
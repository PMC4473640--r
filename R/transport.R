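# Landauer/Meir-Wingreen transport through one contacted nucleotide in the
# wide-band approximation.  Both electrodes touch the same site block k with
# an energy-independent self-energy Sigma_{L/R} = -i Gamma_{L/R}/2 on all m
# orbitals of that site.  The retarded Green's function of the coupled chain
# is obtained from the eigendecomposition of the bare chain plus a low-rank
# (one site block) update, with dense inversion kept as the test oracle.

# conductance quantum 2e^2/h in siemens == amperes per (2e/h)*eV current unit
CURRENT_UNIT_AMPERES <- 7.748091729e-5

#' Conversion constant from internal current units to amperes
#'
#' Currents are stored in units of (2e/h) x eV; multiplying by this constant
#' (the conductance quantum 2e^2/h = 7.748091729e-5 S) converts to amperes.
#'
#' @return A single number, amperes per internal current unit.
#' @export
current_unit_amperes <- function() CURRENT_UNIT_AMPERES

WORK_FUNCTIONS <- c(Al = 4.08, Gr = 4.60, Au = 5.10, Pt = 5.65)

#' Electrode pair in the wide-band approximation
#'
#' The electrode is characterized by its chemical potential, taken as minus
#' the metal work function (molecular levels are referenced to vacuum), and
#' by energy-independent escape rates Gamma_L/Gamma_R.  Work-function
#' defaults: Al 4.08, Gr 4.60, Au 5.10, Pt 5.65 eV, placing Al/Gr in the
#' molecular gap (tunneling regime) and Au/Pt near the HOMO band (resonant
#' regime) for the default synthetic parameters.
#'
#' @param label `"Al"`, `"Gr"`, `"Au"`, `"Pt"` or `"custom"`.
#' @param work_function Work function in eV; required for `"custom"`,
#'   defaulted from the label otherwise.
#' @param gamma Escape rate (eV) used for both electrodes unless overridden.
#' @param gamma_left,gamma_right Per-electrode escape rates (eV, >= 0).
#' @return An `electrode_pair` object.
#' @export
electrode_pair <- function(label = "custom", work_function = NULL,
                           gamma = 1e-3, gamma_left = gamma,
                           gamma_right = gamma) {
  label <- match.arg(label, c(names(WORK_FUNCTIONS), "custom"))
  if (is.null(work_function)) {
    if (label == "custom") stop("custom electrode needs a work_function")
    work_function <- WORK_FUNCTIONS[[label]]
  }
  stopifnot(is.finite(work_function), gamma_left >= 0, gamma_right >= 0)
  structure(
    list(label = label, work_function = work_function,
         chemical_potential = -work_function,
         gamma_left = gamma_left, gamma_right = gamma_right),
    class = "electrode_pair"
  )
}

#' Bias specification (zero temperature)
#'
#' @param voltage Applied bias in volts (default 0.1).
#' @param split Fraction of the bias assigned to the left electrode:
#'   mu_L = mu + split*eV, mu_R = mu - (1-split)*eV.  Default 0.5
#'   (symmetric drop).
#' @return A `bias_spec` object.
#' @export
bias_spec <- function(voltage = 0.1, split = 0.5) {
  stopifnot(is.finite(voltage), split >= 0, split <= 1)
  structure(list(voltage = voltage, split = split, temperature = 0),
            class = "bias_spec")
}

bias_window <- function(electrode, bias) {
  mu <- electrode$chemical_potential
  c(lower = mu - (1 - bias$split) * bias$voltage,
    upper = mu + bias$split * bias$voltage)
}

site_rows <- function(chain, k) ((k - 1) * chain$m + 1):(k * chain$m)

#' Electrode self-energies for contact at site k
#'
#' Within the wide-band approximation \eqn{\Sigma_{L/R} = -i\Gamma_{L/R}/2}
#' on the m orbitals of the contacted site and zero elsewhere;
#' \eqn{\Gamma_{L/R} = -2\,\mathrm{Im}\,\Sigma_{L/R}}.
#'
#' @param electrode An `electrode_pair`.
#' @param chain A `chain_hamiltonian`.
#' @param k Contacted site (1-based).
#' @return List with complex (n m) x (n m) matrices `sigma_left`,
#'   `sigma_right`.
#' @export
self_energy <- function(electrode, chain, k) {
  if (k < 1 || k > chain$n) stop("site k = ", k, " out of range 1..", chain$n)
  nm <- chain$n * chain$m
  rows <- site_rows(chain, k)
  sl <- matrix(0 + 0i, nm, nm)
  sr <- matrix(0 + 0i, nm, nm)
  diag(sl)[rows] <- -1i * electrode$gamma_left / 2
  diag(sr)[rows] <- -1i * electrode$gamma_right / 2
  list(sigma_left = sl, sigma_right = sr)
}

#' Eigendecomposition of the bare chain (cached transport workspace)
#'
#' @param chain A `chain_hamiltonian`.
#' @return List with eigenvalues `values` and eigenvector matrix `vectors`
#'   of the dense chain Hamiltonian.
#' @export
chain_modes <- function(chain) {
  e <- eigen(assemble_dense(chain), symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

# guarded pole denominators: an energy exactly on a bare eigenvalue would
# give an infinite bare resolvent; the electrode broadening makes the
# coupled G finite there, so a 1e-12 eV clamp keeps the algebra stable
# while perturbing the result only at relative order clamp/Gamma
pole_denominators <- function(e, values, clamp = 1e-12) {
  d <- e - values
  tiny <- abs(d) < clamp
  if (any(tiny)) d[tiny] <- ifelse(d[tiny] >= 0, clamp, -clamp)
  d
}

#' Transmission through the contacted base
#'
#' \eqn{T(E) = \mathrm{Tr}[\Gamma_L^k G \Gamma_R^k G^\dagger]}, evaluated
#' from the site-k block of the coupled Green's function:
#' \eqn{G_{kk} = M (I + i\bar\Gamma M)^{-1}} with \eqn{M} the bare site
#' block and \eqn{\bar\Gamma = (\Gamma_L+\Gamma_R)/2}, so
#' \eqn{T = \Gamma_L \Gamma_R \sum_{\alpha\beta} |G_{kk}|^2}.  Bounded by
#' the orbital count m.
#'
#' @param chain A `chain_hamiltonian`.
#' @param electrode An `electrode_pair`.
#' @param k Contacted site.
#' @param energies Numeric vector of energies (eV).
#' @param modes Optional cached [chain_modes()].
#' @return Numeric vector of transmissions, same length as `energies`.
#' @export
transmission <- function(chain, electrode, k, energies, modes = NULL) {
  if (k < 1 || k > chain$n) stop("site k = ", k, " out of range 1..", chain$n)
  if (is.null(modes)) modes <- chain_modes(chain)
  rows <- site_rows(chain, k)
  uk <- modes$vectors[rows, , drop = FALSE]
  tuk <- t(uk)
  lam <- modes$values
  gbar <- (electrode$gamma_left + electrode$gamma_right) / 2
  pref <- electrode$gamma_left * electrode$gamma_right
  m <- chain$m
  id <- diag(m)
  ne <- length(energies)
  # batch the bare site blocks M(E) = U_k diag(1/(E-lambda)) U_k^T for all
  # requested energies into one BLAS product (quadrature rules call with
  # whole node vectors, so this is the hot path)
  nlam <- length(lam)
  dinv <- 1 / vapply(energies, pole_denominators, numeric(nlam), values = lam)
  dinv <- matrix(dinv, nrow = nlam)
  b_all <- tuk[, rep.int(seq_len(m), ne), drop = FALSE] *
    dinv[, rep(seq_len(ne), each = m), drop = FALSE]
  m_all <- uk %*% b_all
  vapply(seq_len(ne), function(i) {
    mm <- m_all[, ((i - 1) * m + 1):(i * m), drop = FALSE]
    g_kk <- mm %*% solve(id + (1i * gbar) * mm)
    pref * sum(Mod(g_kk)^2)
  }, numeric(1))
}

#' Retarded Green's function of the electrode-coupled chain
#'
#' `method = "dyson"` solves the Dyson equation G = g + g Sigma G using the
#' bare-chain eigendecomposition and a low-rank (single site block) update;
#' `method = "direct"` inverts \eqn{(E I - H_S - \Sigma)} densely and serves
#' as the oracle the low-rank route is tested against.
#'
#' @inheritParams transmission
#' @param e Single energy (eV).
#' @param method `"dyson"` or `"direct"`.
#' @return Complex (n m) x (n m) matrix.
#' @export
green_function <- function(chain, electrode, k, e, method = c("dyson", "direct"),
                           modes = NULL) {
  method <- match.arg(method)
  if (k < 1 || k > chain$n) stop("site k = ", k, " out of range 1..", chain$n)
  rows <- site_rows(chain, k)
  gbar <- (electrode$gamma_left + electrode$gamma_right) / 2
  if (method == "direct") {
    h <- assemble_dense(chain)
    a <- diag(e + 0i, nrow(h)) - h
    diag(a)[rows] <- diag(a)[rows] + 1i * gbar
    g <- tryCatch(solve(a), error = function(err) {
      stop(sprintf("Green's function singular at E = %.10g eV", e))
    })
    return(g)
  }
  if (is.null(modes)) modes <- chain_modes(chain)
  u <- modes$vectors
  w <- 1 / pole_denominators(e, modes$values)
  g0 <- u %*% (t(u) * w)                     # bare resolvent (E I - H)^(-1)
  if (gbar == 0) return(g0 + 0i)             # decoupled-electrode limit
  x <- g0[, rows, drop = FALSE]              # g0 B, B = site-k selector
  mm <- g0[rows, rows, drop = FALSE]         # B^T g0 B
  m <- chain$m
  # Woodbury with Sigma_b = -i gbar I_m on the contacted block
  core <- solve((1i / gbar) * diag(m) - mm)
  g0 + x %*% core %*% g0[rows, , drop = FALSE]
}

# panel boundaries for the bias window: every chain eigenvalue within
# [lo - 10*Gamma, hi + 10*Gamma] forces cuts at lambda and lambda +/- {1, 3,
# 10} Gamma (clipped), so each panel holds at most one resonance core or a
# smooth tail -- resonances of width ~Gamma would be missed by a uniform
# rule, and panels with peaks at both endpoints defeat QAGS extrapolation
transmission_panels <- function(lo, hi, eigenvalues, gbar) {
  evs <- eigenvalues[eigenvalues > lo - 10 * gbar & eigenvalues < hi + 10 * gbar]
  pts <- as.vector(outer(c(-10, -3, -1, 0, 1, 3, 10) * gbar, evs, "+"))
  pts <- pts[pts > lo & pts < hi]
  cuts <- sort(unique(c(lo, hi, pts)))
  # merge near-coincident cuts (near-degenerate eigenvalues)
  keep <- c(TRUE, diff(cuts) > 1e-12)
  cuts <- cuts[keep]
  cuts[length(cuts)] <- hi
  cuts
}

panel_integrate <- function(tfun, a, b, rel_tol, depth = 0L) {
  r <- stats::integrate(tfun, a, b, rel.tol = rel_tol, abs.tol = 0,
                        subdivisions = 200L, stop.on.error = FALSE)
  converged <- r$message == "OK" ||
    grepl("roundoff", r$message, fixed = TRUE) ||
    r$abs.error <= rel_tol * max(abs(r$value), .Machine$double.xmin) ||
    r$abs.error <= 1e-12   # negligible absolute contribution, (2e/h)*eV
  if (converged) {
    return(list(value = r$value, abs_error = r$abs.error))
  }
  if (depth >= 4L) {
    stop(sprintf(
      "quadrature failed on panel [%.6g, %.6g]: %s (achieved abs.error %.3g)",
      a, b, r$message, r$abs.error))
  }
  sub <- seq(a, b, length.out = 5L)
  parts <- lapply(seq_len(4L), function(i) {
    panel_integrate(tfun, sub[i], sub[i + 1], rel_tol, depth + 1L)
  })
  list(value = sum(vapply(parts, `[[`, numeric(1), "value")),
       abs_error = sum(vapply(parts, `[[`, numeric(1), "abs_error")))
}

integrate_transmission <- function(tfun, lo, hi, eigenvalues, gbar,
                                   rel_tol = 1e-6) {
  if (hi <= lo) return(list(value = 0, abs_error = 0))
  cuts <- transmission_panels(lo, hi, eigenvalues, gbar)
  total <- 0
  err <- 0
  for (i in seq_len(length(cuts) - 1)) {
    r <- panel_integrate(tfun, cuts[i], cuts[i + 1], rel_tol)
    total <- total + r$value
    err <- err + r$abs_error
  }
  list(value = total, abs_error = err)
}

#' Zero-temperature current through the contacted base
#'
#' \eqn{I_k = (2e/h)\int_{\mu_R}^{\mu_L} T(E)\,dE} with step-function Fermi
#' factors; the result is in (2e/h) x eV units (see
#' [current_unit_amperes()]).  Quadrature is panel-adaptive with forced
#' panel boundaries at every chain eigenvalue inside the bias window.
#'
#' @inheritParams transmission
#' @param bias A `bias_spec`.
#' @param rel_tol Relative quadrature tolerance per panel.
#' @return Single current value, with attribute `abs_error` (quadrature
#'   estimate, same units).
#' @export
site_current <- function(chain, electrode, k, bias, modes = NULL,
                         rel_tol = 1e-6) {
  if (is.null(modes)) modes <- chain_modes(chain)
  win <- bias_window(electrode, bias)
  sgn <- 1
  lo <- win[["lower"]]; hi <- win[["upper"]]
  if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp; sgn <- -1 }
  tfun <- function(e) transmission(chain, electrode, k, e, modes = modes)
  gbar <- (electrode$gamma_left + electrode$gamma_right) / 2
  r <- integrate_transmission(tfun, lo, hi, modes$values, gbar,
                              rel_tol = rel_tol)
  structure(sgn * r$value, abs_error = r$abs_error)
}

#' Scan the chain: current through every base
#'
#' The electrodes contact one nucleotide at a time; the bare-chain
#' eigendecomposition is computed once and reused for all sites.
#'
#' @inheritParams site_current
#' @return A `current_trace`: data frame with columns `site` (1-based),
#'   `base`, `current` ((2e/h) x eV units), carrying `electrode`, `bias`
#'   attributes.
#' @export
scan_chain <- function(chain, electrode, bias, rel_tol = 1e-6) {
  modes <- chain_modes(chain)
  cur <- vapply(seq_len(chain$n), function(k) {
    as.numeric(site_current(chain, electrode, k, bias, modes = modes,
                            rel_tol = rel_tol))
  }, numeric(1))
  trace <- data.frame(site = seq_len(chain$n),
                      base = chain$sequence$symbols,
                      current = cur, stringsAsFactors = FALSE)
  attr(trace, "electrode") <- electrode
  attr(trace, "bias") <- bias
  attr(trace, "sequence_id") <- chain$sequence$id
  class(trace) <- c("current_trace", "data.frame")
  trace
}

#' Write / read a current trace as tab-delimited text
#'
#' Numeric values are written at 17 significant digits, so identical runs
#' produce byte-identical files and read-back is exact.  Provenance
#' (electrode, bias) is stored in `#`-prefixed header lines.
#'
#' @param trace A `current_trace`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `current_trace` (reader).
#' @export
write_trace <- function(trace, path) {
  el <- attr(trace, "electrode"); bi <- attr(trace, "bias")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# electrode\t%s\t%.17g\t%.17g\t%.17g", el$label,
            el$work_function, el$gamma_left, el$gamma_right),
    sprintf("# bias\t%.17g\t%.17g", bi$voltage, bi$split),
    sprintf("# sequence_id\t%s", attr(trace, "sequence_id")),
    "site\tbase\tcurrent"), con)
  writeLines(sprintf("%d\t%s\t%.17g", trace$site, trace$base, trace$current), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- utils::read.delim(textConnection(lines[!startsWith(lines, "# ")]),
                            stringsAsFactors = FALSE)
  trace <- data.frame(site = as.integer(body$site), base = body$base,
                      current = as.numeric(body$current),
                      stringsAsFactors = FALSE)
  for (h in hdr) {
    f <- strsplit(sub("^# ", "", h), "\t")[[1]]
    if (f[1] == "electrode") {
      attr(trace, "electrode") <- electrode_pair(
        f[2], work_function = as.numeric(f[3]),
        gamma_left = as.numeric(f[4]), gamma_right = as.numeric(f[5]))
    } else if (f[1] == "bias") {
      attr(trace, "bias") <- bias_spec(as.numeric(f[2]), as.numeric(f[3]))
    } else if (f[1] == "sequence_id") {
      attr(trace, "sequence_id") <- if (length(f) > 1) f[2] else ""
    }
  }
  class(trace) <- c("current_trace", "data.frame")
  trace
}
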
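# Projector-operator reduction of a full fragment system (H, S) onto an
# active orbital subspace P.  The effective Hamiltonian on P is energy
# dependent; its fixed points det(Heff(E) - E S_PP) = 0 reproduce exactly the
# generalized eigenvalues of the full pencil, which is the validation
# property used throughout the tests.

# symmetric-definite generalized eigenproblem A v = lambda B v via Cholesky
geigen_sym <- function(a, b) {
  r <- chol(b)                      # b = t(r) %*% r
  rinv <- backsolve(r, diag(nrow(b)))
  c_mat <- t(rinv) %*% a %*% rinv
  e <- eigen(symmetrize(c_mat), symmetric = TRUE)
  list(values = e$values, vectors = rinv %*% e$vectors)
}

#' Build non-orthogonal projectors onto the active subspace
#'
#' For a basis with overlap S and active index set P, the projector onto P
#' and its complement Q obey \eqn{\hat P\hat P=\hat P}, \eqn{\hat Q\hat
#' Q=\hat Q}, \eqn{\hat P\hat Q=\hat Q\hat P=0} and \eqn{\hat P+\hat Q=I},
#' but are *not* symmetric matrices when S is non-orthogonal.  The matrices
#' returned here represent the operators acting on the dual (bra) coefficient
#' space, \eqn{P = S D_P S^{-1}} with \eqn{D_P} the diagonal indicator of the
#' active rows, which satisfies all four identities under ordinary matrix
#' products and reduces to the diagonal selector for S = I.
#'
#' @param system A `full_fragment_system`.
#' @param cond_tol Maximum admissible overlap condition number.
#' @return List with `p_matrix`, `q_matrix`, `overlap`, `active_indices`.
#' @export
build_projectors <- function(system, cond_tol = 1e10) {
  s <- system$overlap
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_tol) {
    stop("overlap matrix is singular or ill-conditioned (condition number ",
         format(max(ev) / max(min(ev), .Machine$double.eps)), ")")
  }
  sinv <- solve(s)
  p_idx <- system$active_indices
  m_tot <- nrow(s)
  p <- s[, p_idx, drop = FALSE] %*% sinv[p_idx, , drop = FALSE]
  q_idx <- setdiff(seq_len(m_tot), p_idx)
  q <- s[, q_idx, drop = FALSE] %*% sinv[q_idx, , drop = FALSE]
  list(p_matrix = p, q_matrix = q, overlap = s, active_indices = p_idx)
}

#' Energy-dependent effective Hamiltonian on the active subspace
#'
#' Returns an object whose `evaluate(E)` gives the m x m effective
#' Hamiltonian at energy E (eV).  Two algebraically equivalent routes are
#' provided: `"dyson"` (the default) computes \eqn{H_{eff}(E) = E S_{PP} +
#' [G_{PP}(E)]^{-1}} with the resolvent \eqn{G = (H - ES)^{-1}}, and
#' `"schur"` computes \eqn{H_{PP} + (E S_{PQ} - H_{PQ}) (E S_{QQ} -
#' H_{QQ})^{-1} (E S_{QP} - H_{QP})}.  The output is symmetrized to suppress
#' round-off asymmetry.  Evaluation within `singular_tol` of a pole of the
#' Q-block resolvent (see [q_singularities()]) is an error.
#'
#' @param system A `full_fragment_system`.
#' @param singular_tol Half-width (eV) of the excluded neighborhoods around
#'   the Q-block singular energies.
#' @return An `effective_hamiltonian` object with fields `evaluate`
#'   (function of E and optionally `route`), `s_pp`, `singularities`,
#'   `active_indices`.
#' @export
effective_hamiltonian <- function(system, singular_tol = 1e-6) {
  h <- system$hamiltonian
  s <- system$overlap
  p <- system$active_indices
  q <- setdiff(seq_len(nrow(h)), p)
  if (length(q) == 0) stop("active set must be a proper subset")
  sing <- geigen_sym(h[q, q, drop = FALSE], s[q, q, drop = FALSE])$values
  h_pp <- h[p, p, drop = FALSE]; s_pp <- s[p, p, drop = FALSE]
  h_pq <- h[p, q, drop = FALSE]; s_pq <- s[p, q, drop = FALSE]
  h_qq <- h[q, q, drop = FALSE]; s_qq <- s[q, q, drop = FALSE]

  evaluate <- function(e, route = c("dyson", "schur")) {
    route <- match.arg(route)
    if (any(abs(e - sing) < singular_tol)) {
      stop(sprintf("E = %.8f eV is within %g eV of a Q-block singularity",
                   e, singular_tol))
    }
    heff <- if (route == "dyson") {
      g <- solve(h - e * s)
      e * s_pp + solve(g[p, p, drop = FALSE])
    } else {
      a <- e * s_pq - h_pq
      h_pp + a %*% solve(e * s_qq - h_qq, t(e * s_pq - h_pq))
    }
    symmetrize(heff)
  }

  structure(
    list(evaluate = evaluate, s_pp = s_pp, h_pp = h_pp,
         singularities = sort(sing), active_indices = p, system = system),
    class = "effective_hamiltonian"
  )
}

#' Singular energies of the Q-block resolvent
#'
#' The effective Hamiltonian diverges at the generalized eigenvalues of
#' \eqn{(H_{QQ}, S_{QQ})}, i.e. the eigenvalues of \eqn{S_{QQ}^{-1}H_{QQ}}.
#'
#' @param system A `full_fragment_system`.
#' @return Sorted numeric vector of singular energies (eV).
#' @export
q_singularities <- function(system) {
  p <- system$active_indices
  q <- setdiff(seq_len(nrow(system$hamiltonian)), p)
  if (length(q) == 0) stop("Q subspace is empty")
  sort(geigen_sym(system$hamiltonian[q, q, drop = FALSE],
                  system$overlap[q, q, drop = FALSE])$values)
}

#' Linearize the effective Hamiltonian at an anchor energy
#'
#' The energy dependence of the effective Hamiltonian is weak inside the
#' active window, so a single evaluation at the average energy of the
#' valence orbitals serves as an energy-independent reduced Hamiltonian.
#'
#' @param eff An `effective_hamiltonian`.
#' @param valence_energies Numeric vector of valence orbital energies (eV);
#'   the anchor is their arithmetic mean.
#' @return A `linearized_hamiltonian` with fields `matrix` and
#'   `anchor_energy`.
#' @export
linearize <- function(eff, valence_energies) {
  anchor <- mean(valence_energies)
  structure(
    list(matrix = eff$evaluate(anchor), anchor_energy = anchor),
    class = "linearized_hamiltonian"
  )
}

#' Fixed-point energies of the effective Hamiltonian
#'
#' Scans \eqn{d(E) = \det(H_{eff}(E) - E S_{PP})} on a uniform grid over
#' `window` and refines each sign change by bisection ([stats::uniroot()]).
#' Grid points falling inside the excluded neighborhoods of the Q-block
#' singularities are skipped.  Inside the active window the roots coincide
#' with the generalized eigenvalues of the full (H, S) pencil.
#'
#' @param eff An `effective_hamiltonian`.
#' @param window Length-2 numeric, energy interval to scan (eV).
#' @param n_grid Number of scan points.
#' @param tol Root tolerance passed to [stats::uniroot()].
#' @return Numeric vector of fixed-point energies (eV), sorted.
#' @export
effective_fixed_points <- function(eff, window, n_grid = 10000L, tol = 1e-10) {
  grid <- seq(window[1], window[2], length.out = n_grid)
  keep <- vapply(grid, function(e) all(abs(e - eff$singularities) > 1e-5),
                 logical(1))
  grid <- grid[keep]
  # the Schur route is regular at the pencil eigenvalues being located,
  # whereas the Dyson route inverts a nearly singular full resolvent there
  dfun <- function(e) det(eff$evaluate(e, route = "schur") - e * eff$s_pp)
  dets <- vapply(grid, dfun, numeric(1))
  roots <- numeric(0)
  idx <- which(dets[-1] * dets[-length(dets)] < 0)
  for (i in idx) {
    # a Q-block pole flips the sign of the determinant without a root:
    # skip brackets that contain (or straddle the exclusion zone of) one
    if (any(eff$singularities > grid[i] - 1e-5 &
            eff$singularities < grid[i + 1] + 1e-5)) next
    if (grid[i + 1] - grid[i] > 1.5 * diff(window) / (n_grid - 1)) next
    r <- stats::uniroot(dfun, lower = grid[i], upper = grid[i + 1], tol = tol)
    roots <- c(roots, r$root)
  }
  sort(roots)
}

#' Generalized eigenvalues of the full fragment pencil
#'
#' Dense-solver reference for the projection tests: eigenvalues of
#' \eqn{H v = \lambda S v} for the full system.
#'
#' @param system A `full_fragment_system`.
#' @return Sorted numeric vector of eigenvalues (eV).
#' @export
full_pencil_eigenvalues <- function(system) {
  sort(geigen_sym(system$hamiltonian, system$overlap)$values)
}
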
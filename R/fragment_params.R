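# Reduced tight-binding "alphabet": per-nucleotide m x m onsite blocks h_X and
# ordered-pair nearest-neighbor coupling blocks V_XY, all in eV.  These stand
# in for matrices a first-principles fragment-orbital calculation would
# deliver; the generator only emulates their gross features (HOMO placement,
# HOMO-LUMO gap, weak couplings), not any real chemistry.

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

PARAMS_SCHEMA <- "tb-params/1"

#' Nucleotide alphabet for a chain type
#'
#' @param kind `"DNA"` or `"RNA"`.
#' @return Character vector of the four base symbols, in canonical
#'   (alphabetical) order.
#' @export
tb_alphabet <- function(kind) {
  kind <- match.arg(kind, c("DNA", "RNA"))
  if (kind == "DNA") DNA_ALPHABET else RNA_ALPHABET
}

pair_key <- function(x, y) paste0(x, ":", y)

symmetrize <- function(m) (m + t(m)) / 2

spectral_norm <- function(m) norm(m, type = "2")

is_hermitian <- function(m, tol = 1e-12) {
  max(abs(m - Conj(t(m)))) <= tol
}

#' Default level-placement regime for the synthetic generator
#'
#' Encodes the gross electronic-structure features the generator emulates:
#' HOMO levels inside \[-6, -5\] eV with order G > A ~ C > T, a LUMO about
#' 4 eV above the HOMO, deeper valence levels spaced below the HOMO, weak
#' nearest-neighbor couplings, and an RNA alphabet whose A/C/G blocks differ
#' from DNA only by a small backbone perturbation while U is shifted away
#' from T.
#'
#' @return Named list of regime settings (all energies in eV):
#'   `homo_levels` (per DNA base), `u_shift` (diagonal shift turning T into
#'   U), `lumo_gap`, `lumo_jitter`, `homo_jitter`, `valence_spacing`,
#'   `valence_jitter`, `onsite_noise` (off-diagonal onsite scale),
#'   `coupling_scale` (coupling-block entry scale), `backbone_epsilon`
#'   (spectral-norm bound on the RNA backbone perturbation).
#' @export
default_regime <- function() {
  list(
    homo_levels = c(A = -5.45, C = -5.55, G = -5.15, T = -5.78),
    u_shift = -0.12,
    lumo_gap = 4.0,
    lumo_jitter = 0.10,
    homo_jitter = 0.03,
    valence_spacing = 0.55,
    valence_jitter = 0.05,
    onsite_noise = 0.01,
    coupling_scale = 0.06,
    backbone_epsilon = 0.05
  )
}

#' Construct a fragment parameter set from explicit blocks
#'
#' Low-level constructor used by the generator, the reader, and tests that
#' need hand-built alphabets.  Validates Hermiticity of the onsite blocks and
#' the transpose symmetry `V_YX == t(V_XY)` of the coupling blocks; missing
#' ordered pairs are filled in by transposition when possible.
#'
#' @param alphabet_kind `"DNA"` or `"RNA"`.
#' @param onsite Named list of m x m numeric matrices, one per base (eV).
#' @param coupling Named list of m x m numeric matrices keyed `"X:Y"` for
#'   ordered base pairs (eV).  At least one orientation of each unordered
#'   pair must be present.
#' @param metadata Optional list (seed, regime, ...) stored verbatim.
#' @return A `fragment_params` object.
#' @export
fragment_parameter_set <- function(alphabet_kind, onsite, coupling,
                                   metadata = list()) {
  alphabet <- tb_alphabet(alphabet_kind)
  if (!setequal(names(onsite), alphabet)) {
    stop("onsite blocks must be named exactly ", paste(alphabet, collapse = ","))
  }
  onsite <- onsite[alphabet]
  m <- nrow(onsite[[1]])
  for (b in alphabet) {
    h <- onsite[[b]]
    if (!is.matrix(h) || nrow(h) != m || ncol(h) != m) {
      stop("onsite block for ", b, " is not ", m, "x", m)
    }
    if (!is_hermitian(h)) {
      stop("onsite block for ", b, " is not Hermitian to 1e-12 eV")
    }
  }
  full <- list()
  for (x in alphabet) {
    for (y in alphabet) {
      k <- pair_key(x, y)
      rk <- pair_key(y, x)
      if (!is.null(coupling[[k]])) {
        full[[k]] <- coupling[[k]]
      } else if (!is.null(coupling[[rk]])) {
        full[[k]] <- t(coupling[[rk]])
      } else {
        stop("missing coupling block for pair (", x, ",", y, ")")
      }
    }
  }
  for (x in alphabet) {
    for (y in alphabet) {
      k <- pair_key(x, y)
      v <- full[[k]]
      if (!is.matrix(v) || nrow(v) != m || ncol(v) != m) {
        stop("coupling block ", k, " is not ", m, "x", m)
      }
      if (max(abs(full[[pair_key(y, x)]] - t(v))) > 1e-12) {
        stop("coupling blocks violate V_", y, x, " == t(V_", x, y, ")")
      }
    }
  }
  structure(
    list(
      alphabet = alphabet,
      alphabet_kind = alphabet_kind,
      m = m,
      onsite = onsite,
      coupling = full,
      metadata = c(metadata, list(schema = PARAMS_SCHEMA))
    ),
    class = "fragment_params"
  )
}

# deterministic per-base level ladder: (m-1) occupied levels spaced below the
# HOMO plus one LUMO at homo + gap; m = 1 degenerates to the bare HOMO level
base_level_ladder <- function(homo, m, regime) {
  if (m == 1) return(homo)
  occ <- homo - regime$valence_spacing * ((m - 2):0)
  if (m > 2) {
    occ[seq_len(m - 2)] <- occ[seq_len(m - 2)] +
      stats::runif(m - 2, -regime$valence_jitter, regime$valence_jitter)
  }
  lumo <- homo + regime$lumo_gap +
    stats::runif(1, -regime$lumo_jitter, regime$lumo_jitter)
  c(occ, lumo)
}

random_offdiag_sym <- function(m, scale) {
  e <- matrix(stats::runif(m * m, -scale, scale), m, m)
  e <- symmetrize(e)
  diag(e) <- 0
  e
}

#' Generate a synthetic reduced fragment parameter set
#'
#' Draws a seeded, deterministic tight-binding "alphabet": one m x m Hermitian
#' onsite block per base whose HOMO eigenvalue lies in \[-6, -5\] eV and whose
#' LUMO sits about 4 eV higher, plus m x m nearest-neighbor coupling blocks
#' for all 16 ordered base pairs with entries two orders of magnitude below
#' the onsite level spread.  Second-nearest-neighbor couplings do not exist
#' in the data model.  For RNA the A/C/G blocks equal the DNA blocks of the
#' same seed plus a backbone perturbation of spectral norm at most
#' `regime$backbone_epsilon`, while U is the T block shifted by
#' `regime$u_shift` on the diagonal.
#'
#' @param alphabet_kind `"DNA"` or `"RNA"`.
#' @param m Number of active molecular orbitals per nucleotide (default 5:
#'   four HOMO-side levels and one LUMO).
#' @param seed Integer seed; the result is bitwise reproducible.
#' @param regime Level-placement settings, see [default_regime()].
#' @return A `fragment_params` object.
#' @examples
#' p <- generate_parameter_set("DNA", m = 5, seed = 1)
#' eigen(p$onsite$G, symmetric = TRUE, only.values = TRUE)$values
#' @export
generate_parameter_set <- function(alphabet_kind, m = 5L, seed = 1L,
                                   regime = default_regime()) {
  alphabet_kind <- match.arg(alphabet_kind, c("DNA", "RNA"))
  if (!is.numeric(m) || length(m) != 1L || m < 1) stop("m must be an integer >= 1")
  m <- as.integer(m)

  if (alphabet_kind == "RNA") {
    dna <- generate_parameter_set("DNA", m = m, seed = seed, regime = regime)
    return(rna_from_dna(dna, seed, regime))
  }

  set.seed(seed)
  alphabet <- DNA_ALPHABET
  onsite <- list()
  for (b in alphabet) {
    homo <- regime$homo_levels[[b]] +
      stats::runif(1, -regime$homo_jitter, regime$homo_jitter)
    levels <- base_level_ladder(homo, m, regime)
    onsite[[b]] <- diag(levels, nrow = m) + random_offdiag_sym(m, regime$onsite_noise)
  }
  coupling <- list()
  for (i in seq_along(alphabet)) {
    for (j in i:length(alphabet)) {
      x <- alphabet[i]; y <- alphabet[j]
      v <- matrix(stats::rnorm(m * m, 0, regime$coupling_scale), m, m)
      if (x == y) v <- symmetrize(v)
      coupling[[pair_key(x, y)]] <- v
    }
  }
  fragment_parameter_set(
    "DNA", onsite, coupling,
    metadata = list(seed = seed, regime = regime,
                    homo_index = if (m == 1) 1L else m - 1L)
  )
}

# RNA alphabet derived from the DNA set of the same seed: small symmetric
# backbone perturbation on A/C/G, diagonal shift T -> U, couplings relabeled
# with a small perturbation that respects the transpose symmetry.
rna_from_dna <- function(dna, seed, regime) {
  set.seed(seed + 1L)
  m <- dna$m
  onsite <- list()
  for (b in c("A", "C", "G")) {
    pert <- random_offdiag_sym(m, 1) + diag(stats::runif(m, -1, 1), nrow = m)
    pert <- symmetrize(pert)
    nrm <- spectral_norm(pert)
    if (nrm > 0) pert <- pert * (0.8 * regime$backbone_epsilon / nrm)
    onsite[[b]] <- dna$onsite[[b]] + pert
  }
  onsite[["U"]] <- dna$onsite[["T"]] + diag(regime$u_shift, nrow = m)
  relabel <- function(b) if (b == "U") "T" else b
  coupling <- list()
  for (i in seq_along(RNA_ALPHABET)) {
    for (j in i:length(RNA_ALPHABET)) {
      x <- RNA_ALPHABET[i]; y <- RNA_ALPHABET[j]
      v <- dna$coupling[[pair_key(relabel(x), relabel(y))]]
      pert <- matrix(stats::rnorm(m * m, 0, 0.2 * regime$coupling_scale), m, m)
      v <- v + if (x == y) symmetrize(pert) else pert
      coupling[[pair_key(x, y)]] <- v
    }
  }
  fragment_parameter_set(
    "RNA", onsite, coupling,
    metadata = list(seed = seed, regime = regime,
                    homo_index = if (m == 1) 1L else m - 1L)
  )
}

#' Onsite level spectrum of one base
#'
#' @param params A `fragment_params` object.
#' @param base Base symbol.
#' @return Sorted eigenvalues (eV) of the onsite block.
#' @export
onsite_levels <- function(params, base) {
  eigen(params$onsite[[base]], symmetric = TRUE, only.values = TRUE)$values |>
    sort()
}

#' HOMO and LUMO eigenvalues of one base
#'
#' @inheritParams onsite_levels
#' @return Named numeric vector `c(homo=, lumo=)`; `lumo` is `NA` for m = 1.
#' @export
frontier_levels <- function(params, base) {
  lev <- onsite_levels(params, base)
  m <- params$m
  if (m == 1) return(c(homo = lev[1], lumo = NA_real_))
  c(homo = lev[m - 1], lumo = lev[m])
}

#' @export
print.fragment_params <- function(x, ...) {
  cat(sprintf("<fragment_params> %s alphabet, m = %d orbitals/site\n",
              x$alphabet_kind, x$m))
  for (b in x$alphabet) {
    fl <- frontier_levels(x, b)
    cat(sprintf("  %s: HOMO %+.3f eV  LUMO %s\n", b, fl["homo"],
                if (is.na(fl["lumo"])) "-" else sprintf("%+.3f eV", fl["lumo"])))
  }
  invisible(x)
}

## ---- full (unreduced) fragment systems: fixtures for the projection module

#' Generate a full fragment system with non-orthogonal overlap
#'
#' Builds a random M x M real symmetric Hamiltonian and a symmetric
#' positive-definite overlap with unit diagonal, plus a designated active
#' subspace whose diagonal levels sit inside a known energy window well
#' separated from the remaining levels.  Used to exercise the projection
#' machinery against a dense generalized-eigensolver oracle.
#'
#' @param M Total orbital count.
#' @param active_count Size of the active subspace (first `active_count`
#'   orbitals); must be < M.
#' @param seed Integer seed.
#' @param coupling_scale Scale of random symmetric off-diagonal Hamiltonian
#'   entries (eV).
#' @param s_offdiag Scale of random off-diagonal overlap entries; shrunk
#'   automatically until the overlap is safely positive definite.
#' @return A `full_fragment_system` with fields `hamiltonian`, `overlap`,
#'   `active_indices` and an `active_window` attribute (eV) bracketing the
#'   active levels.
#' @export
generate_full_fragment_system <- function(M, active_count, seed = 1L,
                                          coupling_scale = 0.15,
                                          s_offdiag = 0.05) {
  if (M <= active_count || active_count < 1) {
    stop("require M > active_count >= 1")
  }
  set.seed(seed)
  nq <- M - active_count
  lev_p <- stats::runif(active_count, -6.2, -4.8)
  lev_q <- c(stats::runif(ceiling(nq / 2), -12, -8.5),
             stats::runif(floor(nq / 2), -2.5, 1.5))
  h <- diag(c(lev_p, lev_q), nrow = M)
  h <- h + random_offdiag_sym(M, coupling_scale)
  s <- diag(M)
  off <- random_offdiag_sym(M, s_offdiag)
  while (min(eigen(diag(M) + off, symmetric = TRUE, only.values = TRUE)$values) < 0.1) {
    off <- off / 2
  }
  s <- diag(M) + off
  structure(
    list(hamiltonian = h, overlap = s,
         active_indices = seq_len(active_count)),
    active_window = c(-7.5, -3.5),
    class = "full_fragment_system"
  )
}

## ---- serialization -------------------------------------------------------

# matrices are encoded row-major as %.17g strings: 17 significant digits
# round-trip IEEE doubles exactly, which plain JSON numbers do not guarantee
encode_matrix <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m),
       data = sprintf("%.17g", as.vector(t(m))))
}

decode_matrix <- function(x) {
  matrix(as.numeric(unlist(x$data)), nrow = x$nrow, ncol = x$ncol, byrow = TRUE)
}

#' Write a fragment parameter set to JSON
#'
#' The on-disk form is a versioned JSON document with row-major matrix
#' entries encoded at 17 significant digits, so `read_parameter_set()`
#' reproduces the object bit-exactly.
#'
#' @param params A `fragment_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "fragment_params"))
  doc <- list(
    schema = PARAMS_SCHEMA,
    alphabet_kind = params$alphabet_kind,
    alphabet = params$alphabet,
    m = params$m,
    seed = params$metadata$seed,
    homo_index = params$metadata$homo_index,
    onsite = lapply(params$onsite, encode_matrix),
    coupling = lapply(params$coupling, encode_matrix)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a fragment parameter set from JSON
#'
#' Validates the schema version, the presence of all 16 ordered coupling
#' blocks, Hermiticity of every onsite block and the pair transpose symmetry;
#' corrupt files fail with the offending block named.
#'
#' @param path File written by [write_parameter_set()].
#' @return A `fragment_params` object.
#' @export
read_parameter_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, PARAMS_SCHEMA)) {
    stop("schema mismatch: expected ", PARAMS_SCHEMA, ", found ",
         if (is.null(doc$schema)) "<none>" else doc$schema)
  }
  alphabet <- tb_alphabet(doc$alphabet_kind)
  for (x in alphabet) for (y in alphabet) {
    if (is.null(doc$coupling[[pair_key(x, y)]])) {
      stop("parameter file is missing coupling block for pair (", x, ",", y, ")")
    }
  }
  onsite <- lapply(doc$onsite, decode_matrix)
  coupling <- lapply(doc$coupling, decode_matrix)
  fragment_parameter_set(
    doc$alphabet_kind, onsite, coupling,
    metadata = list(seed = doc$seed, homo_index = doc$homo_index)
  )
}
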
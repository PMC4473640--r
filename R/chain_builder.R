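# Block-tridiagonal chain Hamiltonian of a concrete sequence.  Onsite blocks
# carry a Hermitian renormalization from each existing neighbor's coupling
# block; hopping blocks are the raw ordered-pair couplings.  Strictly first
# nearest neighbor: no (i, i+2) blocks exist in the data model.

#' Construct a nucleotide sequence object
#'
#' @param symbols Character: either a single string (`"GATTACA"`) or a
#'   character vector of single-base symbols.
#' @param alphabet_kind `"DNA"` or `"RNA"`.
#' @param id Free-text identifier (reported, never interpreted).
#' @param map_u_t If `TRUE`, explicitly convert T to U (RNA) or U to T (DNA)
#'   before validation; the mapping is never applied silently.
#' @return A `nucleotide_sequence` object (0-based internally irrelevant;
#'   all reports are 1-based).
#' @export
nucleotide_sequence <- function(symbols, alphabet_kind = "DNA", id = "",
                                map_u_t = FALSE) {
  if (length(symbols) == 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  symbols <- toupper(symbols)
  alphabet <- tb_alphabet(alphabet_kind)
  if (map_u_t) {
    if (alphabet_kind == "RNA") symbols[symbols == "T"] <- "U"
    else symbols[symbols == "U"] <- "T"
  }
  if (length(symbols) == 0L) stop("sequence must be nonempty")
  bad <- setdiff(unique(symbols), alphabet)
  if (length(bad) > 0) {
    stop("symbols not in ", alphabet_kind, " alphabet: ",
         paste(bad, collapse = ","))
  }
  structure(list(symbols = symbols, alphabet_kind = alphabet_kind, id = id),
            class = "nucleotide_sequence")
}

#' @export
length.nucleotide_sequence <- function(x) length(x$symbols)

#' @export
print.nucleotide_sequence <- function(x, ...) {
  s <- paste(x$symbols, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<nucleotide_sequence> %s (%d nt%s): %s\n", x$alphabet_kind,
              length(x), if (nzchar(x$id)) paste0(", ", x$id) else "", s))
  invisible(x)
}

#' Assemble the block-tridiagonal chain Hamiltonian of a sequence
#'
#' Interior onsite blocks are \eqn{h_{X_i} + R(V_{X_i X_{i+1}}) + R(V_{X_i
#' X_{i-1}})} where \eqn{R(V) = (V + V^T)/2} is the Hermitian
#' renormalization map; terminal sites include only the existing neighbor's
#' term.  Hopping blocks between i and i+1 are the ordered-pair coupling
#' blocks \eqn{V_{X_i X_{i+1}}}, copied unmodified.
#'
#' @param seq A `nucleotide_sequence`.
#' @param params A `fragment_params` whose alphabet kind matches `seq`.
#' @return A `chain_hamiltonian` with fields `onsite_blocks`,
#'   `hopping_blocks` (length n-1), `sequence`, `m`, `n`.
#' @export
build_chain <- function(seq, params) {
  stopifnot(inherits(seq, "nucleotide_sequence"),
            inherits(params, "fragment_params"))
  if (!identical(seq$alphabet_kind, params$alphabet_kind)) {
    stop("alphabet-kind mismatch: sequence is ", seq$alphabet_kind,
         " but parameters are ", params$alphabet_kind)
  }
  sym <- seq$symbols
  bad <- setdiff(unique(sym), params$alphabet)
  if (length(bad) > 0) stop("unknown symbol(s): ", paste(bad, collapse = ","))
  n <- length(sym)
  renorm <- function(v) (v + t(v)) / 2
  onsite <- vector("list", n)
  for (i in seq_len(n)) {
    h <- params$onsite[[sym[i]]]
    if (i < n) h <- h + renorm(params$coupling[[pair_key(sym[i], sym[i + 1])]])
    if (i > 1) h <- h + renorm(params$coupling[[pair_key(sym[i], sym[i - 1])]])
    onsite[[i]] <- h
  }
  hopping <- if (n > 1) {
    lapply(seq_len(n - 1), function(i) params$coupling[[pair_key(sym[i], sym[i + 1])]])
  } else list()
  structure(
    list(onsite_blocks = onsite, hopping_blocks = hopping,
         sequence = seq, m = params$m, n = n),
    class = "chain_hamiltonian"
  )
}

#' Dense Hermitian matrix of a chain Hamiltonian
#'
#' @param chain A `chain_hamiltonian`.
#' @return The (n m) x (n m) symmetric matrix with the chain's block layout.
#' @export
assemble_dense <- function(chain) {
  m <- chain$m; n <- chain$n
  h <- matrix(0, n * m, n * m)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * m + 1):(i * m)
    h[rows, rows] <- chain$onsite_blocks[[i]]
    if (i < n) {
      cols <- (i * m + 1):((i + 1) * m)
      h[rows, cols] <- chain$hopping_blocks[[i]]
      h[cols, rows] <- t(chain$hopping_blocks[[i]])
    }
  }
  h
}

#' @export
print.chain_hamiltonian <- function(x, ...) {
  cat(sprintf("<chain_hamiltonian> %d sites x %d orbitals (%s)\n",
              x$n, x$m, paste(utils::head(x$sequence$symbols, 20), collapse = "")))
  invisible(x)
}

## ---- FASTA ---------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' Standard multi-record FASTA; every record becomes a
#' [nucleotide_sequence()].  T/U conversion is applied only when `map_u_t =
#' TRUE`, mirroring the constructor.
#'
#' @param path FASTA file.
#' @param alphabet_kind `"DNA"` or `"RNA"`.
#' @param map_u_t Explicit T<->U mapping flag.
#' @return List of `nucleotide_sequence` objects.
#' @export
read_fasta <- function(path, alphabet_kind = "DNA", map_u_t = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  lapply(seq_along(set), function(i) {
    nucleotide_sequence(as.character(set[[i]]), alphabet_kind,
                        id = if (is.null(ids[i]) || is.na(ids[i])) "" else ids[i],
                        map_u_t = map_u_t)
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `nucleotide_sequence` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nucleotide_sequence")) seqs <- list(seqs)
  strings <- vapply(seqs, function(s) paste(s$symbols, collapse = ""), character(1))
  ids <- vapply(seqs, function(s) s$id, character(1))
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  set <- Biostrings::BStringSet(strings)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
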
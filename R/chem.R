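# Chemistry backend contract: canonical SMILES via OpenBabel (ChemmineOB),
# randomized SMILES / scaffolds / structure counts via the package's own
# molecular-graph layer.

# Vectorized OpenBabel canonicalization. OpenBabel stops converting a batch
# at the first invalid entry, so on truncation we record an NA there and
# resume with the remainder. Returns NA_character_ for invalid SMILES.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  if (any(grepl("[\n\t ]", smiles))) {
    stop("SMILES must not contain whitespace", call. = FALSE)
  }
  lo <- 1L
  while (lo <= n) {
    hi <- n
    res <- ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(paste(smiles[lo:hi], collapse = "\n"), "\n"))
    lines <- if (nzchar(res)) strsplit(res, "\n", fixed = TRUE)[[1]] else character(0)
    lines <- sub("[\t ].*$", "", lines)
    k <- length(lines)
    if (k > hi - lo + 1L) stop("unexpected OpenBabel output", call. = FALSE)
    if (k > 0L) out[lo:(lo + k - 1L)] <- lines
    if (k == hi - lo + 1L) break
    lo <- lo + k + 1L  # skip the invalid entry (left as NA)
  }
  empty <- !is.na(out) & !nzchar(out)
  out[empty] <- NA_character_
  out
}

#' Canonicalize a SMILES string
#'
#' Returns the deterministic canonical SMILES of a molecule, computed with
#' the OpenBabel backend. All enumeration variants of one molecule map to
#' the same canonical form, and the function is idempotent:
#' `canonicalize(canonicalize(s)) == canonicalize(s)`.
#'
#' @param smiles A single non-empty SMILES string.
#' @return The canonical SMILES string.
#' @examples
#' \donttest{canonicalize("OCC")}
#' @export
canonicalize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  out <- ob_canonical(smiles)
  if (is.na(out)) invalid_structure("unparsable SMILES", smiles)
  out
}

#' Canonicalize a vector of SMILES strings
#'
#' Batch form of [canonicalize()]; invalid entries yield `NA` instead of an
#' error so that corpus curation can count them.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
canonicalize_all <- function(smiles) {
  ob_canonical(as.character(smiles))
}

#' Standardize a SMILES string
#'
#' The standardization contract applied during curation: the structure is
#' sanitized and normalized by the chemistry backend and rendered in
#' canonical form. Exposed as a single function so a fuller standardization
#' pipeline (salt stripping, tautomer rules, ...) can be slotted in without
#' touching the curation logic.
#'
#' @param smiles A single SMILES string.
#' @return Standardized canonical SMILES.
#' @export
standardize_smiles <- function(smiles) {
  canonicalize(smiles)
}

#' Generate a randomized SMILES for a molecule
#'
#' Re-writes the molecule from a randomized atom ordering, producing a
#' syntactically valid SMILES of the same structure
#' (`canonicalize(randomized_smiles(s, k)) == canonicalize(s)`).
#' Deterministic for a fixed seed.
#'
#' @param smiles A valid SMILES string.
#' @param rng_seed Integer seed for the atom-order permutation.
#' @return A SMILES string.
#' @export
randomized_smiles <- function(smiles, rng_seed) {
  g <- smiles_parse(smiles)
  rank <- with_seed(rng_seed, sample.int(g$n))
  smiles_write(g, rank)
}

#' Count heavy (non-hydrogen) atoms
#'
#' @param smiles A valid SMILES string.
#' @return Integer count of non-hydrogen atoms.
#' @examples
#' heavy_atom_count("CCO")  # 3
#' @export
heavy_atom_count <- function(smiles) {
  g <- smiles_parse(smiles)
  sum(g$element != "H")
}

#' Is a structure a mixture of disconnected fragments?
#'
#' Detection is structural (connected components of the parsed graph), not
#' textual: `"C1.C1"` reconnects through its ring closure into a single
#' fragment and is not a mixture.
#'
#' @param smiles A valid SMILES string.
#' @return `TRUE` iff the structure has more than one disconnected fragment.
#' @export
is_mixture <- function(smiles) {
  g <- smiles_parse(smiles)
  max(mol_components(g)) > 1L
}

#' Count rings (cyclomatic number)
#'
#' @param smiles A valid SMILES string.
#' @return Integer number of independent rings.
#' @export
ring_count <- function(smiles) {
  g <- smiles_parse(smiles)
  length(g$b_from) - g$n + max(mol_components(g))
}

#' Count atoms of one element
#'
#' @param smiles A valid SMILES string.
#' @param element Element symbol, e.g. `"N"`.
#' @return Integer count.
#' @export
atom_count <- function(smiles, element) {
  g <- smiles_parse(smiles)
  sum(g$element == element)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The scaffold is the molecule's ring systems plus the linkers connecting
#' them (the 2-core of the molecular graph), extended by atoms attached to
#' that framework through double or triple bonds. Acyclic molecules have an
#' empty scaffold. The result is returned in canonical form, so structurally
#' related molecules (e.g. benzene and toluene) share identical scaffold
#' text, and the scaffold of a scaffold is itself.
#'
#' @param smiles A valid SMILES string.
#' @return Canonical scaffold SMILES, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  g <- smiles_parse(smiles)
  deg <- tabulate(c(g$b_from, g$b_to), g$n)
  keep <- rep(TRUE, g$n)
  adj <- mol_adjacency(g)
  repeat {
    leaves <- which(keep & deg <= 1L)
    if (length(leaves) == 0L) break
    for (a in leaves) {
      keep[a] <- FALSE
      deg[a] <- 0L
      for (b in adj[[a]]) {
        o <- bond_other(g, b, a)
        if (keep[o]) deg[o] <- deg[o] - 1L
      }
    }
  }
  if (!any(keep)) return("")
  multi <- g$b_type %in% c("2", "3")
  repeat {
    grow <- which(multi &
                    (keep[g$b_from] != keep[g$b_to]))
    if (length(grow) == 0L) break
    keep[g$b_from[grow]] <- TRUE
    keep[g$b_to[grow]] <- TRUE
  }
  sub <- mol_subgraph(g, which(keep))
  canonicalize(smiles_write(sub))
}

# Run an expression under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
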
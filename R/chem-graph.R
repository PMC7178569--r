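# Lightweight molecular-graph layer backing SMILES enumeration, scaffold
# extraction and structure counts. Parsing covers the organic-subset SMILES
# grammar (bare atoms B C N O P S F Cl Br I and aromatic b c n o p s,
# bracket atoms, bond orders -/=/#/:, branches, ring closures incl. %NN,
# dot-disconnected fragments). Stereo markers (/ \ @ @@) are accepted and
# discarded; canonical text is delegated to the OpenBabel backend.

BARE_ATOMS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
BARE_AROMATIC <- c("b", "c", "n", "o", "p", "s")

invalid_structure <- function(msg, smiles) {
  stop(structure(
    class = c("invalid_structure", "error", "condition"),
    list(message = paste0("invalid structure: ", msg, " in ", sQuote(smiles)),
         call = NULL, smiles = smiles)))
}

parse_bracket_atom <- function(tok, smiles) {
  m <- regexec(
    "^\\[([0-9]+)?([A-Za-z][a-z]?|\\*)(@@?)?(H[0-9]*)?([+-][0-9]+|\\++|-+)?(:[0-9]+)?\\]$",
    tok)
  g <- regmatches(tok, m)[[1]]
  if (length(g) == 0L) invalid_structure(paste0("bad bracket atom ", tok), smiles)
  sym <- g[3]
  if (sym == "*") invalid_structure("wildcard atom not supported", smiles)
  arom <- sym == tolower(sym) && substr(sym, 1, 1) %in% letters
  el <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  hpart <- g[5]
  h <- if (hpart == "") 0L
       else if (hpart == "H") 1L
       else as.integer(substring(hpart, 2))
  cpart <- g[6]
  chg <- if (cpart == "") 0L
         else if (grepl("^[+-][0-9]+$", cpart)) {
           as.integer(substring(cpart, 2)) * (if (substr(cpart, 1, 1) == "+") 1L else -1L)
         } else nchar(cpart) * (if (substr(cpart, 1, 1) == "+") 1L else -1L)
  iso <- if (g[2] == "") 0L else as.integer(g[2])
  list(element = el, aromatic = arom, hcount = h, charge = chg, isotope = iso)
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`: atom property vectors (`element`, `aromatic`,
#'   `charge`, `isotope`, `hcount`, `bracket`) and bond vectors (`b_from`,
#'   `b_to`, `b_type` with types `"1"`, `"2"`, `"3"`, `"ar"`).
#' @keywords internal
smiles_parse <- function(smiles) {
  toks <- tryCatch(tokenize_smiles(smiles),
                   error = function(e) invalid_structure(conditionMessage(e), smiles))
  n_guess <- length(toks)
  element <- character(n_guess); aromatic <- logical(n_guess)
  charge <- integer(n_guess); isotope <- integer(n_guess)
  hcount <- integer(n_guess); bracket <- logical(n_guess)
  na <- 0L
  b_from <- integer(0); b_to <- integer(0); b_type <- character(0)
  prev <- NA_integer_
  pend <- NA_character_
  stack <- integer(0)
  rings <- list()

  implied_type <- function(a1, a2) {
    if (aromatic[a1] && aromatic[a2]) "ar" else "1"
  }
  add_bond <- function(a1, a2, type) {
    if (a1 == a2) invalid_structure("self bond", smiles)
    b_from[length(b_from) + 1L] <<- a1
    b_to[length(b_to) + 1L] <<- a2
    b_type[length(b_type) + 1L] <<- if (is.na(type)) implied_type(a1, a2) else type
  }
  add_atom <- function(p) {
    na <<- na + 1L
    element[na] <<- p$element; aromatic[na] <<- p$aromatic
    charge[na] <<- p$charge; isotope[na] <<- p$isotope
    hcount[na] <<- p$hcount; bracket[na] <<- p$bracket
    if (!is.na(prev)) add_bond(prev, na, pend)
    prev <<- na
    pend <<- NA_character_
  }

  bond_map <- c("-" = "1", "=" = "2", "#" = "3", ":" = "ar",
                "/" = "1", "\\" = "1")
  for (tok in toks) {
    first <- substr(tok, 1, 1)
    if (first == "[") {
      p <- parse_bracket_atom(tok, smiles)
      p$bracket <- TRUE
      add_atom(p)
    } else if (tok %in% BARE_ATOMS) {
      add_atom(list(element = tok, aromatic = FALSE, hcount = NA_integer_,
                    charge = 0L, isotope = 0L, bracket = FALSE))
    } else if (tok %in% BARE_AROMATIC) {
      add_atom(list(element = toupper(tok), aromatic = TRUE,
                    hcount = NA_integer_, charge = 0L, isotope = 0L,
                    bracket = FALSE))
    } else if (tok %in% names(bond_map)) {
      if (is.na(prev)) invalid_structure("bond with no preceding atom", smiles)
      pend <- bond_map[[tok]]
    } else if (grepl("^[0-9]$", tok) || grepl("^%[0-9]{2}$", tok)) {
      if (is.na(prev)) invalid_structure("ring bond with no preceding atom", smiles)
      key <- sub("^%", "", tok)
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, bond = pend)
      } else {
        open <- rings[[key]]
        type <- if (!is.na(pend)) pend else open$bond
        add_bond(open$atom, prev, type)
        rings[[key]] <- NULL
      }
      pend <- NA_character_
    } else if (tok == "(") {
      if (is.na(prev)) invalid_structure("branch with no preceding atom", smiles)
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) invalid_structure("unmatched ')'", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      if (!is.na(pend)) invalid_structure("bond before '.'", smiles)
      prev <- NA_integer_
    } else {
      invalid_structure(paste0("unrecognized token ", sQuote(tok)), smiles)
    }
  }
  if (length(rings) > 0L) invalid_structure("unclosed ring bond", smiles)
  if (!is.na(pend)) invalid_structure("dangling bond", smiles)
  if (length(stack) > 0L) invalid_structure("unmatched '('", smiles)
  if (na == 0L) invalid_structure("no atoms", smiles)
  length(element) <- na; length(aromatic) <- na; length(charge) <- na
  length(isotope) <- na; length(hcount) <- na; length(bracket) <- na
  structure(list(element = element, aromatic = aromatic, charge = charge,
                 isotope = isotope, hcount = hcount, bracket = bracket,
                 b_from = b_from, b_to = b_to, b_type = b_type, n = na),
            class = "mol_graph")
}

mol_adjacency <- function(g) {
  adj <- vector("list", g$n)
  for (b in seq_along(g$b_from)) {
    adj[[g$b_from[b]]] <- c(adj[[g$b_from[b]]], b)
    adj[[g$b_to[b]]] <- c(adj[[g$b_to[b]]], b)
  }
  adj
}

bond_other <- function(g, b, a) if (g$b_from[b] == a) g$b_to[b] else g$b_from[b]

mol_components <- function(g) {
  adj <- mol_adjacency(g)
  comp <- integer(g$n)
  k <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[a]]) {
        o <- bond_other(g, b, a)
        if (comp[o] == 0L) { comp[o] <- k; queue <- c(queue, o) }
      }
    }
  }
  comp
}

mol_subgraph <- function(g, atoms) {
  atoms <- sort(atoms)
  newid <- integer(g$n)
  newid[atoms] <- seq_along(atoms)
  keep_b <- which(newid[g$b_from] > 0L & newid[g$b_to] > 0L)
  structure(list(element = g$element[atoms], aromatic = g$aromatic[atoms],
                 charge = g$charge[atoms], isotope = g$isotope[atoms],
                 hcount = g$hcount[atoms], bracket = g$bracket[atoms],
                 b_from = newid[g$b_from[keep_b]], b_to = newid[g$b_to[keep_b]],
                 b_type = g$b_type[keep_b], n = length(atoms)),
            class = "mol_graph")
}

atom_token <- function(g, a) {
  el <- g$element[a]
  sym <- if (g$aromatic[a]) tolower(el) else el
  if (!g$bracket[a]) return(sym)
  h <- g$hcount[a]
  hpart <- if (is.na(h) || h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  chg <- g$charge[a]
  cpart <- if (chg == 0L) ""
           else if (chg == 1L) "+"
           else if (chg == -1L) "-"
           else if (chg > 0L) paste0("+", chg)
           else paste0("-", -chg)
  iso <- if (g$isotope[a] > 0L) as.character(g$isotope[a]) else ""
  paste0("[", iso, sym, hpart, cpart, "]")
}

bond_token <- function(g, b) {
  type <- g$b_type[b]
  both_arom <- g$aromatic[g$b_from[b]] && g$aromatic[g$b_to[b]]
  switch(type,
         "1" = if (both_arom) "-" else "",
         "ar" = if (both_arom) "" else ":",
         "2" = "=",
         "3" = "#")
}

ring_digit <- function(k) {
  if (k <= 9L) as.character(k)
  else if (k <= 99L) sprintf("%%%02d", k)
  else stop("too many simultaneous ring closures", call. = FALSE)
}

#' Write a molecular graph as SMILES under a given atom ordering
#'
#' Performs a depth-first traversal that starts, within each fragment, at
#' the atom with the smallest rank and visits neighbours in rank order.
#' Distinct rank vectors yield distinct but equivalent SMILES renderings of
#' the same molecule.
#'
#' @param g A `mol_graph`.
#' @param rank Numeric vector, one distinct value per atom.
#' @return A SMILES string.
#' @keywords internal
smiles_write <- function(g, rank = seq_len(g$n)) {
  stopifnot(length(rank) == g$n)
  adj <- mol_adjacency(g)
  visited <- logical(g$n)
  bond_used <- logical(length(g$b_from))
  children <- vector("list", g$n)   # per atom: list of (bond, atom) tree edges
  ring_at <- vector("list", g$n)    # per atom: list of (num, bond, closing)
  preorder <- integer(0)
  back_edges <- list()

  visit <- function(a) {
    visited[a] <<- TRUE
    preorder[length(preorder) + 1L] <<- a
    nb <- adj[[a]]
    if (length(nb) > 1L) nb <- nb[order(rank[vapply(nb, bond_other, 0L, g = g, a = a)])]
    for (b in nb) {
      if (bond_used[b]) next
      o <- bond_other(g, b, a)
      if (!visited[o]) {
        bond_used[b] <<- TRUE
        children[[a]][[length(children[[a]]) + 1L]] <<- c(b, o)
        visit(o)
      } else {
        bond_used[b] <<- TRUE
        back_edges[[length(back_edges) + 1L]] <<- c(o, a, b)  # earlier, later, bond
      }
    }
  }

  roots <- integer(0)
  for (a in order(rank)) {
    if (!visited[a]) { roots <- c(roots, a); visit(a) }
  }

  if (length(back_edges) > 0L) {
    pre_pos <- integer(g$n); pre_pos[preorder] <- seq_along(preorder)
    ord <- order(vapply(back_edges, function(e) pre_pos[e[1]], 0L),
                 vapply(back_edges, function(e) pre_pos[e[2]], 0L))
    for (k in seq_along(ord)) {
      e <- back_edges[[ord[k]]]
      ring_at[[e[1]]][[length(ring_at[[e[1]]]) + 1L]] <- list(num = k, bond = e[3], closing = FALSE)
      ring_at[[e[2]]][[length(ring_at[[e[2]]]) + 1L]] <- list(num = k, bond = e[3], closing = TRUE)
    }
  }

  emit <- function(a) {
    out <- atom_token(g, a)
    for (r in ring_at[[a]]) {
      sym <- if (r$closing) bond_token(g, r$bond) else ""
      out <- paste0(out, sym, ring_digit(r$num))
    }
    ch <- children[[a]]
    nch <- length(ch)
    if (nch > 0L) {
      for (i in seq_len(nch)) {
        b <- ch[[i]][1]; o <- ch[[i]][2]
        part <- paste0(bond_token(g, b), emit(o))
        out <- paste0(out, if (i < nch) paste0("(", part, ")") else part)
      }
    }
    out
  }

  paste(vapply(roots, emit, ""), collapse = ".")
}
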
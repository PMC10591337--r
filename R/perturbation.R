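# Robustness perturbations: methyl-group addition at a random substitutable
# position, and Gaussian distortion of Cartesian coordinates.

# Tokenize a SMILES string into atom tokens and everything between them.
# Returns a data frame with the start/end character positions of each atom
# token (bracket atoms, two-letter halogens, organic-subset symbols).
.smiles_atom_tokens <- function(smiles) {
  pat <- "\\[[^\\]]+\\]|Cl|Br|[BCNOPSFI]|[bcnops]"
  m <- gregexpr(pat, smiles)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Extend an atom-token end position past any ring-closure digits (optionally
# preceded by a bond symbol) and chirality/charge already sit inside brackets.
.skip_ring_closures <- function(smiles, pos) {
  n <- nchar(smiles)
  repeat {
    rest <- substr(smiles, pos + 1L, n)
    m <- regmatches(rest, regexpr("^[-=#:/\\\\]?(%\\d\\d|\\d)", rest))
    if (!length(m) || !nzchar(m)) break
    pos <- pos + nchar(m)
  }
  pos
}

#' Add one methyl group at a random substitutable position
#'
#' Picks one heavy atom bearing at least one (implicit) hydrogen uniformly at
#' random and replaces one of its hydrogens with a methyl group, increasing
#' the heavy-atom count by exactly one.  The site choice is seeded and
#' uniform over the eligible heavy atoms.
#'
#' @param smiles Input SMILES.
#' @param seed Integer seed for the site choice.
#' @return The perturbed SMILES string, with attributes `site` (the chosen
#'   atom index in graph order) and `n_eligible`.
#' @examples
#' \donttest{
#' add_methyl("C", seed = 1)   # methane -> ethane
#' }
#' @export
add_methyl <- function(smiles, seed = 1L) {
  g <- build_graph(smiles)
  eligible <- which(g$hydrogen_counts >= 1L)
  if (!length(eligible))
    stop("no substitutable site: no heavy atom carries a hydrogen", call. = FALSE)
  set.seed(seed)
  site <- eligible[sample.int(length(eligible), 1L)]

  toks <- .smiles_atom_tokens(smiles)
  if (nrow(toks) != g$n_atoms)
    stop("internal SMILES tokenization does not match the parsed atom count",
         call. = FALSE)
  tok_start <- toks$start[site]
  tok_end <- toks$end[site]
  atom_tok <- substr(smiles, tok_start, tok_end)
  # bracket atoms carry an explicit hydrogen count that must be decremented
  if (startsWith(atom_tok, "[")) {
    body <- substr(atom_tok, 2L, nchar(atom_tok) - 1L)
    new_body <- sub("H(?![0-9])", "", body, perl = TRUE)
    if (identical(new_body, body)) {
      hm <- regmatches(body, regexpr("H[0-9]+", body))
      if (length(hm)) {
        k <- as.integer(substring(hm, 2L))
        rep_h <- if (k <= 1L) "" else if (k == 2L) "H" else sprintf("H%d", k - 1L)
        new_body <- sub("H[0-9]+", rep_h, body)
      }
    }
    atom_tok <- paste0("[", new_body, "]")
  }
  ins <- .skip_ring_closures(smiles, tok_end)
  out <- paste0(substr(smiles, 1L, tok_start - 1L), atom_tok,
                substr(smiles, tok_end + 1L, ins), "(C)",
                substr(smiles, ins + 1L, nchar(smiles)))

  g2 <- tryCatch(build_graph(out), error = function(e) NULL)
  if (is.null(g2) || g2$n_atoms != g$n_atoms + 1L)
    stop(sprintf("methyl insertion produced an invalid molecule: '%s'", out),
         call. = FALSE)
  structure(out, site = site, n_eligible = length(eligible))
}

#' Gaussian distortion of Cartesian coordinates
#'
#' Adds independent zero-mean Gaussian noise with standard deviation `sigma`
#' (Angstrom) to every coordinate of every atom; `sigma = 0` returns the
#' input unchanged.  With many atoms the root-mean-square per-atom
#' displacement approaches `sigma * sqrt(3)`.
#'
#' @param coords `n x 3` coordinate matrix in Angstrom.
#' @param sigma Distortion parameter in Angstrom (>= 0); the reference
#'   protocol uses 0.02, 0.05 and 0.1.
#' @param seed Integer seed.
#' @return Distorted `n x 3` matrix.
#' @export
distort_coords <- function(coords, sigma, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) return(coords)
  set.seed(seed)
  coords + matrix(stats::rnorm(length(coords), 0, sigma), nrow(coords), 3L)
}
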
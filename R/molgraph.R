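# SMILES -> attributed heavy-atom molecular graphs.
#
# Parsing and perception (aromaticity, hybridization, hydrogen counts) are
# delegated to Open Babel through ChemmineOB; this module turns the perceived
# molecule into fixed-width node/edge encodings for the GNNs.

ELEMENT_VOCAB <- c("C", "N", "O", "F")
HYBRID_VOCAB <- c("sp", "sp2", "sp3", "other")
BOND_VOCAB <- c("single", "double", "triple", "aromatic")
#' Node feature vector length (4 element + 4 hybridization + 2 aromatic + H count)
#' @keywords internal
D_NODE <- 11L
# 4 bond-order one-hot + bond length (Angstrom) + length-presence flag
D_EDGE <- 6L

one_hot <- function(value, vocab) as.numeric(vocab == value)

#' Encode one heavy atom as a feature vector
#'
#' Concatenates one-hot element (`C,N,O,F`), one-hot hybridization
#' (`sp,sp2,sp3,other`), one-hot aromaticity (`not aromatic, aromatic`) and
#' the integer number of attached hydrogens; total length 11.  Hydrogens are
#' implicit: graphs contain heavy atoms only and hydrogen counts enter as a
#' node feature.
#'
#' @param element Element symbol, one of `C`, `N`, `O`, `F`.
#' @param hybridization One of `sp`, `sp2`, `sp3`, `other`.
#' @param aromatic Logical flag.
#' @param n_hydrogens Nonnegative integer count of attached hydrogens.
#' @return Numeric vector of length 11.
#' @examples
#' featurize_atom("C", "sp3", FALSE, 3)
#' @export
featurize_atom <- function(element, hybridization, aromatic, n_hydrogens) {
  if (!element %in% ELEMENT_VOCAB)
    stop(sprintf("unsupported element '%s' (expected one of %s)", element,
                 paste(ELEMENT_VOCAB, collapse = ", ")), call. = FALSE)
  if (!hybridization %in% HYBRID_VOCAB) hybridization <- "other"
  stopifnot(is.logical(aromatic), length(aromatic) == 1L,
            n_hydrogens >= 0)
  c(one_hot(element, ELEMENT_VOCAB),
    one_hot(hybridization, HYBRID_VOCAB),
    as.numeric(c(!aromatic, aromatic)),
    as.numeric(n_hydrogens))
}

# SYBYL atom type -> (element, hybridization) for the QM9 vocabulary.
.sybyl_parse <- function(atom_type) {
  parts <- strsplit(atom_type, ".", fixed = TRUE)[[1]]
  element <- parts[1]
  suffix <- if (length(parts) > 1) parts[2] else ""
  hyb <- switch(suffix,
                "1" = "sp", "2" = "sp2", "3" = "sp3",
                "ar" = "sp2", "am" = "sp2", "pl3" = "sp2", "co2" = "sp2",
                "other")
  list(element = element, hybridization = hyb, sybyl_aromatic = suffix == "ar")
}

# Convert a SMILES to TRIPOS MOL2 (explicit hydrogens) and parse atoms/bonds.
# Open Babel keeps the heavy atoms in SMILES order, which fixes the atom
# ordering of the graph deterministically.
.parse_smiles_mol2 <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", source = smiles,
                              options = data.frame(names = "h", args = "")),
    error = function(e) ""
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  if (!length(a0) || !length(b0) || b0 <= a0 + 1L)
    stop(sprintf("could not parse SMILES '%s'", smiles), call. = FALSE)
  atom_lines <- lines[(a0 + 1L):(b0 - 1L)]
  bond_lines <- lines[(b0 + 1L):length(lines)]
  bond_lines <- bond_lines[!grepl("^@|^\\s*$", bond_lines)]
  atoms <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "\\s+"),
                                 function(f) f[1:6]))
  bonds <- if (length(bond_lines))
    do.call(rbind, lapply(strsplit(trimws(bond_lines), "\\s+"),
                          function(f) f[1:4]))
  else matrix(character(0), 0, 4)
  list(
    atom_type = atoms[, 6],
    bond_from = as.integer(bonds[, 2]),
    bond_to = as.integer(bonds[, 3]),
    bond_type = bonds[, 4]
  )
}

#' Build an attributed heavy-atom molecular graph from SMILES
#'
#' Parses the SMILES with Open Babel, folds hydrogens into per-atom counts,
#' and encodes nodes with [featurize_atom()].  Edge features are a one-hot
#' bond order (`single`, `double`, `triple`, `aromatic`; amide bonds count as
#' single) followed by the bond length in Angstrom and a presence flag; the
#' length is 0 with flag 0 when no coordinates are supplied.  Atom order is
#' the heavy-atom order of the SMILES string, so the same SMILES always
#' yields the same graph.
#'
#' @param smiles A SMILES string over H, C, N, O, F.
#' @param coords Optional `n_atoms x 3` matrix of Cartesian coordinates in
#'   Angstrom, in graph atom order (heavy atoms only).
#' @param molecule_id Optional identifier; defaults to the SMILES.
#' @return An object of class `molecular_graph` with fields `molecule_id`,
#'   `smiles`, `n_atoms`, `elements`, `hydrogen_counts`, `aromatic`,
#'   `hybridization`, `node_features` (`n_atoms x 11`), `edges` (two-column
#'   matrix of undirected atom-index pairs, 1-based), `edge_features`
#'   (`n_edges x 6`) and `coords` (matrix or `NULL`).
#' @examples
#' \donttest{
#' g <- build_graph("CCO")
#' g$n_atoms            # 3
#' g$hydrogen_counts    # 3 2 1
#' }
#' @export
build_graph <- function(smiles, coords = NULL, molecule_id = smiles) {
  m <- .parse_smiles_mol2(smiles)
  parsed <- lapply(m$atom_type, .sybyl_parse)
  elements <- vapply(parsed, `[[`, "", "element")
  heavy <- which(elements != "H")
  n_atoms <- length(heavy)
  if (!n_atoms) stop("molecule has no heavy atoms", call. = FALSE)
  bad <- setdiff(unique(elements[heavy]), ELEMENT_VOCAB)
  if (length(bad))
    stop(sprintf("unsupported element '%s'", bad[1]), call. = FALSE)
  idx_of <- integer(length(elements))  # mol2 index -> heavy index (0 for H)
  idx_of[heavy] <- seq_len(n_atoms)

  h_counts <- integer(n_atoms)
  edges <- matrix(integer(0), 0, 2)
  bond_orders <- character(0)
  for (k in seq_along(m$bond_from)) {
    a <- m$bond_from[k]; b <- m$bond_to[k]
    ha <- elements[a] == "H"; hb <- elements[b] == "H"
    if (ha && hb) next
    if (ha || hb) {
      heavy_end <- if (ha) b else a
      h_counts[idx_of[heavy_end]] <- h_counts[idx_of[heavy_end]] + 1L
    } else {
      edges <- rbind(edges, c(idx_of[a], idx_of[b]))
      bond_orders <- c(bond_orders, switch(m$bond_type[k],
                                           "1" = "single", "2" = "double",
                                           "3" = "triple", "ar" = "aromatic",
                                           "am" = "single", "single"))
    }
  }

  aromatic <- vapply(parsed[heavy], `[[`, TRUE, "sybyl_aromatic")
  if (nrow(edges)) {
    ar_bonds <- which(bond_orders == "aromatic")
    aromatic[unique(as.integer(edges[ar_bonds, ]))] <- TRUE
  }
  hyb <- vapply(parsed[heavy], `[[`, "", "hybridization")

  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_atoms || ncol(coords) != 3L)
      stop(sprintf(
        "coordinate block has %d rows but the molecule has %d heavy atoms",
        nrow(coords), n_atoms), call. = FALSE)
    storage.mode(coords) <- "double"
  }

  node_features <- t(vapply(seq_len(n_atoms), function(i)
    featurize_atom(elements[heavy][i], hyb[i], aromatic[i], h_counts[i]),
    numeric(D_NODE)))
  if (n_atoms == 1L) node_features <- matrix(node_features, 1L, D_NODE)

  edge_features <- matrix(0, nrow(edges), D_EDGE)
  for (k in seq_len(nrow(edges))) {
    edge_features[k, 1:4] <- one_hot(bond_orders[k], BOND_VOCAB)
    if (!is.null(coords)) {
      edge_features[k, 5] <- sqrt(sum((coords[edges[k, 1], ] -
                                         coords[edges[k, 2], ])^2))
      edge_features[k, 6] <- 1
    }
  }

  structure(
    list(molecule_id = molecule_id, smiles = smiles, n_atoms = n_atoms,
         elements = elements[heavy], hydrogen_counts = h_counts,
         aromatic = aromatic, hybridization = hyb,
         node_features = node_features, edges = edges,
         edge_features = edge_features, coords = coords),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d heavy atoms, %d bonds\n",
              x$molecule_id, x$n_atoms, nrow(x$edges)))
  invisible(x)
}

#' Indices of carbon atoms in a molecular graph
#'
#' Carbon K-edge spectra arise from carbon 1s cores, so attribution and
#' ground-truth labeling repeatedly need the carbon positions.
#'
#' @param graph A `molecular_graph`.
#' @return Integer vector of carbon atom indices (1-based, graph order).
#' @export
carbon_indices <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  which(graph$elements == "C")
}

#' Read an XYZ coordinate file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` rows in
#' Angstrom.
#'
#' @param path File path.
#' @return List with `elements` (character) and `coords` (`n x 3` matrix).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(rows, `[[`, "", 1L)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(elements = elements, coords = coords)
}

#' Write an XYZ coordinate file
#'
#' @param elements Character vector of element symbols.
#' @param coords `n x 3` coordinate matrix in Angstrom.
#' @param path File path.
#' @param comment Second-line comment.
#' @export
write_xyz <- function(elements, coords, path, comment = "") {
  stopifnot(length(elements) == nrow(coords))
  lines <- c(length(elements), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", elements,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SMILES file
#'
#' One molecule per line; an optional tab-separated second field is the
#' molecule id.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `molecule_id`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[[`, "", 1L),
    molecule_id = vapply(parts, function(p)
      if (length(p) > 1L) p[2] else p[1], ""),
    stringsAsFactors = FALSE
  )
}
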
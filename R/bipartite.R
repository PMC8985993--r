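# Element-specific weighted bipartite graphs between protein and ligand
# atoms.  A biadjacency is the dense weight matrix B(v_i, v_j) = w_ij with
# protein atoms on the rows and ligand atoms on the columns; w_ij is either
# the Euclidean distance d(v_i, v_j) in Angstrom, or the logistic
# electrostatic weight 1 / (1 + exp(-c q_i q_j / d(v_i, v_j))).

#' Element-pair groups for a featurization mode
#'
#' Distance mode pairs protein heavy atoms \{C,N,O,S\} with ligand heavy
#' atoms \{C,N,O,S,P,F,Cl,Br,I\} (36 groups); electrostatic mode adds
#' hydrogen on both sides (50 groups).  The order is protein-element major,
#' ligand-element minor, in the fixed element orders above; this order
#' defines the feature-vector layout and never changes.
#'
#' @param mode `"distance"` or `"electrostatic"`.
#' @return data.frame with columns `protein_element`, `ligand_element`.
#' @export
element_groups <- function(mode = c("distance", "electrostatic")) {
  mode <- match.arg(mode)
  pe <- if (mode == "distance") PROTEIN_ELEMENTS_DISTANCE else
    PROTEIN_ELEMENTS_ELECTROSTATIC
  le <- if (mode == "distance") LIGAND_ELEMENTS_DISTANCE else
    LIGAND_ELEMENTS_ELECTROSTATIC
  data.frame(
    protein_element = rep(pe, each = length(le)),
    ligand_element = rep(le, times = length(pe)),
    stringsAsFactors = FALSE
  )
}

#' Split a complex into element-pair atom groups
#'
#' Returns one entry per element-pair group, in the fixed layout order,
#' with the row indices of the matching protein and ligand atoms.  Empty
#' subsets are preserved (they later contribute all-zero feature blocks so
#' vectors keep a fixed length).
#'
#' @param complex a `molecular_complex`.
#' @param mode `"distance"` or `"electrostatic"`.
#' @return list of lists with elements `protein_element`, `ligand_element`,
#'   `protein_idx`, `ligand_idx`.
#' @export
group_atom_pairs <- function(complex, mode = c("distance", "electrostatic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(complex, "molecular_complex"))
  groups <- element_groups(mode)
  lapply(seq_len(nrow(groups)), function(g) {
    pe <- groups$protein_element[g]
    le <- groups$ligand_element[g]
    list(
      protein_element = pe,
      ligand_element = le,
      protein_idx = which(complex$protein$element == pe),
      ligand_idx = which(complex$ligand$element == le)
    )
  })
}

.biadjacency <- function(weights, mode) {
  structure(list(weights = weights, mode = mode), class = "dc_biadjacency")
}

# Accept either a dc_biadjacency or a bare weight matrix everywhere
# downstream.
.weights_of <- function(B) {
  if (inherits(B, "dc_biadjacency")) B$weights else as.matrix(B)
}

#' Distance-weighted biadjacency matrix
#'
#' `weights[i, j]` is the Euclidean distance in Angstrom between protein
#' atom i and ligand atom j.  Empty subsets give a 0-row or 0-column
#' matrix.
#'
#' @param P,L atom tables (possibly 0-row).
#' @return a `dc_biadjacency` with an `nrow(P) x nrow(L)` weight matrix.
#' @export
distance_biadjacency <- function(P, L) {
  if (nrow(P) == 0L || nrow(L) == 0L) {
    return(.biadjacency(matrix(numeric(0), nrow(P), nrow(L)), "distance"))
  }
  .biadjacency(.pairwise_distances(P, L), "distance")
}

#' Electrostatic biadjacency matrix
#'
#' `weights[i, j] = 1 / (1 + exp(-c q_i q_j / d(v_i, v_j)))`, a logistic
#' weight in the open interval (0, 1).  Opposite charges give weights below
#' 1/2 (attractive pairs enter the filtration early), like charges above
#' 1/2, and uncharged pairs sit exactly at 1/2.
#'
#' @param P,L atom tables; every atom must carry a charge.
#' @param c coupling constant (default 100).
#' @return a `dc_biadjacency` with weights in (0, 1).
#' @export
electrostatic_biadjacency <- function(P, L, c = 100) {
  if (nrow(P) == 0L || nrow(L) == 0L) {
    return(.biadjacency(matrix(numeric(0), nrow(P), nrow(L)),
                        "electrostatic"))
  }
  for (side in list(P = P, L = L)) {
    miss <- is.na(side$charge)
    if (any(miss)) {
      stop("missing partial charge for atom serial(s): ",
           paste(side$serial[miss], collapse = ", "))
    }
  }
  d <- .pairwise_distances(P, L)
  if (any(d == 0)) {
    ij <- which(d == 0, arr.ind = TRUE)[1L, ]
    stop("coincident atoms (protein serial ", P$serial[ij[1]],
         ", ligand serial ", L$serial[ij[2]],
         "): electrostatic weight undefined at zero distance")
  }
  qq <- outer(P$charge, L$charge)
  w <- 1 / (1 + exp(-c * qq / d))
  # keep weights strictly inside (0,1) even when the exponent overflows
  eps <- .Machine$double.xmin
  w[w <= 0] <- eps
  w[w >= 1] <- 1 - .Machine$double.eps
  .biadjacency(w, "electrostatic")
}

#' @export
print.dc_biadjacency <- function(x, ...) {
  cat("Biadjacency (", x$mode, " mode): ",
      nrow(x$weights), " protein x ", ncol(x$weights), " ligand atoms\n",
      sep = "")
  invisible(x)
}
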
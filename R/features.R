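# Riemann-zeta spectral descriptors along the filtration, and assembly of
# fixed-layout feature vectors.
#
# For a Laplacian spectrum {lambda_i} the zeta descriptor is
#   zeta(s) = sum over nonzero lambda_i of lambda_i^(-s).
# Zero eigenvalues are excluded for every s — the only convention under
# which all eleven exponents are finite (zeta(s) diverges at lambda = 0 for
# s > 0).  Consequently zeta(0) equals the rank of the Laplacian and
# zeta(-1) its trace.

#' The eleven zeta exponents
#'
#' Fixed order s = 5, 4, 3, 2, 1, 0, -1, -2, -3, -4, -5; this order defines
#' the innermost stride of the feature layout.
#' @export
ZETA_EXPONENTS <- c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4, -5)

#' Spectral zeta function of a Laplacian spectrum
#'
#' @param spectrum numeric vector of eigenvalues (any order).
#' @param s exponent.
#' @param tol relative zero tolerance; eigenvalues at or below it are
#'   excluded.
#' @return `sum(lambda^(-s))` over the nonzero eigenvalues; 0 for an empty
#'   or all-zero spectrum.
#' @export
zeta <- function(spectrum, s, tol = ZERO_EIGENVALUE_TOL) {
  lam <- spectrum[spectrum >= .zero_threshold(spectrum, tol)]
  if (length(lam) == 0L) return(0)
  sum(lam^(-s))
}

.zeta_row <- function(spectrum, tol = ZERO_EIGENVALUE_TOL) {
  lam <- spectrum[spectrum >= .zero_threshold(spectrum, tol)]
  if (length(lam) == 0L) return(numeric(length(ZETA_EXPONENTS)))
  vapply(ZETA_EXPONENTS, function(s) sum(lam^(-s)), numeric(1))
}

# Fast 0-D spectral curve of one side of a weighted bipartite graph.
#
# Only edges matter for the zeta values: isolated-but-present vertices add
# zero eigenvalues, which every zeta excludes.  For side vertices i, i' the
# edge (i, i') enters the filtration at
#   f_e(i, i') = min over witnesses j of max(W[i, j], W[i', j]),
# the smallest threshold at which some witness relates to both.  The
# spectrum changes only when the threshold crosses one of these critical
# values, so each distinct edge set is decomposed once and shared across
# grid values.
.zeta_curve_side <- function(W, grid, tol = ZERO_EIGENVALUE_TOL) {
  ns <- length(ZETA_EXPONENTS)
  out <- matrix(0, length(grid), ns)
  n1 <- nrow(W); n2 <- ncol(W)
  if (n1 == 0L || n2 == 0L) return(out)
  FE <- matrix(Inf, n1, n1)
  for (j in seq_len(n2)) {
    cj <- W[, j]
    FE <- pmin(FE, outer(cj, cj, pmax))
  }
  diag(FE) <- Inf
  crit <- FE[upper.tri(FE)]
  crit <- sort(unique(crit[crit <= max(grid)]))
  if (length(crit) == 0L) return(out)
  # state index per grid value = number of critical values passed
  state <- findInterval(grid, crit)
  cache <- vector("list", length(crit))
  for (r in seq_along(grid)) {
    s <- state[r]
    if (s == 0L) next
    if (is.null(cache[[s]])) {
      adj <- FE <= crit[s]
      deg <- rowSums(adj)
      keep <- deg > 0
      A <- adj[keep, keep, drop = FALSE]
      L <- diag(rowSums(A), nrow(A)) - A
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      cache[[s]] <- .zeta_row(ev, tol)
    }
    out[r, ] <- cache[[s]]
  }
  out
}

#' Persistent zeta curve of one Dowker side
#'
#' Row i holds the eleven zeta descriptors of the 0-dimensional Hodge
#' Laplacian of the chosen side's Dowker complex at grid value i.  Grid
#' values at which the complex is empty (or edgeless) give all-zero rows.
#'
#' @param B a `dc_biadjacency` or bare weight matrix.
#' @param grid increasing numeric thresholds.
#' @param side `"protein"` or `"ligand"`.
#' @param tol relative zero tolerance.
#' @return `length(grid) x 11` numeric matrix; columns named by exponent.
#' @export
persistent_zeta_curve <- function(B, grid, side = c("protein", "ligand"),
                                  tol = ZERO_EIGENVALUE_TOL) {
  side <- match.arg(side)
  W <- .weights_of(B)
  if (side == "ligand") W <- t(W)
  out <- .zeta_curve_side(W, grid, tol)
  colnames(out) <- paste0("s", ZETA_EXPONENTS)
  out
}

#' Betti-number curves of both Dowker sides
#'
#' Convenience view of the filtration: beta_0 and beta_1 of each side at
#' every grid value (computed through the Laplacian kernel).
#'
#' @inheritParams persistent_zeta_curve
#' @param max_dim maximum dimension enumerated (must be at least 2 for
#'   beta_1).
#' @param vertex_rule vertex convention, see [build_dowker_pair()].
#' @return data.frame with columns `f`, `beta0_protein`, `beta1_protein`,
#'   `beta0_ligand`, `beta1_ligand`.
#' @export
betti_curves <- function(B, grid, max_dim = 2L,
                         vertex_rule = c("dowker", "all")) {
  vertex_rule <- match.arg(vertex_rule)
  rows <- lapply(grid, function(f) {
    pair <- build_dowker_pair(B, f, max_dim, vertex_rule)
    c(f = f,
      beta0_protein = betti_number(pair$protein, 0L),
      beta1_protein = betti_number(pair$protein, 1L),
      beta0_ligand = betti_number(pair$ligand, 0L),
      beta1_ligand = betti_number(pair$ligand, 1L))
  })
  as.data.frame(do.call(rbind, rows))
}

.mode_grid <- function(mode) filtration_grid(mode)

.featurize_one_mode <- function(complex, mode, c_elec = 100,
                                tol = ZERO_EIGENVALUE_TOL) {
  groups <- group_atom_pairs(complex, mode)
  grid <- .mode_grid(mode)
  blocks <- lapply(groups, function(g) {
    P <- complex$protein[g$protein_idx, , drop = FALSE]
    L <- complex$ligand[g$ligand_idx, , drop = FALSE]
    B <- if (mode == "distance") distance_biadjacency(P, L) else
      electrostatic_biadjacency(P, L, c = c_elec)
    cp <- persistent_zeta_curve(B, grid, "protein", tol)
    cl <- persistent_zeta_curve(B, grid, "ligand", tol)
    # layout within a group: protein side then ligand side; within a side,
    # filtration-major, exponent-minor
    c(as.vector(t(cp)), as.vector(t(cl)))
  })
  unlist(blocks, use.names = FALSE)
}

#' Feature-vector length of a mode
#'
#' 63,360 for distance (36 groups x 80 grid values x 11 exponents x 2
#' sides), 55,000 for electrostatic (50 x 50 x 11 x 2), 118,360 combined.
#'
#' @param mode `"distance"`, `"electrostatic"` or `"combined"`.
#' @return integer length.
#' @export
feature_length <- function(mode = c("distance", "electrostatic", "combined")) {
  mode <- match.arg(mode)
  len <- function(m) {
    nrow(element_groups(m)) * length(filtration_grid(m)) *
      length(ZETA_EXPONENTS) * 2L
  }
  switch(mode,
         distance = len("distance"),
         electrostatic = len("electrostatic"),
         combined = len("distance") + len("electrostatic"))
}

#' Feature index names of a mode
#'
#' Names encode the layout `mode_group_side_f<threshold>_s<exponent>` in
#' vector order: group-major (protein element then ligand element, fixed
#' element orders), then side (protein first), then ascending filtration,
#' then the exponents 5 ... -5.
#'
#' @inheritParams feature_length
#' @return character vector of length [feature_length()].
#' @export
feature_names <- function(mode = c("distance", "electrostatic", "combined")) {
  mode <- match.arg(mode)
  if (mode == "combined") {
    return(c(feature_names("distance"), feature_names("electrostatic")))
  }
  groups <- element_groups(mode)
  grid <- filtration_grid(mode)
  tag <- if (mode == "distance") "d" else "e"
  g_lab <- paste0(groups$protein_element, ".", groups$ligand_element)
  as.vector(vapply(g_lab, function(g) {
    as.vector(vapply(c("P", "L"), function(side) {
      as.vector(vapply(grid, function(f) {
        paste0(tag, "_", g, "_", side, "_f", format(f), "_s", ZETA_EXPONENTS)
      }, character(length(ZETA_EXPONENTS))))
    }, character(length(grid) * length(ZETA_EXPONENTS))))
  }, character(2L * length(grid) * length(ZETA_EXPONENTS))))
}

#' Featurize a molecular complex
#'
#' Computes the fixed-layout persistent-zeta descriptor of a binding core.
#' Empty element groups contribute all-zero blocks, so the length depends
#' only on the mode.  Electrostatic and combined modes require partial
#' charges on every grouped atom.
#'
#' @param complex a `molecular_complex` (normally the output of
#'   [extract_binding_core()]).
#' @param mode `"distance"`, `"electrostatic"` or `"combined"`.
#' @param c_elec electrostatic coupling constant (default 100).
#' @param tol relative zero tolerance for eigenvalues.
#' @return named numeric vector of length [feature_length()].
#' @export
featurize_complex <- function(complex,
                              mode = c("distance", "electrostatic",
                                       "combined"),
                              c_elec = 100, tol = ZERO_EIGENVALUE_TOL) {
  mode <- match.arg(mode)
  stopifnot(inherits(complex, "molecular_complex"))
  v <- if (mode == "combined") {
    c(.featurize_one_mode(complex, "distance", c_elec, tol),
      .featurize_one_mode(complex, "electrostatic", c_elec, tol))
  } else {
    .featurize_one_mode(complex, mode, c_elec, tol)
  }
  stats::setNames(v, feature_names(mode))
}

#' Featurize a list of complexes
#'
#' @param complexes list of `molecular_complex` objects.
#' @param mode featurization mode.
#' @param require_labels error when any complex lacks a label (training
#'   context).
#' @param ... passed to [featurize_complex()].
#' @return list with `x` (matrix, one row per complex, rows in input
#'   order) and `y` (numeric label vector, NA where absent).
#' @export
featurize_dataset <- function(complexes,
                              mode = c("distance", "electrostatic",
                                       "combined"),
                              require_labels = FALSE, ...) {
  mode <- match.arg(mode)
  stopifnot(length(complexes) > 0L)
  y <- vapply(complexes, function(cx) cx$label, numeric(1))
  if (require_labels && any(is.na(y))) {
    stop("missing affinity label for complex(es): ",
         paste(vapply(complexes[is.na(y)], `[[`, "", "id"), collapse = ", "))
  }
  x <- t(vapply(complexes, featurize_complex, numeric(feature_length(mode)),
                mode = mode, ...))
  rownames(x) <- vapply(complexes, `[[`, "", "id")
  list(x = x, y = y)
}
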
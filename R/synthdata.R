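# Synthetic protein-ligand binding cores, random bipartite graphs, named
# fixtures, and an independent rank-based homology oracle.  Everything is
# driven by explicit integer seeds and leaves the caller's RNG state
# untouched.

#' Evaluate an expression under a private RNG seed
#'
#' Saves and restores `.Random.seed`, so synthetic generators never leak
#' random state into the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default element frequencies for synthetic binding cores
#'
#' Approximate all-atom element compositions: protein sites are about half
#' hydrogen with carbon dominating the heavy atoms; drug-like ligands add
#' occasional S/P and halogens.
#'
#' @return list with components `protein` and `ligand`, each a named
#'   probability vector over the element universes.
#' @export
default_element_frequencies <- function() {
  list(
    protein = c(C = 0.32, N = 0.09, O = 0.10, S = 0.01, H = 0.48),
    ligand = c(C = 0.36, N = 0.06, O = 0.08, S = 0.01, P = 0.01,
               F = 0.02, Cl = 0.02, Br = 0.005, I = 0.005, H = 0.43)
  )
}

#' Specification of a synthetic binding core
#'
#' @param n_protein,n_ligand atom counts (>= 1).
#' @param box_edge edge of the cubic bounding box in Angstrom.
#' @param charge_range interval for uniform partial charges (elementary
#'   charges).
#' @param element_frequencies list as in [default_element_frequencies()].
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_protein = 40L, n_ligand = 12L, box_edge = 20,
                           charge_range = c(-1, 1),
                           element_frequencies =
                             default_element_frequencies()) {
  if (n_protein < 1L || n_ligand < 1L) stop("atom counts must be >= 1")
  if (box_edge <= 0) stop("box_edge must be > 0")
  structure(
    list(n_protein = as.integer(n_protein), n_ligand = as.integer(n_ligand),
         box_edge = box_edge, charge_range = charge_range,
         element_frequencies = element_frequencies),
    class = "synthetic_spec"
  )
}

#' Generate a random synthetic binding core
#'
#' Ligand atoms are placed uniformly in a central sub-box (a third of the
#' box edge) and protein atoms uniformly in the full box, emulating a
#' pocket surrounding a bound ligand; elements are drawn from the spec's
#' frequencies and charges uniformly from the charge range.  With
#' `planted_label = TRUE` the affinity label is a stated monotone function
#' of the number of heavy-atom protein-ligand contacts within
#' `contact_cutoff`: `label = 1 + 0.05 * contacts + N(0, noise_sd)`, with
#' the noiseless value attached as attribute `"noiseless_label"` for
#' recovery tests.  Contacts are counted over heavy atoms (the element
#' universe of the distance-mode graphs) so the planted signal lies in the
#' support of the descriptor under test; hydrogen positions act as pure
#' nuisance structure.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer seed; the same seed reproduces the same complex.
#' @param planted_label plant an affinity label (default `FALSE`).
#' @param noise_sd Gaussian noise standard deviation on the planted label.
#' @param contact_cutoff contact distance in Angstrom (default 5).
#' @param id complex identifier.
#' @return a `molecular_complex`.
#' @export
random_complex <- function(spec = synthetic_spec(), seed = 1L,
                           planted_label = FALSE, noise_sd = 0.3,
                           contact_cutoff = 5, id = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(id)) id <- paste0("synth", seed)
  with_seed(seed, {
    ef <- spec$element_frequencies
    draw_atoms <- function(n, freq, lo, hi) {
      .atom_table(
        serial = seq_len(n),
        element = sample(names(freq), n, replace = TRUE,
                         prob = freq / sum(freq)),
        x = stats::runif(n, lo, hi),
        y = stats::runif(n, lo, hi),
        z = stats::runif(n, lo, hi),
        charge = stats::runif(n, spec$charge_range[1], spec$charge_range[2])
      )
    }
    e <- spec$box_edge
    lig <- draw_atoms(spec$n_ligand, ef$ligand, e / 3, 2 * e / 3)
    prot <- draw_atoms(spec$n_protein, ef$protein, 0, e)
    cx <- molecular_complex(prot, lig, id = id)
    if (planted_label) {
      ph <- prot[prot$element != "H", , drop = FALSE]
      lh <- lig[lig$element != "H", , drop = FALSE]
      contacts <- sum(.pairwise_distances(ph, lh) <= contact_cutoff)
      noiseless <- 1 + 0.05 * contacts
      cx$label <- noiseless + stats::rnorm(1, 0, noise_sd)
      attr(cx, "noiseless_label") <- noiseless
    }
    cx
  })
}

#' Generate a synthetic binding-affinity dataset
#'
#' Draws `n` binding cores whose atom counts vary from complex to complex
#' (uniformly over the given ranges), emulating the size variability of
#' real pockets and ligands — the dominant natural source of
#' contact-count, and hence affinity, variation.  Labels are planted as in
#' [random_complex()].
#'
#' @param n number of complexes.
#' @param seed integer seed driving both the size draws and the
#'   per-complex generators.
#' @param n_protein_range,n_ligand_range inclusive integer ranges of atom
#'   counts per side.
#' @param box_edge,charge_range,element_frequencies as in
#'   [synthetic_spec()].
#' @param noise_sd,contact_cutoff as in [random_complex()].
#' @return list of `molecular_complex` objects with planted labels.
#' @export
random_complex_set <- function(n, seed = 1L,
                               n_protein_range = c(30L, 60L),
                               n_ligand_range = c(8L, 20L),
                               box_edge = 20, charge_range = c(-1, 1),
                               element_frequencies =
                                 default_element_frequencies(),
                               noise_sd = 0.3, contact_cutoff = 5) {
  draws <- with_seed(seed, list(
    np = sample(n_protein_range[1]:n_protein_range[2], n, replace = TRUE),
    nl = sample(n_ligand_range[1]:n_ligand_range[2], n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  lapply(seq_len(n), function(i) {
    spec <- synthetic_spec(draws$np[i], draws$nl[i], box_edge,
                           charge_range, element_frequencies)
    random_complex(spec, seed = draws$seeds[i], planted_label = TRUE,
                   noise_sd = noise_sd, contact_cutoff = contact_cutoff,
                   id = sprintf("synth%03d", i))
  })
}

#' Random weighted bipartite graph
#'
#' `law = "uniform"` draws i.i.d. weights from `range`; `law =
#' "bernoulli"` places an edge of weight 1 with probability `density` and
#' weight `Inf` otherwise (so any finite threshold recovers the unweighted
#' graph).
#'
#' @param n1,n2 vertex counts (>= 1).
#' @param seed integer seed.
#' @param law `"uniform"` or `"bernoulli"`.
#' @param density edge probability for the Bernoulli law.
#' @param range weight range for the uniform law.
#' @return a `dc_biadjacency` with an `n1 x n2` weight matrix.
#' @export
random_bipartite <- function(n1, n2, seed = 1L,
                             law = c("uniform", "bernoulli"),
                             density = 0.5, range = c(0, 1)) {
  law <- match.arg(law)
  if (n1 < 1L || n2 < 1L) stop("n1 and n2 must be >= 1")
  W <- with_seed(seed, {
    if (law == "uniform") {
      matrix(stats::runif(n1 * n2, range[1], range[2]), n1, n2)
    } else {
      matrix(ifelse(stats::runif(n1 * n2) < density, 1, Inf), n1, n2)
    }
  })
  .biadjacency(W, "synthetic")
}

#' Rank-based homology oracle
#'
#' Computes `beta_k = nullity(B_k) - rank(B_{k+1})` by singular values of
#' the boundary matrices — no eigensolver involved, so it is an
#' independent check on [betti_number()].  The nullity of the absent `B_0`
#' is the number of vertices.
#'
#' @param K a `dowker_complex` with `max_dim >= k + 1` (so `B_{k+1}` is
#'   enumerated).
#' @param k dimension.
#' @param tol relative singular-value tolerance (same zero rule as the
#'   eigensolver).
#' @return non-negative integer.
#' @export
homology_oracle <- function(K, k, tol = ZERO_EIGENVALUE_TOL) {
  stopifnot(inherits(K, "dowker_complex"))
  nk <- n_simplices(K, k)
  if (nk == 0L) return(0L)
  mat_rank <- function(M) {
    if (length(M) == 0L) return(0L)
    sv <- svd(M, nu = 0, nv = 0)$d
    sum(sv > tol * max(1, sv[1L]))
  }
  nullity_k <- if (k == 0L) nk else nk - mat_rank(boundary_matrix(K, k))
  rank_k1 <- if (k < K$max_dim && n_simplices(K, k + 1L) > 0L) {
    mat_rank(boundary_matrix(K, k + 1L))
  } else 0L
  as.integer(nullity_k - rank_k1)
}

#' Named combinatorial and geometric fixtures
#'
#' Small hand-verified objects used throughout the tests:
#' \describe{
#'   \item{`star`}{three protein vertices all related to one ligand
#'     witness: the protein side is a full 2-simplex, the ligand side a
#'     single vertex.}
#'   \item{`hexagon`}{a 6-cycle as a bipartite graph (3 + 3 vertices):
#'     both Dowker sides are hollow triangles with beta_1 = 1.}
#'   \item{`two_components`}{two star components: beta_0 = 2 on both
#'     sides once both components exist, but the sides differ at
#'     thresholds where the graph is disconnected with an edgeless
#'     vertex.}
#'   \item{`flag_vs_dowker`}{three protein vertices pairwise related via
#'     distinct witnesses, with no common witness: the three edges exist
#'     but no 2-simplex, while the flag (clique) complex of the projection
#'     graph would fill the triangle.}
#'   \item{`two_chains`}{two interleaved helical point chains with their
#'     distance biadjacency — a geometric filtration whose beta_1 curves
#'     agree on both sides.}
#' }
#'
#' @param name fixture name.
#' @return list with at least `W` (weight matrix), `description`, and
#'   fixture-specific expected values.
#' @export
fixture <- function(name = c("star", "hexagon", "two_components",
                             "flag_vs_dowker", "two_chains")) {
  name <- match.arg(name)
  edge_matrix <- function(n1, n2, edges) {
    W <- matrix(Inf, n1, n2)
    for (e in edges) W[e[1], e[2]] <- 1
    W
  }
  switch(name,
    star = list(
      W = edge_matrix(3, 1, list(c(1, 1), c(2, 1), c(3, 1))),
      description = "one witness relating three vertices",
      expected = list(protein = c(beta0 = 1L, beta1 = 0L),
                      ligand = c(beta0 = 1L, beta1 = 0L))
    ),
    hexagon = list(
      W = edge_matrix(3, 3, list(c(1, 1), c(2, 1), c(2, 2), c(3, 2),
                                 c(3, 3), c(1, 3))),
      description = "6-cycle: hollow triangle on each side",
      expected = list(protein = c(beta0 = 1L, beta1 = 1L),
                      ligand = c(beta0 = 1L, beta1 = 1L))
    ),
    two_components = list(
      W = edge_matrix(4, 2, list(c(1, 1), c(2, 1), c(3, 2), c(4, 2))),
      description = "two disjoint stars",
      expected = list(protein = c(beta0 = 2L, beta1 = 0L),
                      ligand = c(beta0 = 2L, beta1 = 0L))
    ),
    flag_vs_dowker = list(
      W = edge_matrix(3, 3, list(c(1, 1), c(2, 1), c(2, 2), c(3, 2),
                                 c(1, 3), c(3, 3))),
      description = paste("pairwise witnesses, no common witness:",
                          "Dowker complex is a hollow triangle,",
                          "flag complex of the projection is filled"),
      expected = list(protein = c(beta0 = 1L, beta1 = 1L))
    ),
    two_chains = local({
      t1 <- seq(0, 4 * pi, length.out = 24)
      chain <- function(phase) {
        data.frame(serial = seq_along(t1), element = "P",
                   x = 6 * cos(t1 + phase), y = 6 * sin(t1 + phase),
                   z = 1.5 * t1, charge = NA_real_,
                   stringsAsFactors = FALSE)
      }
      a <- chain(0); b <- chain(pi)
      list(W = .pairwise_distances(a, b), chain_a = a, chain_b = b,
           description = "two interleaved helical chains (distance weights)")
    })
  )
}
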
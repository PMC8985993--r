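test_that("zeta closed forms hold, with zero eigenvalues excluded", {
  expect_equal(zeta(c(1, 2), 2), 1.25)
  expect_equal(zeta(c(0, 2), 1), 0.5)
  expect_equal(zeta(c(2, 2, 2), -1), 6)          # trace
  expect_equal(zeta(c(0, 1, 3), 0), 2)           # rank
  expect_equal(zeta(numeric(0), 3), 0)
  expect_equal(zeta(c(0, 0), -2), 0)
})

test_that("zeta curves are zero until edges exist and saturate on K_n", {
  # all weights above the grid maximum: nothing ever appears
  W <- matrix(5, 3, 2)
  expect_equal(persistent_zeta_curve(W, seq(0.1, 1, by = 0.1), "protein"),
               persistent_zeta_curve(W, seq(0.1, 1, by = 0.1), "protein") * 0)
  # star with n vertices saturates to the complete graph
  n <- 5
  curve <- persistent_zeta_curve(matrix(0.5, n, 1), c(0.1, 1), "protein")
  expect_equal(curve[1, ], setNames(rep(0, 11), paste0("s", ZETA_EXPONENTS)))
  expect_equal(unname(curve[2, "s0"]), n - 1)        # rank of L_0(K_n)
  expect_equal(unname(curve[2, "s-1"]), n * (n - 1)) # trace = 2 * #edges
  expect_equal(unname(curve[2, "s1"]), (n - 1) / n)  # (n-1) eigenvalues n
})

test_that("the trace curve equals twice the projection edge count", {
  W <- random_bipartite(6, 5, seed = 51)$weights
  grid <- seq(0.1, 1, by = 0.1)
  curve <- persistent_zeta_curve(W, grid, "protein")
  edges <- vapply(grid, function(f) {
    adj <- projection_adjacency(W, f, "protein")
    sum(adj) / 2
  }, numeric(1))
  expect_equal(unname(curve[, "s-1"]), 2 * edges)
  expect_true(all(diff(2 * edges) >= 0))
})

test_that("zeta curves match the explicit complex-building route", {
  for (s in 1:6) {
    W <- random_bipartite(5, 6, seed = 700 + s)$weights
    grid <- seq(0.15, 0.95, by = 0.1)
    for (side in c("protein", "ligand")) {
      fast <- persistent_zeta_curve(W, grid, side)
      slow <- t(vapply(grid, function(f) {
        K <- build_dowker_pair(W, f, max_dim = 1)[[side]]
        ev <- laplacian_spectrum(hodge_laplacian(K, 0))
        vapply(ZETA_EXPONENTS, function(ss) zeta(ev, ss), numeric(1))
      }, numeric(11)))
      expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
    }
  }
})

test_that("feature vectors have the fixed layout lengths for any input", {
  cx_small <- random_complex(synthetic_spec(n_protein = 6, n_ligand = 3),
                             seed = 2)
  cx_big <- random_complex(synthetic_spec(n_protein = 50, n_ligand = 15),
                           seed = 3)
  for (cx in list(cx_small, cx_big)) {
    expect_length(featurize_complex(cx, "distance"), 63360L)
  }
  expect_length(featurize_complex(cx_small, "electrostatic"), 55000L)
  comb <- featurize_complex(cx_small, "combined")
  expect_length(comb, 118360L)
  expect_equal(unname(comb[1:63360]),
               unname(featurize_complex(cx_small, "distance")))
  expect_equal(feature_length("distance"), 63360L)
  expect_equal(feature_length("electrostatic"), 55000L)
  expect_equal(feature_length("combined"), 118360L)
  expect_length(feature_names("combined"), 118360L)
})

test_that("electrostatic features demand charges", {
  cx <- random_complex(synthetic_spec(n_protein = 6, n_ligand = 3), seed = 4)
  cx$protein$charge[2] <- NA
  expect_error(featurize_complex(cx, "electrostatic"), "charge")
})

test_that("a single-pair group contributes only zero rows", {
  # one protein C and one ligand C at 3 Angstrom: a lone related pair has
  # one vertex per side and an empty edge set, so every zeta is zero
  prot <- atoms_at(c(0, 0, 0), element = "C")
  lig <- atoms_at(c(3, 0, 0), element = "C")
  cx <- molecular_complex(prot, lig)
  v <- featurize_complex(cx, "distance")
  expect_true(all(v == 0))
})

test_that("features are invariant under rigid motion and atom reorder", {
  cx <- random_complex(synthetic_spec(n_protein = 25, n_ligand = 10),
                       seed = 9)
  v0 <- featurize_complex(cx, "distance")
  # random rotation + translation applied to protein and ligand alike
  rot <- with_seed(10, qr.Q(qr(matrix(rnorm(9), 3))))
  shift <- c(5, -3, 2)
  move <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% rot
    at$x <- xyz[, 1] + shift[1]
    at$y <- xyz[, 2] + shift[2]
    at$z <- xyz[, 3] + shift[3]
    at
  }
  cx_m <- molecular_complex(move(cx$protein), move(cx$ligand))
  v1 <- featurize_complex(cx_m, "distance")
  expect_lt(max(abs(v1 - v0)) / max(1, max(abs(v0))), 1e-9)
  # permuting atom rows leaves the spectra, hence the features, unchanged
  perm_p <- with_seed(11, sample(nrow(cx$protein)))
  cx_p <- molecular_complex(cx$protein[perm_p, ], cx$ligand)
  expect_equal(unname(featurize_complex(cx_p, "distance")), unname(v0))
})

test_that("dataset featurization is deterministic and order-faithful", {
  cxs <- lapply(1:3, function(s) {
    cx <- random_complex(synthetic_spec(n_protein = 8, n_ligand = 4),
                         seed = s)
    cx$label <- s
    cx
  })
  ds <- featurize_dataset(cxs, "distance", require_labels = TRUE)
  expect_equal(dim(ds$x), c(3L, 63360L))
  expect_equal(ds$y, 1:3 + 0)
  ds2 <- featurize_dataset(cxs, "distance")
  expect_identical(ds$x, ds2$x)
  dsr <- featurize_dataset(rev(cxs), "distance")
  expect_equal(dsr$x, ds$x[3:1, ])
  cxs[[2]]$label <- NA_real_
  expect_error(featurize_dataset(cxs, "distance", require_labels = TRUE),
               "label")
})

test_that("Betti curves of the two chains agree along the filtration", {
  fx <- fixture("two_chains")
  grid <- seq(4, 14, by = 2)
  bc <- betti_curves(fx$W, grid)
  expect_equal(bc$beta1_protein, bc$beta1_ligand)
  expect_true(any(bc$beta1_protein > 0))   # the chains do link cycles
  # beta_0 also agrees wherever the bipartite graph is connected
  conn <- vapply(grid, function(f) bipartite_connected(fx$W, f), logical(1))
  expect_equal(bc$beta0_protein[conn], bc$beta0_ligand[conn])
})
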
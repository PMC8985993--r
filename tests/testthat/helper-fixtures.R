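# Shared fixture builders: tiny structure files written into tempdir() and
# small generators used across test files.

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       4.000   2.000   3.000  1.00  0.00           O",
    "END"), path)
  path
}

write_halogen_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "HETATM    1 CL   LIG A   1       0.000   0.000   0.000  1.00  0.00          CL",
    "HETATM    2  C1  LIG A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

write_toy_mol2 <- function(path = tempfile(fileext = ".mol2")) {
  writeLines(c(
    "@<TRIPOS>MOLECULE", "toy", "3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 C1          0.0000    0.0000    0.0000 C.ar      1 LIG        -0.3000",
    "      2 N1          1.5000    0.0000    0.0000 N.4       1 LIG         0.3000",
    "      3 CL1         3.0000    0.0000    0.0000 Cl        1 LIG        -0.1000",
    "@<TRIPOS>BOND",
    "     1    1    2 ar",
    "     2    2    3 1"), path)
  path
}

write_toy_sdf <- function(path = tempfile(fileext = ".sdf")) {
  writeLines(c(
    "toy", "  synthetic", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.3000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END", "$$$$"), path)
  path
}

write_toy_pqr <- function(path = tempfile(fileext = ".pqr"),
                          serials = 1:3,
                          charges = c(0.55, -0.20, -0.35)) {
  lines <- sprintf(
    "ATOM  %5d  C   ALA A   1       1.000   2.000   3.000 %7.4f 1.5000",
    serials, charges)
  writeLines(c(lines, "END"), path)
  path
}

# atom table helper for hand-built geometries
atoms_at <- function(coords, element = "C", charge = NA_real_) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  data.frame(serial = seq_len(nrow(coords)), element = element,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             charge = charge, stringsAsFactors = FALSE)
}

# connectivity of the thresholded bipartite graph, by BFS over the union
# vertex set (independent of all Dowker code)
bipartite_connected <- function(W, f) {
  A <- W <= f
  n1 <- nrow(A); n2 <- ncol(A)
  deg1 <- rowSums(A); deg2 <- colSums(A)
  live <- c(deg1 > 0, deg2 > 0)
  if (!any(live)) return(FALSE)
  n <- n1 + n2
  seen <- rep(FALSE, n)
  queue <- which(live)[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- if (v <= n1) n1 + which(A[v, ]) else which(A[, v - n1])
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen[live])
}

# shared random-graph corpus: 200 small weighted bipartite graphs
acceptance_corpus <- function(n_graphs = 200L) {
  lapply(seq_len(n_graphs), function(i) {
    n1 <- 3L + (i %% 4L)
    n2 <- 3L + ((i + 2L) %% 4L)
    if (i %% 5L == 0L) {
      random_bipartite(n1, n2, seed = 1000L + i, law = "bernoulli",
                       density = 0.55)
    } else {
      random_bipartite(n1, n2, seed = 1000L + i)
    }
  })
}

finite_thresholds <- function(W) {
  w <- unique(as.vector(W))
  sort(w[is.finite(w)])
}
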
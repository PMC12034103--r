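# in-code fixture builders shared across the test files

# a minimal loop with explicit nucleotide centers: one atom per nucleotide
# unless full = TRUE, in which case all six backbone atoms are placed at
# fixed offsets around each center
toy_loop <- function(centers, bases = NULL, bp = NULL, stk = NULL,
                     family = NULL, full = FALSE, loc = NULL) {
  n <- nrow(centers)
  if (is.null(bases)) bases <- rep(c("A", "C", "G", "U"), length.out = n)
  if (is.null(loc)) loc <- sprintf("TEST_A:1-%d", n)
  nts <- lapply(seq_len(n), function(t) {
    if (full) {
      offs <- rnaloopclust:::ATOM_OFFSETS
      xyz <- sweep(offs, 2, centers[t, ], `+`)
    } else {
      xyz <- matrix(centers[t, ], 1, 3, dimnames = list("C4'", NULL))
    }
    nucleotide(t, bases[t], coords = xyz)
  })
  rna_loop(loc, nts, bp, stk, family)
}

# deterministic random centers
rand_centers <- function(n, seed = 1, scale = 5) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = scale), n, 3)
}

# rigid motion: rotate by Euler angles and translate
rigid_transform <- function(X, ang = c(0.3, -1.1, 2.0), shift = c(5, -2, 7)) {
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  Ry <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- Rz(ang[3]) %*% Ry(ang[2]) %*% Rx(ang[1])
  sweep(X %*% t(R), 2, shift, `+`)
}

# independent oracle for optimal-superposition RMSD: coarse grid over Euler
# angles followed by Nelder-Mead refinement from the best starts; never
# touches the SVD route used by kabsch_rmsd()
rmsd_rotation_search <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])),
                 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
                 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(a) sqrt(sum((Qc - Pc %*% t(rot(a)))^2) / nrow(P))
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- Inf; starts <- list()
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- f(c(a1, a2, a3))
    starts[[length(starts) + 1L]] <- list(a = c(a1, a2, a3), v = v)
  }
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "v"))][1:5]
  for (s in starts) {
    o <- stats::optim(s$a, f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# small labelled graph set: two well-separated synthetic families
two_family_graphs <- function(n_per_family = 20L, seed = 1L) {
  tm <- builtin_templates()[c("SR", "KT")]
  ds <- generate_dataset(tm, n_per_family, noise_spec(), seed = seed)
  list(graphs = lapply(ds$loops, encode_loop), ds = ds)
}
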
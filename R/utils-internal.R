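# Internal helpers shared across modules.

# Euclidean norm of a 3-vector.
vnorm <- function(v) sqrt(sum(v * v))

# Unit vector; errors on zero length.
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Angle (degrees) at vertex `b` formed by points a-b-c.
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Coordinates of a pose's atoms as an n x 3 matrix.
atom_coords <- function(pose) {
  as.matrix(pose$atoms[, c("x", "y", "z")])
}

# Indices of atoms carrying a given role tag.
atoms_with_role <- function(pose, role) {
  which(vapply(pose$atoms$roles, function(r) role %in% r, logical(1)))
}

# Neighbour indices of atom i (optionally heavy only).
atom_neighbours <- function(pose, i, heavy_only = FALSE) {
  b <- pose$bonds
  nb <- c(b$j[b$i == i], b$i[b$j == i])
  if (heavy_only) nb <- nb[pose$atoms$element[nb] != "H"]
  nb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
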
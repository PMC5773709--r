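# Shared test helpers: hand-built summaries and small fixtures.

# Build a fingerprint_summary directly (for distance-model unit tests where
# the point cloud is irrelevant).
make_summary <- function(id, centroid, sigma, eigvecs = diag(3),
                         eigvals = c(3, 2, 1), n_points = 10L) {
  structure(
    list(seq_id = id,
         centroid = stats::setNames(as.numeric(centroid), c("X", "Y", "Z")),
         sigma = stats::setNames(as.numeric(sigma), c("X", "Y", "Z")),
         eigvals = eigvals,
         eigvecs = matrix(as.numeric(eigvecs), 3, 3,
                          dimnames = list(c("X", "Y", "Z"), NULL)),
         mean_radius = 1, n_points = n_points, degenerate = all(sigma == 0)),
    class = "fingerprint_summary")
}

# Rotation matrix about the z-like axis by angle a (columns are the rotated
# basis vectors).
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Cyclic rotation of a sequence string by k bases.
rotate_seq <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) s else paste0(substr(s, k + 1, n), substr(s, 1, k))
}

# Write records to a temporary FASTA and return the path.
tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  write_fasta(records, path)
  path
}

# Circularised track of a seeded random sequence.
random_circ_track <- function(n, seed, gc = 0.5) {
  circularise(compute_track(random_genome(n, gc = gc, seed = seed)))
}
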
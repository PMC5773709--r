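# The 3D cumulative nucleotide walk ("genome-fingerprints map").
#
# Each base moves the walk by a unit step on all three axes:
#   A (+1,+1,+1)   G (+1,-1,-1)   C (-1,+1,-1)   T (-1,-1,+1)
# so after n bases
#   X_n = (A_n + G_n) - (C_n + T_n)   purine vs pyrimidine bias
#   Y_n = (A_n + C_n) - (G_n + T_n)   amino vs keto bias
#   Z_n = (A_n + T_n) - (C_n + G_n)   weak vs strong hydrogen bonding
# A sustained composition bias therefore draws a straight line along an axis.
# Circularisation removes the linear trend so the walk closes at the origin,
# making the map independent of where the (circular or arbitrarily cut)
# sequence was opened.

STEP_TABLE <- matrix(
  c( 1,  1,  1,   # A
    -1,  1, -1,   # C
     1, -1, -1,   # G
    -1, -1,  1),  # T
  nrow = 4L, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("X", "Y", "Z"))
)

# Coerce the accepted sequence inputs to a single A/C/G/T string + id.
as_walk_input <- function(x) {
  if (inherits(x, "cleaned_genome")) {
    list(id = x$record$id, seq = x$record$seq)
  } else if (inherits(x, "genome_record")) {
    list(id = x$id, seq = x$seq)
  } else if (is.character(x) && length(x) == 1L) {
    list(id = "seq", seq = toupper(x))
  } else {
    stop("expected a genome_record, cleaned_genome or character string",
         call. = FALSE)
  }
}

#' Compute the raw cumulative 3D walk of a sequence
#'
#' @param x A [genome_record()], [clean_ns()] result, or A/C/G/T string.
#' @param id Optional identifier override.
#' @return An object of class `fingerprint_track`: `seq_id`, `n_points`,
#'   `coords` (an `n x 3` matrix of cumulative X/Y/Z, integer-valued for raw
#'   tracks), `circularised = FALSE`.
#' @examples
#' compute_track("ACGT")$coords  # returns to the origin: balanced composition
#' @export
compute_track <- function(x, id = NULL) {
  inp <- as_walk_input(x)
  if (!nzchar(inp$seq)) stop("empty sequence", call. = FALSE)
  bases <- strsplit(inp$seq, "", fixed = TRUE)[[1L]]
  idx <- match(bases, rownames(STEP_TABLE))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop(sprintf(
      "non-ACGT character '%s' at position %d; run clean_ns() first",
      bases[p], p), call. = FALSE)
  }
  steps <- STEP_TABLE[idx, , drop = FALSE]
  coords <- apply(steps, 2L, cumsum)
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1L,
                                             dimnames = list(NULL, c("X", "Y", "Z")))
  new_track(if (is.null(id)) inp$id else id, coords, circularised = FALSE)
}

new_track <- function(seq_id, coords, circularised) {
  structure(list(seq_id = seq_id, n_points = nrow(coords), coords = coords,
                 circularised = circularised),
            class = "fingerprint_track")
}

#' @export
print.fingerprint_track <- function(x, ...) {
  cat(sprintf("<fingerprint_track> %s: %s points (%s)\n", x$seq_id,
              format(x$n_points, big.mark = ","),
              if (x$circularised) "circularised" else "raw"))
  invisible(x)
}

#' Circularise a walk by linear detrending
#'
#' Subtracts the straight line from the origin to the walk's endpoint,
#' `K~_n = K_n - (n/N) K_N` per axis, so the track closes at the origin.
#' This removes the dependence on the arbitrary cut-off site of the sequence.
#'
#' @param track A raw [compute_track()] result.
#' @return A circularised `fingerprint_track`; the input is unchanged.
#' @export
circularise <- function(track) {
  stopifnot(inherits(track, "fingerprint_track"))
  if (track$circularised) {
    warning("track is already circularised; returning it unchanged")
    return(track)
  }
  n <- track$n_points
  endpoint <- track$coords[n, ]
  trend <- outer(seq_len(n) / n, endpoint)
  new_track(track$seq_id, track$coords - trend, circularised = TRUE)
}

#' Summarise a circularised walk into the statistics used by the distance model
#'
#' The summary is the geometric fingerprint used for map-to-map comparison:
#' the geometric centre (centroid) of the point cloud, per-axis population
#' standard deviations, the eigen-structure of the 3x3 coordinate covariance
#' (shape and orientation of the cloud), and the mean radius. All statistics
#' are over the N walk points (the origin, n = 0, is not a point of the walk
#' and is excluded).
#'
#' @param track A circularised `fingerprint_track` with at least 2 points.
#' @return An object of class `fingerprint_summary`: `centroid`, `sigma`
#'   (population SDs), `eigvals` (descending), `eigvecs` (unit columns ordered
#'   by descending eigenvalue, sign-fixed so the largest-magnitude component
#'   is positive), `mean_radius`, `n_points`, `degenerate`.
#' @export
summarise_track <- function(track) {
  stopifnot(inherits(track, "fingerprint_track"))
  if (!track$circularised) {
    stop("summaries are computed on circularised tracks; call circularise()",
         call. = FALSE)
  }
  n <- track$n_points
  if (n < 2L) stop("need at least 2 points to summarise", call. = FALSE)
  centroid <- colMeans(track$coords)
  centered <- sweep(track$coords, 2L, centroid)
  covm <- crossprod(centered) / n          # population covariance
  sigma <- sqrt(diag(covm))
  mean_radius <- mean(sqrt(rowSums(centered^2)))
  degenerate <- FALSE
  if (all(sigma == 0)) {
    eigvals <- c(0, 0, 0)
    eigvecs <- diag(3)
    degenerate <- TRUE
  } else {
    ed <- eigen(covm, symmetric = TRUE)
    eigvals <- pmax(ed$values, 0)
    eigvecs <- ed$vectors
    # Relative eigenvalue ties leave the eigenbasis arbitrary within the
    # tied subspace; flag the summary rather than pretend an orientation.
    gaps <- diff(eigvals)
    if (any(abs(gaps) < 1e-9 * max(eigvals, 1e-300))) degenerate <- TRUE
    # Sign convention: largest-magnitude component of each vector positive.
    for (k in 1:3) {
      v <- eigvecs[, k]
      if (v[which.max(abs(v))] < 0) eigvecs[, k] <- -v
    }
  }
  dimnames(eigvecs) <- list(c("X", "Y", "Z"), NULL)
  structure(
    list(seq_id = track$seq_id,
         centroid = stats::setNames(centroid, c("X", "Y", "Z")),
         sigma = stats::setNames(sigma, c("X", "Y", "Z")),
         eigvals = eigvals, eigvecs = eigvecs,
         mean_radius = mean_radius, n_points = n, degenerate = degenerate),
    class = "fingerprint_summary"
  )
}

#' @export
print.fingerprint_summary <- function(x, ...) {
  cat(sprintf("<fingerprint_summary> %s (%s points)\n", x$seq_id,
              format(x$n_points, big.mark = ",")))
  cat(sprintf("  centroid (%.3f, %.3f, %.3f), sigma (%.3f, %.3f, %.3f)\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$sigma[1], x$sigma[2], x$sigma[3]))
  cat(sprintf("  eigenvalues %.4g %.4g %.4g, mean radius %.3f%s\n",
              x$eigvals[1], x$eigvals[2], x$eigvals[3], x$mean_radius,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fingerprint a sequence end-to-end
#'
#' Convenience wrapper: clean if needed, walk, circularise, summarise.
#'
#' @param x A [genome_record()], [clean_ns()] result, or sequence string.
#' @return A `fingerprint_summary`.
#' @export
fingerprint <- function(x) {
  if (inherits(x, "genome_record") && grepl("[^ACGT]", x$seq)) x <- clean_ns(x)
  summarise_track(circularise(compute_track(x)))
}

#' Export / import a track as TSV (columns n, X, Y, Z)
#'
#' @param track A `fingerprint_track`.
#' @param path Output path.
#' @return `path` invisibly, or the re-read track for the reader.
#' @export
write_track_tsv <- function(track, path) {
  stopifnot(inherits(track, "fingerprint_track"))
  df <- data.frame(n = seq_len(track$n_points), track$coords)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @param seq_id Identifier for the re-read track.
#' @param circularised Whether the stored track was circularised.
#' @export
read_track_tsv <- function(path, seq_id = "track", circularised = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("n", "X", "Y", "Z") %in% names(df)))
  new_track(seq_id, as.matrix(df[, c("X", "Y", "Z")]), circularised)
}

#' Cache a track in compact binary form
#'
#' Serialised-R cache for large tracks where TSV is wasteful; for exchange
#' with other tools use [write_track_tsv()].
#'
#' @param track A `fingerprint_track`.
#' @param path Cache file path.
#' @return `path` invisibly; [load_track()] returns the track.
#' @export
cache_track <- function(track, path) {
  stopifnot(inherits(track, "fingerprint_track"))
  saveRDS(track, path, compress = "gzip")
  invisible(path)
}

#' @rdname cache_track
#' @export
load_track <- function(path) {
  track <- readRDS(path)
  stopifnot(inherits(track, "fingerprint_track"))
  track
}

#' Export a fingerprint summary as JSON
#'
#' @param summary A `fingerprint_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "fingerprint_summary"))
  x <- list(seq_id = summary$seq_id,
            n_points = summary$n_points,
            centroid = unname(summary$centroid),
            sigma = unname(summary$sigma),
            eigvals = summary$eigvals,
            eigvecs = apply(summary$eigvecs, 2L, identity, simplify = FALSE),
            mean_radius = summary$mean_radius,
            degenerate = summary$degenerate)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
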
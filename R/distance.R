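# The alignment-free distance model.
#
# Two summaries are compared by (1) a weighted Euclidean distance d between
# geometric centres, each axis weighted by the geometric mean of the two
# genomes' per-axis spreads,
#   d(i,j) = sqrt( sqrt(sX_i sX_j) (Xbar_i - Xbar_j)^2
#                + sqrt(sY_i sY_j) (Ybar_i - Ybar_j)^2
#                + sqrt(sZ_i sZ_j) (Zbar_i - Zbar_j)^2 )
# and (2) the summed angles between rank-matched covariance eigenvectors,
#   cos t_k = (C_k^i . C_k^j) / (|C_k^i||C_k^j|),  t_k = arccos|cos t_k|,
#   Theta = t_1 + t_2 + t_3,
# combined multiplicatively, D = d * Theta. Theta discriminates clouds that
# share a centre but differ in orientation; the product form also means two
# distinct clouds with identical orientation score D = 0 (a documented
# degeneracy of the model, not repaired here).

#' Weighted Euclidean distance between two fingerprint summaries
#'
#' Each axis term is weighted by the geometric mean of the two per-axis
#' population standard deviations; an axis with zero spread in either genome
#' drops out.
#'
#' @param si,sj `fingerprint_summary` objects.
#' @return Non-negative scalar `d`, symmetric in its arguments.
#' @export
weighted_distance <- function(si, sj) {
  stopifnot(inherits(si, "fingerprint_summary"),
            inherits(sj, "fingerprint_summary"))
  w <- sqrt(si$sigma * sj$sigma)
  sqrt(sum(w * (si$centroid - sj$centroid)^2))
}

#' Angles between rank-matched covariance eigenvectors
#'
#' Eigenvectors are matched by eigenvalue rank (first with first, and so on).
#' Because an eigenvector's sign is arbitrary, the angle is taken as
#' `arccos(|cos|)`, confining each axis angle to `[0, pi/2]` and making the
#' factor invariant to sign flips. Cosines are clipped to `[-1, 1]` against
#' rounding.
#'
#' @param si,sj `fingerprint_summary` objects.
#' @return A list with `theta` (three per-rank angles, radians) and `Theta`
#'   (their sum, in `[0, 3 pi / 2]`). Zero-variance (degenerate flat) clouds
#'   give `Theta = 0` with a warning.
#' @export
angle_factor <- function(si, sj) {
  stopifnot(inherits(si, "fingerprint_summary"),
            inherits(sj, "fingerprint_summary"))
  if (all(si$sigma == 0) || all(sj$sigma == 0)) {
    warning("zero-variance summary: angle factor defined as 0")
    return(list(theta = c(0, 0, 0), Theta = 0))
  }
  cosines <- vapply(1:3, function(k) {
    vi <- si$eigvecs[, k]; vj <- sj$eigvecs[, k]
    sum(vi * vj) / (sqrt(sum(vi^2)) * sqrt(sum(vj^2)))
  }, 0)
  theta <- acos(pmin(1, abs(cosines)))
  list(theta = theta, Theta = sum(theta))
}

#' Combined distance: weighted Euclidean times summed eigen-angle
#'
#' `D = d * Theta`. Note the documented degeneracy: two distinct clouds with
#' identical eigen-orientation have `Theta = 0` and hence `D = 0`. Use
#' `mode = "d"` in [build_distance_matrix()] for a pure centroid distance.
#'
#' @param si,sj `fingerprint_summary` objects.
#' @return Non-negative scalar `D`.
#' @export
combined_distance <- function(si, sj) {
  weighted_distance(si, sj) * angle_factor(si, sj)$Theta
}

#' Assemble a pairwise distance matrix from fingerprint summaries
#'
#' @param summaries List of `fingerprint_summary` objects with unique ids.
#' @param mode `"D"` (default, combined distance) or `"d"` (weighted
#'   Euclidean only).
#' @return An object of class `distance_matrix`: `labels`, `values` (an
#'   `M x M` symmetric matrix with zero diagonal), `mode`, `meta`.
#' @export
build_distance_matrix <- function(summaries, mode = c("D", "d")) {
  mode <- match.arg(mode)
  stopifnot(is.list(summaries), length(summaries) >= 2L)
  lapply(summaries, function(s) stopifnot(inherits(s, "fingerprint_summary")))
  labels <- vapply(summaries, `[[`, "", "seq_id")
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ", paste(unique(labels[duplicated(labels)]),
                                     collapse = ", "), call. = FALSE)
  }
  m <- length(summaries)
  values <- matrix(0, m, m, dimnames = list(labels, labels))
  fun <- if (mode == "D") combined_distance else weighted_distance
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      v <- fun(summaries[[i]], summaries[[j]])
      values[i, j] <- v
      values[j, i] <- v
    }
  }
  if (any(!is.finite(values))) stop("non-finite distances", call. = FALSE)
  new_distance_matrix(labels, values, mode,
                      meta = list(n_points = vapply(summaries, `[[`, 0, "n_points")))
}

new_distance_matrix <- function(labels, values, mode, meta = list()) {
  stopifnot(is.matrix(values), nrow(values) == length(labels),
            ncol(values) == length(labels))
  if (max(abs(values - t(values))) > 1e-12 * max(1, max(abs(values)))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(values) != 0)) stop("diagonal must be zero", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, mode = mode, meta = meta),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d taxa, mode %s\n", length(x$labels), x$mode))
  print(round(x$values, 6))
  invisible(x)
}

#' @export
as.matrix.distance_matrix <- function(x, ...) x$values

#' Write / read a PHYLIP square distance matrix
#'
#' The strict dialect pads names to 10 characters (truncating longer ones and
#' erroring on a collision); the relaxed dialect writes full names followed by
#' whitespace-separated values. Values are printed with 6 decimals. Files
#' round-trip through [read_phylip()].
#'
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @param dialect `"strict"` or `"relaxed"`.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path, dialect = c("strict", "relaxed")) {
  stopifnot(inherits(dm, "distance_matrix"))
  dialect <- match.arg(dialect)
  labels <- dm$labels
  if (dialect == "strict") {
    short <- substr(labels, 1L, 10L)
    if (anyDuplicated(short)) {
      coll <- labels[short %in% short[duplicated(short)]]
      stop("strict PHYLIP name collision after truncation to 10 characters: ",
           paste(coll, collapse = ", "), call. = FALSE)
    }
    names_out <- formatC(short, width = 10L, flag = "-")
  } else {
    if (any(grepl("\\s", labels))) {
      stop("relaxed PHYLIP labels must not contain whitespace", call. = FALSE)
    }
    names_out <- labels
  }
  lines <- c(
    format(length(labels)),
    vapply(seq_along(labels), function(i) {
      paste0(names_out[i], " ",
             paste(sprintf("%.6f", dm$values[i, ]), collapse = " "))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @param mode Mode label to attach to the re-read matrix.
#' @export
read_phylip <- function(path, mode = "D") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- as.integer(trimws(lines[1L]))
  if (is.na(m) || length(lines) != m + 1L) {
    stop("malformed PHYLIP matrix: ", path, call. = FALSE)
  }
  labels <- character(m)
  values <- matrix(0, m, m)
  for (i in seq_len(m)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) != m + 1L) {
      stop("malformed PHYLIP row ", i, " in ", path, call. = FALSE)
    }
    labels[i] <- parts[1L]
    values[i, ] <- as.numeric(parts[-1L])
  }
  # Tolerate printed-precision asymmetry, then symmetrise exactly.
  values <- (values + t(values)) / 2
  diag(values) <- 0
  new_distance_matrix(labels, values, mode)
}

#' Export a distance matrix as labelled TSV
#'
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  df <- data.frame(label = dm$labels, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
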
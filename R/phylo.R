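# Neighbour-joining on the weighted distance matrix, plus Newick I/O.
#
# The agglomeration is the classical Saitou-Nei scheme. It is implemented
# here (rather than delegated) so its contract is fixed: Q-criterion ties are
# broken by the lowest (i, j) index pair in the current cluster order
# (original input order, merged clusters appended at the end), and negative
# branch lengths are clamped to zero and flagged. Minimum-evolution trees and
# split networks are reached through PHYLIP export, not re-implemented.

# Quote a label for Newick if it contains reserved characters.
quote_newick_label <- function(x) {
  needs <- grepl("[][():;,'[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Build a neighbour-joining tree from a distance matrix
#'
#' @param dm A `distance_matrix` (or a plain symmetric labelled matrix).
#' @return An unrooted `ape::phylo` tree with branch lengths. Negative branch
#'   lengths are clamped to 0; if any were, the attribute `"clamped"` on the
#'   tree is `TRUE`. Two taxa give a single edge split evenly.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' nj_tree(m)
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    labels <- dm$labels
    d <- dm$values
  } else if (is.matrix(dm)) {
    labels <- rownames(dm)
    if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
    d <- unname(dm)
  } else {
    stop("expected a distance_matrix or matrix", call. = FALSE)
  }
  m <- length(labels)
  if (m < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix contains NaN/Inf", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }

  clamped <- FALSE
  clamp <- function(b) {
    if (b < 0) { clamped <<- TRUE; 0 } else b
  }
  # Clusters carry their Newick substring; tips use placeholders so labels
  # with arbitrary characters never confuse the parser.
  ph <- paste0("t", seq_len(m))
  sub <- ph

  if (m == 2L) {
    half <- clamp(d[1L, 2L] / 2)
    nwk <- sprintf("(%s:%.12g,%s:%.12g);", sub[1L], half, sub[2L], half)
  } else {
    while (length(sub) > 3L) {
      r <- length(sub)
      rs <- rowSums(d)
      q <- (r - 2) * d - outer(rs, rs, `+`)
      diag(q) <- Inf
      qmin <- min(q)
      hit <- which(q <= qmin, arr.ind = TRUE)
      hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
      i <- hit[1L, 1L]; j <- hit[1L, 2L]
      bi <- clamp(d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2)))
      bj <- clamp(d[i, j] - (d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))))
      merged <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], bi, sub[j], bj)
      keep <- setdiff(seq_len(r), c(i, j))
      dn <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
      d <- rbind(cbind(d[keep, keep, drop = FALSE], dn), c(dn, 0))
      sub <- c(sub[keep], merged)
    }
    b1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    b2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    b3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                   sub[1], b1, sub[2], b2, sub[3], b3)
  }
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[match(tree$tip.label, ph)]
  attr(tree, "clamped") <- clamped
  tree
}

#' Write / read a tree in Newick format
#'
#' Labels containing Newick-reserved characters (parentheses, brackets,
#' colons, semicolons, commas, quotes or whitespace) are single-quoted on
#' output and unquoted on input, so files round-trip.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path` invisibly; [read_newick()] returns the `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  labels <- quote_newick_label(tree$tip.label)
  serialise <- function(node) {
    if (node <= ntip) return(labels[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      paste0(serialise(tree$edge[r, 2L]),
             if (!is.null(tree$edge.length))
               sprintf(":%.10g", tree$edge.length[r]) else "")
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  writeLines(paste0(serialise(ntip + 1L), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  text <- paste(readLines(path), collapse = "")
  # Shield quoted labels (which may hold reserved characters) from the
  # parser behind placeholders, then restore them on the parsed tree.
  m <- gregexpr("'(?:[^']|'')*'", text, perl = TRUE)[[1L]]
  quoted <- character(0)
  if (m[1L] != -1L) {
    quoted <- regmatches(text, list(m))[[1L]]
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], sprintf("GFMAPQLBL%d", i), text, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (length(quoted)) {
    unq <- gsub("''", "'", substr(quoted, 2L, nchar(quoted) - 1L))
    hit <- match(tree$tip.label, sprintf("GFMAPQLBL%d", seq_along(quoted)))
    tree$tip.label[!is.na(hit)] <- unq[hit[!is.na(hit)]]
  }
  tree
}
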
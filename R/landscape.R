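# Landscape analysis of fingerprint maps.
#
# A galaxy of maps (GGFM) draws several genomes' walks on shared panels so
# related assemblies can be compared as pictures. A sustained composition
# bias (for example a long tandem array) appears as a long sharp straight
# line on a coordinate-versus-position panel; the detector formalises that
# visual cue as sliding-window least squares, and pred_delete() excises a
# flagged segment ("proofreading errors-deletion") with full provenance.

GGFM_PANELS <- c("X-Y", "X-Z", "Y-Z", "X-Length", "Y-Length", "Z-Length",
                 "X-Y-Z")

#' Assemble a galaxy of genome-fingerprints maps (GGFM)
#'
#' Downsamples each track deterministically (every `stride`-th point plus the
#' first and last) and organises polylines for the seven standard panels:
#' X-Y, X-Z, Y-Z, X-Length, Y-Length, Z-Length and the 3D X-Y-Z view.
#' Downsampling affects plotting only; detection always runs on full tracks.
#'
#' @param tracks A `fingerprint_track` or list of them.
#' @param stride Keep every `stride`-th point (>= 1).
#' @return An object of class `ggfm`: `polylines` (per-genome data frames with
#'   columns n, X, Y, Z), `panels`, `stride`, `colours`.
#' @export
build_ggfm <- function(tracks, stride = 1L) {
  if (inherits(tracks, "fingerprint_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L)
  lapply(tracks, function(t) stopifnot(inherits(t, "fingerprint_track")))
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  ids <- vapply(tracks, `[[`, "", "seq_id")
  polylines <- lapply(tracks, function(t) {
    idx <- unique(c(seq.int(1L, t$n_points, by = stride), t$n_points))
    data.frame(n = idx,
               X = t$coords[idx, "X"],
               Y = t$coords[idx, "Y"],
               Z = t$coords[idx, "Z"])
  })
  names(polylines) <- ids
  structure(list(polylines = polylines, panels = GGFM_PANELS,
                 stride = as.integer(stride),
                 colours = stats::setNames(grDevices::hcl.colors(
                   max(length(ids), 2L), "Dark 3")[seq_along(ids)], ids)),
            class = "ggfm")
}

#' @export
print.ggfm <- function(x, ...) {
  cat(sprintf("<ggfm> %d genome(s), stride %d, %d panels\n",
              length(x$polylines), x$stride, length(x$panels)))
  invisible(x)
}

#' Bin a circularised walk into a 2D contour grid
#'
#' Histograms the (X, Y) point cloud on a square grid; each occupied cell
#' carries the mean circularised Z of its member points (the "colour" of the
#' contour map). Unoccupied cells are `NA`, not zero.
#'
#' @param track A circularised `fingerprint_track`.
#' @param bin_count Bins per axis (default 512). A fully degenerate cloud
#'   (all points identical) collapses to a single-cell grid.
#' @return An object of class `contour_grid`: `x_edges`, `y_edges`, `cells`
#'   (mean Z, `bin_count x bin_count`), `counts`, `bin_count`.
#' @export
contour_grid <- function(track, bin_count = 512L) {
  stopifnot(inherits(track, "fingerprint_track"))
  if (bin_count < 1L) stop("bin_count must be >= 1", call. = FALSE)
  x <- track$coords[, "X"]; y <- track$coords[, "Y"]; z <- track$coords[, "Z"]
  xr <- range(x); yr <- range(y)
  if (diff(xr) == 0 && diff(yr) == 0) bin_count <- 1L
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xe <- seq(pad(xr)[1L], pad(xr)[2L], length.out = bin_count + 1L)
  ye <- seq(pad(yr)[1L], pad(yr)[2L], length.out = bin_count + 1L)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  flat <- (iy - 1L) * bin_count + ix
  counts <- matrix(0L, bin_count, bin_count)
  tab <- tabulate(flat, nbins = bin_count^2)
  counts[] <- tab
  sums <- matrix(0, bin_count, bin_count)
  agg <- rowsum(z, group = flat)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  cells <- sums / counts
  cells[counts == 0L] <- NA_real_
  structure(list(seq_id = track$seq_id, x_edges = xe, y_edges = ye,
                 cells = cells, counts = counts, bin_count = bin_count),
            class = "contour_grid")
}

# Windowed least-squares of coordinate against position via cumulative sums.
window_fits <- function(k, starts, w) {
  starts <- as.numeric(starts)
  w <- as.numeric(w)
  n <- length(k)
  ck <- c(0, cumsum(k))
  ck2 <- c(0, cumsum(k^2))
  cnk <- c(0, cumsum(seq_len(n) * k))
  ends <- starts + w - 1L
  sy <- ck[ends + 1L] - ck[starts]
  syy <- ck2[ends + 1L] - ck2[starts]
  sxy <- cnk[ends + 1L] - cnk[starts]
  sx <- (starts + ends) * w / 2
  # sum of squares of w consecutive integers starting at `starts`
  sq <- function(m) m * (m + 1) * (2 * m + 1) / 6
  sxx <- sq(ends) - sq(starts - 1)
  sxy_c <- w * sxy - sx * sy
  sxx_c <- w * sxx - sx^2
  syy_c <- w * syy - sy^2
  slope <- sxy_c / sxx_c
  r2 <- ifelse(syy_c > 0, sxy_c^2 / (sxx_c * syy_c), 0)
  data.frame(start = starts, end = ends, slope = slope, r2 = r2)
}

#' Detect composition-biased straight-line segments on a walk
#'
#' Slides a window along each axis of the track and fits coordinate against
#' position by least squares. Windows whose absolute slope and R-squared pass
#' the thresholds, share a slope sign, and overlap (or touch) are merged;
#' merged runs shorter than `min_len` are dropped. The slope and R-squared
#' reported for a segment are refitted over the merged extent. Detection runs
#' on the full-resolution track the GGFM displays (normally circularised;
#' pass a raw track to inspect raw-walk trends).
#'
#' @param track A `fingerprint_track` with more points than `window`.
#' @param cleaned Optional [clean_ns()] result used to report segment
#'   boundaries in original assembly coordinates.
#' @param window Window length in bases (default 10000).
#' @param min_len Minimum merged segment length in bases (default 50000).
#' @param min_abs_slope Minimum |slope| in coordinate units per base
#'   (default 0.2).
#' @param min_r2 Minimum per-window R-squared (default 0.98).
#' @param step Window start spacing in bases (default `window %/% 5`).
#' @return A data frame with one row per segment: `axis`, `start_cleaned`,
#'   `end_cleaned`, `start_original`, `end_original`, `slope`, `r2`, `length`;
#'   sorted by axis then start. Zero rows when nothing passes.
#' @export
detect_bias_segments <- function(track, cleaned = NULL, window = 10000L,
                                 min_len = 50000L, min_abs_slope = 0.2,
                                 min_r2 = 0.98, step = NULL) {
  stopifnot(inherits(track, "fingerprint_track"))
  n <- track$n_points
  if (window > n) stop("window exceeds track length", call. = FALSE)
  if (is.null(step)) step <- max(1L, window %/% 5L)
  starts <- seq.int(1L, n - window + 1L, by = step)
  out <- list()
  for (axis in c("X", "Y", "Z")) {
    fits <- window_fits(track$coords[, axis], starts, window)
    pass <- fits[abs(fits$slope) >= min_abs_slope & fits$r2 >= min_r2, ,
                 drop = FALSE]
    if (nrow(pass) == 0L) next
    pass$sign <- sign(pass$slope)
    # Merge overlapping/adjacent passing windows of the same slope sign.
    runs <- list()
    cur <- pass[1L, ]
    for (i in seq_len(nrow(pass))[-1L]) {
      w <- pass[i, ]
      if (w$sign == cur$sign && w$start <= cur$end + 1L) {
        cur$end <- max(cur$end, w$end)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- w
      }
    }
    runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      len <- r$end - r$start + 1L
      if (len < min_len) next
      refit <- window_fits(track$coords[, axis], r$start, len)
      out[[length(out) + 1L]] <- data.frame(
        axis = axis, start_cleaned = r$start, end_cleaned = r$end,
        slope = refit$slope, r2 = refit$r2, length = len)
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(axis = character(0), start_cleaned = numeric(0),
                      end_cleaned = numeric(0), start_original = numeric(0),
                      end_original = numeric(0), slope = numeric(0),
                      r2 = numeric(0), length = numeric(0))
    return(res)
  }
  res <- do.call(rbind, out)
  if (!is.null(cleaned)) {
    res$start_original <- map_to_original(cleaned, res$start_cleaned)
    res$end_original <- map_to_original(cleaned, res$end_cleaned)
  } else {
    res$start_original <- res$start_cleaned
    res$end_original <- res$end_cleaned
  }
  res <- res[, c("axis", "start_cleaned", "end_cleaned", "start_original",
                 "end_original", "slope", "r2", "length")]
  res <- res[order(res$axis, res$start_cleaned), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Proofreading errors-deletion (PRED) of a flagged segment
#'
#' Excises an interval (in cleaned coordinates, since detection and the maps
#' address the effective genome) from a cleaned genome. The gap ledger is
#' extended with the excised span in original coordinates (kind `"pred"`,
#' absorbing any N-gaps it contains) and the deleted subsequence is kept on
#' the result for provenance.
#'
#' @param cleaned A [clean_ns()] result.
#' @param iv A [genome_interval()] in cleaned coordinates.
#' @return A new `cleaned_genome`; `$deletions` gains an entry with the
#'   cleaned interval, the original-coordinate span and the deleted sequence.
#' @export
pred_delete <- function(cleaned, iv) {
  stopifnot(inherits(cleaned, "cleaned_genome"),
            inherits(iv, "genome_interval"))
  clen <- cleaned$ledger$cleaned_length
  if (iv$end > clen) stop("interval out of cleaned-coordinate range",
                          call. = FALSE)
  if (iv$start == 1 && iv$end == clen) {
    stop("deletion would empty the sequence", call. = FALSE)
  }
  seq <- cleaned$record$seq
  deleted <- substr(seq, iv$start, iv$end)
  new_seq <- paste0(substr(seq, 1L, iv$start - 1L),
                    substr(seq, iv$end + 1L, clen))
  orig_start <- map_to_original(cleaned, iv$start)
  orig_end <- map_to_original(cleaned, iv$end)
  gaps <- cleaned$ledger$gaps
  inside <- gaps$start >= orig_start & gaps$end <= orig_end
  gaps <- rbind(gaps[!inside, , drop = FALSE],
                data.frame(start = orig_start, end = orig_end,
                           length = orig_end - orig_start + 1, kind = "pred"))
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  # Merge runs that became adjacent (an N-gap touching the excised span).
  merged <- gaps[0, ]
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    last <- nrow(merged)
    if (last > 0L && g$start <= merged$end[last] + 1) {
      merged$end[last] <- max(merged$end[last], g$end)
      merged$length[last] <- merged$end[last] - merged$start[last] + 1
      if (g$kind == "pred") merged$kind[last] <- "pred"
    } else {
      merged <- rbind(merged, g)
    }
  }
  ledger <- gap_ledger(merged, cleaned$ledger$original_length, nchar(new_seq))
  deletions <- c(cleaned$deletions, list(list(
    interval_cleaned = iv,
    interval_original = genome_interval(cleaned$source_id, orig_start, orig_end),
    seq = deleted)))
  new_cleaned_genome(
    genome_record(cleaned$record$id, new_seq, cleaned$record$description),
    ledger, cleaned$source_id, deletions)
}

#' Export detected segments
#'
#' TSV keeps 1-based inclusive coordinates; BED converts to 0-based half-open
#' (original coordinates).
#'
#' @param segments A [detect_bias_segments()] result.
#' @param path Output path.
#' @param seq_id Chromosome name for the BED export.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
write_segments_bed <- function(segments, path, seq_id = "seq") {
  bed <- data.frame(chrom = rep(seq_id, nrow(segments)),
                    start = format(segments$start_original - 1,
                                   scientific = FALSE, trim = TRUE),
                    end = format(segments$end_original,
                                 scientific = FALSE, trim = TRUE),
                    name = paste0("bias_", segments$axis),
                    score = round(segments$r2 * 1000))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Oblique projection used for the 3D panel.
project_3d <- function(x, y, z) list(u = x + 0.4 * z, v = y + 0.4 * z)

#' Render map panels to image files
#'
#' For a [build_ggfm()] dataset, writes one image per panel (seven in total);
#' for a [contour_grid()], writes a single heat map. Vector (SVG) output is
#' deterministic for a given dataset.
#'
#' @param x A `ggfm` or `contour_grid`.
#' @param dir Output directory (created if missing).
#' @param format `"svg"` or `"png"`.
#' @return Character vector of written file paths, invisibly.
#' @export
render_maps <- function(x, dir, format = c("svg", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  open_dev <- function(path) {
    if (format == "svg") grDevices::svg(path, width = 6, height = 6)
    else grDevices::png(path, width = 900, height = 900, res = 150)
  }
  if (inherits(x, "ggfm")) {
    if (length(x$polylines) == 0L) stop("empty GGFM dataset", call. = FALSE)
    paths <- character(0)
    for (panel in x$panels) {
      path <- file.path(dir, paste0("panel_", panel, ".", format))
      open_dev(path)
      draw_panel(x, panel)
      grDevices::dev.off()
      paths <- c(paths, path)
    }
  } else if (inherits(x, "contour_grid")) {
    path <- file.path(dir, paste0("contour_", x$seq_id, ".", format))
    open_dev(path)
    graphics::image(x = x$x_edges, y = x$y_edges, z = x$cells,
                    col = grDevices::hcl.colors(64, "Viridis"),
                    xlab = "X", ylab = "Y",
                    main = paste("Contour (X-Y, mean Z):", x$seq_id))
    grDevices::dev.off()
    paths <- path
  } else {
    stop("expected a ggfm or contour_grid", call. = FALSE)
  }
  invisible(paths)
}

draw_panel <- function(g, panel) {
  cols <- g$colours
  get_xy <- function(df) {
    switch(panel,
      "X-Y" = list(x = df$X, y = df$Y, xl = "X", yl = "Y"),
      "X-Z" = list(x = df$X, y = df$Z, xl = "X", yl = "Z"),
      "Y-Z" = list(x = df$Y, y = df$Z, xl = "Y", yl = "Z"),
      "X-Length" = list(x = df$n, y = df$X, xl = "position (bp)", yl = "X"),
      "Y-Length" = list(x = df$n, y = df$Y, xl = "position (bp)", yl = "Y"),
      "Z-Length" = list(x = df$n, y = df$Z, xl = "position (bp)", yl = "Z"),
      "X-Y-Z" = {
        p <- project_3d(df$X, df$Y, df$Z)
        list(x = p$u, y = p$v, xl = "X + 0.4 Z", yl = "Y + 0.4 Z")
      },
      stop("unknown panel: ", panel, call. = FALSE))
  }
  all_xy <- lapply(g$polylines, get_xy)
  xlim <- range(unlist(lapply(all_xy, `[[`, "x")))
  ylim <- range(unlist(lapply(all_xy, `[[`, "y")))
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = all_xy[[1L]]$xl, ylab = all_xy[[1L]]$yl, main = panel)
  for (i in seq_along(all_xy)) {
    graphics::lines(all_xy[[i]]$x, all_xy[[i]]$y, col = cols[[i]])
  }
  graphics::legend("topright", legend = names(g$polylines),
                   col = cols, lty = 1, cex = 0.7, bty = "n")
}
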
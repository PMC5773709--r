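# Tandem-repeat bookkeeping: core-unit nomenclature, exact-motif scanning,
# tandem-run finding, interval arithmetic and repeat-fraction summaries.
#
# A core-unit (CU) is the monomer of a tandem array, named by its length
# (e.g. 173U = a 173-bp unit). A core-unit repeat (CUR) is the array itself,
# named unit-by-copies (e.g. 173U1020C = 1,020 copies of 173U, 176,460 bp) --
# the same object called a higher-order repeat (HOR) in the centromere
# literature.

#' Parse / format core-unit-repeat (CUR) names
#'
#' @param name A CUR name of the form `<unit>U<copies>C`, e.g. `"173U1020C"`.
#' @return `parse_cur()`: an object of class `core_unit_repeat` with fields
#'   `unit_len`, `copies`, `total_len` (`unit_len * copies`), `total_kbp`
#'   (two decimals, rounded half away from zero), and optional `motif` /
#'   `location`. `format_cur()`: the name string.
#' @examples
#' parse_cur("173U1020C")$total_len  # 176460
#' @export
parse_cur <- function(name) {
  if (!is_string(name) || !grepl("^[0-9]+U[0-9]+C$", name)) {
    stop("malformed CUR name (expected <digits>U<digits>C): ", name,
         call. = FALSE)
  }
  parts <- as.numeric(strsplit(name, "[UC]")[[1L]])
  new_cur(parts[1L], parts[2L])
}

new_cur <- function(unit_len, copies, motif = NULL, location = NULL) {
  if (unit_len < 1 || copies < 1) stop("need unit_len >= 1 and copies >= 1",
                                       call. = FALSE)
  if (!is.null(motif) && nchar(motif) != unit_len) {
    stop("motif length must equal unit_len", call. = FALSE)
  }
  total <- unit_len * copies
  structure(list(unit_len = unit_len, copies = copies, motif = motif,
                 location = location, total_len = total,
                 total_kbp = format_bp(total, "Kbp")),
            class = "core_unit_repeat")
}

#' @rdname parse_cur
#' @param cur A `core_unit_repeat`.
#' @export
format_cur <- function(cur) {
  stopifnot(inherits(cur, "core_unit_repeat"))
  sprintf("%dU%dC", cur$unit_len, cur$copies)
}

#' @export
print.core_unit_repeat <- function(x, ...) {
  cat(sprintf("<core_unit_repeat> %s: %s bp (%.2f Kbp)%s\n", format_cur(x),
              format(x$total_len, big.mark = ","), x$total_kbp,
              if (!is.null(x$motif)) paste0(", motif ", x$motif) else ""))
  invisible(x)
}

#' Length of a 1-based inclusive interval
#'
#' @param iv A [genome_interval()].
#' @return `end - start + 1`.
#' @examples
#' interval_length(genome_interval("chrY", 10744193, 11592902))  # 848710
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genome_interval"))
  iv$end - iv$start + 1
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Scan a sequence for exact copies of a motif
#'
#' Matches are exact, case-insensitive, left-to-right greedy and
#' non-overlapping, on the forward strand by default.
#'
#' @param x A [genome_record()], [clean_ns()] result, or sequence string.
#' @param motif An A/C/G/T motif.
#' @param both_strands Also count matches of the reverse complement
#'   (default `FALSE`).
#' @return A list with `count` and `positions` (1-based start positions; for
#'   `both_strands` a second element `positions_rc`).
#' @examples
#' scan_motif("TTAGGGTTAGGG", "TTAGGG")$count  # 2
#' @export
scan_motif <- function(x, motif, both_strands = FALSE) {
  inp <- as_walk_input(x)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("motif must be a non-empty A/C/G/T string", call. = FALSE)
  }
  hit <- function(m) {
    g <- gregexpr(m, inp$seq, fixed = TRUE)[[1L]]
    if (g[1L] == -1L) integer(0) else as.integer(g)
  }
  fwd <- hit(motif)
  out <- list(count = length(fwd), positions = fwd)
  if (both_strands) {
    rc <- reverse_complement(motif)
    pos_rc <- if (rc == motif) integer(0) else hit(rc)
    out$positions_rc <- pos_rc
    out$count <- out$count + length(pos_rc)
  }
  out
}

#' Find maximal tandem runs of a motif
#'
#' A run is a maximal block of consecutive, abutting motif copies. Intervals
#' are 1-based inclusive in the coordinates of `x`.
#'
#' @inheritParams scan_motif
#' @param min_copies Minimum copies for a run to be reported (default 2).
#' @return A data frame with columns `start`, `end`, `copies`, `length`;
#'   run intervals are disjoint and `length = copies * nchar(motif)`.
#' @examples
#' find_tandem_runs("TTAGGGTTAGGG", "TTAGGG")  # one run of 2 copies
#' @export
find_tandem_runs <- function(x, motif, min_copies = 2L) {
  res <- scan_motif(x, motif)
  u <- nchar(toupper(motif))
  pos <- res$positions
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      copies = integer(0), length = numeric(0))
  if (length(pos) == 0L) return(empty)
  # Consecutive matches u apart form a run.
  brk <- c(0L, which(diff(pos) != u), length(pos))
  runs <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    copies <- length(idx)
    data.frame(start = pos[idx[1L]], end = pos[idx[copies]] + u - 1,
               copies = copies, length = copies * u)
  }))
  runs <- runs[runs$copies >= min_copies, , drop = FALSE]
  rownames(runs) <- NULL
  if (nrow(runs) == 0L) empty else runs
}

#' Repeat content of a segment as a percentage
#'
#' Sums component lengths as given (no overlap resolution, matching how
#' repeat tables are totalled) and reports `100 * sum / segment_len` rounded
#' half away from zero to two decimals. For an overlap-aware figure see
#' [union_length()].
#'
#' @param component_lengths Numeric vector of component lengths in bp
#'   (possibly empty).
#' @param segment_len Segment length in bp (> 0).
#' @return Percentage, two decimals.
#' @examples
#' repeat_fraction(c(350570, 584950, 58170), 1300051)  # 76.43
#' @export
repeat_fraction <- function(component_lengths, segment_len) {
  if (segment_len <= 0) stop("segment_len must be > 0", call. = FALSE)
  if (length(component_lengths) == 0L) return(0)
  if (any(component_lengths < 0)) stop("negative component length",
                                       call. = FALSE)
  round_half_away(100 * sum(component_lengths) / segment_len, 2L)
}

#' Union length of a set of intervals
#'
#' Overlap-aware total coverage, for honest coverage numbers when CUR
#' intervals nest (one array can lie inside another).
#'
#' @param intervals List of [genome_interval()] objects (or a 2-column
#'   matrix / data frame of starts and ends).
#' @return Total number of bases covered by the union.
#' @export
union_length <- function(intervals) {
  if (is.list(intervals) && length(intervals) &&
      inherits(intervals[[1L]], "genome_interval")) {
    se <- cbind(vapply(intervals, `[[`, 0, "start"),
                vapply(intervals, `[[`, 0, "end"))
  } else {
    se <- as.matrix(as.data.frame(intervals))
  }
  if (nrow(se) == 0L) return(0)
  se <- se[order(se[, 1L]), , drop = FALSE]
  total <- 0
  cur_s <- se[1L, 1L]; cur_e <- se[1L, 2L]
  for (i in seq_len(nrow(se))[-1L]) {
    if (se[i, 1L] <= cur_e + 1) {
      cur_e <- max(cur_e, se[i, 2L])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- se[i, 1L]; cur_e <- se[i, 2L]
    }
  }
  total + (cur_e - cur_s + 1)
}

#' Export tandem runs / CUR tables
#'
#' @param runs A [find_tandem_runs()] result.
#' @param path Output path.
#' @param seq_id Chromosome name for BED output.
#' @param motif Motif (for naming).
#' @return `path`, invisibly.
#' @export
write_runs_bed <- function(runs, path, seq_id = "seq", motif = "motif") {
  bed <- data.frame(chrom = rep(seq_id, nrow(runs)),
                    start = format(runs$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(runs$end, scientific = FALSE, trim = TRUE),
                    name = sprintf("%dU%dC", nchar(motif), runs$copies))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_runs_bed
#' @param curs List of `core_unit_repeat` objects.
#' @export
write_cur_tsv <- function(curs, path) {
  df <- do.call(rbind, lapply(curs, function(x) {
    loc <- x$location
    data.frame(name = format_cur(x), unit_len = x$unit_len, copies = x$copies,
               bp = x$total_len, kbp = x$total_kbp,
               start = if (is.null(loc)) NA else loc$start,
               end = if (is.null(loc)) NA else loc$end)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
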
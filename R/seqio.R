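# Sequence input/output, N-run cleaning and coordinate bookkeeping.
#
# The cumulative-walk machinery only consumes A/C/G/T, so assembly gaps
# (runs of N) and ambiguity codes are excised before fingerprinting; a gap
# ledger preserves the mapping between cleaned and original coordinates so
# detected segments can be reported against the assembly.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Create a genome record
#'
#' A genome record is the package's basic sequence container: an identifier,
#' a free-text description and an upper-case nucleotide string over the IUPAC
#' alphabet (plus U).
#'
#' @param id Non-empty identifier.
#' @param seq Nucleotide string; lower case is accepted and upper-cased
#'   (soft-masking is not treated as a gap).
#' @param description Optional free text.
#' @return An object of class `genome_record` with fields `id`, `description`,
#'   `seq` and `length`.
#' @examples
#' genome_record("toy", "acgtN")
#' @export
genome_record <- function(id, seq, description = "") {
  if (!is_string(id)) stop("record id must be a non-empty string", call. = FALSE)
  if (!is.character(seq) || length(seq) != 1L) {
    stop("seq must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  bad <- check_alphabet(seq)
  if (!is.na(bad$char)) {
    stop(sprintf("non-IUPAC character '%s' at position %d of record '%s'",
                 bad$char, bad$pos, id), call. = FALSE)
  }
  structure(
    list(id = id, description = as.character(description), seq = seq,
         length = nchar(seq)),
    class = "genome_record"
  )
}

# First character outside the IUPAC alphabet, or NA.
check_alphabet <- function(seq) {
  m <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seq)
  if (m == -1L) list(char = NA_character_, pos = NA_integer_)
  else list(char = substr(seq, m, m), pos = as.integer(m))
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s bp)\n", x$id,
              format(x$length, big.mark = ",")))
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  head <- substr(x$seq, 1L, 60L)
  cat("  ", head, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects, one per entry, in file order.
#'   Sequences are upper-cased; `U` is preserved as read.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    h <- headers[[i]]
    id <- sub("\\s.*$", "", h)
    if (!nzchar(id)) {
      stop(sprintf("malformed header for entry %d of '%s' (empty id)", i, path),
           call. = FALSE)
    }
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    seq <- toupper(as.character(set[[i]]))
    bad <- check_alphabet(seq)
    if (!is.na(bad$char)) {
      stop(sprintf(
        "non-IUPAC character '%s' at sequence position %d of entry '%s' in '%s'",
        bad$char, bad$pos, id, path), call. = FALSE)
    }
    genome_record(id, seq, desc)
  })
}

#' Write genome records to a FASTA file
#'
#' @param records A `genome_record` or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width)
  invisible(path)
}

#' Create a genome interval (1-based, inclusive)
#'
#' All coordinates handled by the package are 1-based and inclusive; BED
#' exports convert to 0-based half-open at the boundary.
#'
#' @param seq_id Sequence identifier the interval refers to.
#' @param start,end Start and end positions, `1 <= start <= end`.
#' @return An object of class `genome_interval`.
#' @examples
#' genome_interval("chrY", 9999936, 11299986)
#' @export
genome_interval <- function(seq_id, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    stop("invalid interval: need 1 <= start <= end", call. = FALSE)
  }
  structure(list(seq_id = as.character(seq_id), start = start, end = end),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("<genome_interval> %s:%s-%s (%s bp)\n", x$seq_id,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start + 1, big.mark = ",")))
  invisible(x)
}

# Construct a gap ledger from a data.frame of removed original-coordinate
# intervals (columns start, end, length, kind).
gap_ledger <- function(gaps, original_length, cleaned_length) {
  stopifnot(is.data.frame(gaps),
            all(c("start", "end", "length", "kind") %in% names(gaps)))
  if (nrow(gaps) > 1L) {
    o <- order(gaps$start)
    gaps <- gaps[o, , drop = FALSE]
    if (any(gaps$start[-1L] <= gaps$end[-nrow(gaps)])) {
      stop("gap intervals overlap", call. = FALSE)
    }
  }
  rownames(gaps) <- NULL
  if (cleaned_length != original_length - sum(gaps$length)) {
    stop("ledger inconsistent: cleaned_length != original_length - gaps",
         call. = FALSE)
  }
  structure(list(gaps = gaps, original_length = original_length,
                 cleaned_length = cleaned_length),
            class = "gap_ledger")
}

#' Remove N homopolymers (and all other non-ACGT runs) from a record
#'
#' Produces the "effective genome": the walk is computed on A/C/G/T only,
#' bypassing assembly gaps by linking the two bases flanking each run of Ns.
#' `U` is converted to `T` before cleaning; every other non-ACGT character
#' (including IUPAC ambiguity codes) is treated as N. Every removed run is
#' logged in the gap ledger with its original 1-based inclusive coordinates;
#' runs of at least `min_run` characters are classified as `"gap"`, shorter
#' ones as `"ambiguity"`.
#'
#' @param record A [genome_record()].
#' @param min_run Minimum run length for a removed run to be classified as an
#'   assembly gap in the ledger (default 1: every run is a gap).
#' @return An object of class `cleaned_genome`: fields `record` (A/C/G/T-only
#'   [genome_record()]), `ledger` (gap ledger), `source_id`, `deletions`.
#' @examples
#' cg <- clean_ns(genome_record("x", "ACNNNGT"))
#' cg$record$seq           # "ACGT"
#' cg$ledger$gaps          # one run at (3,5)
#' @export
clean_ns <- function(record, min_run = 1L) {
  stopifnot(inherits(record, "genome_record"))
  if (record$length == 0L) stop("empty record", call. = FALSE)
  if (min_run < 1L) stop("min_run must be >= 1", call. = FALSE)
  seq <- chartr("U", "T", record$seq)
  m <- gregexpr("[^ACGT]+", seq)[[1L]]
  if (m[1L] == -1L) {
    gaps <- data.frame(start = numeric(0), end = numeric(0),
                       length = numeric(0), kind = character(0))
    cleaned_seq <- seq
  } else {
    start <- as.numeric(m)
    len <- as.numeric(attr(m, "match.length"))
    gaps <- data.frame(start = start, end = start + len - 1, length = len,
                       kind = ifelse(len >= min_run, "gap", "ambiguity"))
    cleaned_seq <- gsub("[^ACGT]+", "", seq)
  }
  if (!nzchar(cleaned_seq)) {
    stop("cleaning removed the whole sequence of '", record$id, "'",
         call. = FALSE)
  }
  ledger <- gap_ledger(gaps, record$length, nchar(cleaned_seq))
  new_cleaned_genome(
    genome_record(record$id, cleaned_seq, record$description),
    ledger, record$id
  )
}

new_cleaned_genome <- function(record, ledger, source_id, deletions = list()) {
  if (grepl("[^ACGT]", record$seq)) {
    stop("cleaned genome must contain only A/C/G/T", call. = FALSE)
  }
  structure(list(record = record, ledger = ledger, source_id = source_id,
                 deletions = deletions),
            class = "cleaned_genome")
}

#' @export
print.cleaned_genome <- function(x, ...) {
  cat(sprintf("<cleaned_genome> %s: %s bp effective of %s bp original (%d runs removed)\n",
              x$source_id,
              format(x$ledger$cleaned_length, big.mark = ","),
              format(x$ledger$original_length, big.mark = ","),
              nrow(x$ledger$gaps)))
  if (length(x$deletions)) {
    cat(sprintf("  %d proofreading deletion(s) applied\n", length(x$deletions)))
  }
  invisible(x)
}

#' Map cleaned coordinates back to original assembly coordinates
#'
#' @param cleaned A [clean_ns()] result.
#' @param pos Vector of 1-based positions in cleaned coordinates.
#' @return Original 1-based positions (strictly increasing in `pos`).
#' @export
map_to_original <- function(cleaned, pos) {
  stopifnot(inherits(cleaned, "cleaned_genome"))
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos < 1) || any(pos > cleaned$ledger$cleaned_length)) {
    stop("position out of cleaned-coordinate range", call. = FALSE)
  }
  gaps <- cleaned$ledger$gaps
  if (nrow(gaps) == 0L) return(pos)
  # Cleaned coordinate of the base immediately after gap i:
  # gap start minus total gap length before it.
  before <- c(0, cumsum(gaps$length))[seq_len(nrow(gaps))]
  gap_start_cleaned <- gaps$start - before
  idx <- findInterval(pos, gap_start_cleaned)
  pos + c(0, cumsum(gaps$length))[idx + 1L]
}

#' Map original assembly coordinates to cleaned coordinates
#'
#' Inverse of [map_to_original()], defined on non-gap original positions.
#'
#' @param cleaned A [clean_ns()] result.
#' @param pos Vector of 1-based original positions, none inside a removed run.
#' @return Cleaned 1-based positions.
#' @export
map_to_cleaned <- function(cleaned, pos) {
  stopifnot(inherits(cleaned, "cleaned_genome"))
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos < 1) || any(pos > cleaned$ledger$original_length)) {
    stop("position out of original-coordinate range", call. = FALSE)
  }
  gaps <- cleaned$ledger$gaps
  if (nrow(gaps) == 0L) return(pos)
  in_gap <- vapply(pos, function(p) any(p >= gaps$start & p <= gaps$end), NA)
  if (any(in_gap)) {
    stop("position(s) fall inside a removed run: ",
         paste(pos[in_gap], collapse = ", "), call. = FALSE)
  }
  removed_before <- vapply(pos, function(p) sum(gaps$length[gaps$end < p]), 0)
  pos - removed_before
}

#' Extract a subsequence by interval
#'
#' @param x A [genome_record()] or [clean_ns()] result. For a cleaned genome
#'   the interval addresses cleaned coordinates.
#' @param iv A [genome_interval()].
#' @return A [genome_record()] of length `end - start + 1`.
#' @export
extract_interval <- function(x, iv) {
  stopifnot(inherits(iv, "genome_interval"))
  rec <- if (inherits(x, "cleaned_genome")) x$record else x
  stopifnot(inherits(rec, "genome_record"))
  if (iv$end > rec$length) {
    stop(sprintf("interval (%s,%s) out of bounds for '%s' (%s bp)",
                 iv$start, iv$end, rec$id, rec$length), call. = FALSE)
  }
  genome_record(
    sprintf("%s:%d-%d", rec$id, iv$start, iv$end),
    substr(rec$seq, iv$start, iv$end),
    sprintf("subsequence of %s", rec$id)
  )
}

#' Export the gap ledger
#'
#' `write_gap_bed()` writes standard 0-based half-open BED;
#' `write_gap_tsv()` writes 1-based inclusive columns start, end, length, kind.
#'
#' @param cleaned A [clean_ns()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gap_bed <- function(cleaned, path) {
  stopifnot(inherits(cleaned, "cleaned_genome"))
  g <- cleaned$ledger$gaps
  bed <- data.frame(chrom = cleaned$source_id,
                    start = format(g$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(g$end, scientific = FALSE, trim = TRUE),
                    name = g$kind)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gap_bed
#' @export
write_gap_tsv <- function(cleaned, path) {
  stopifnot(inherits(cleaned, "cleaned_genome"))
  g <- cleaned$ledger$gaps[, c("start", "end", "length", "kind")]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
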
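# Seeded synthetic genomes with the structure the method assumes:
# composition-biased tandem blocks, N-gap runs, point divergence, and
# antecedent/descendent assembly pairs. Every generator is a pure function
# of its parameters plus a seed (global RNG state is never touched).

#' Generate a random genome at a given GC content
#'
#' Bases are drawn i.i.d.: G and C each with probability `gc/2`, A and T each
#' with `(1-gc)/2`.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed; identical inputs give identical sequences.
#' @param id Record identifier.
#' @return A [genome_record()].
#' @examples
#' random_genome(100, gc = 0.5, seed = 7)
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, id = "synthetic") {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]", call. = FALSE)
  seq <- with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""))
  genome_record(id, seq, sprintf("synthetic i.i.d. genome, gc=%g, seed=%d",
                                 gc, as.integer(seed)))
}

#' Insert a tandem block or an N run into a record
#'
#' `insert_tandem()` inserts `copies` abutting copies of `motif` so the
#' record grows by `copies * nchar(motif)`; `insert_n_run()` inserts a run of
#' Ns (an assembly-gap placeholder). Position `at` is the 1-based position
#' the inserted block will occupy (the former occupant shifts right).
#'
#' @param record A [genome_record()].
#' @param motif A/C/G/T motif.
#' @param copies Number of copies.
#' @param at Insertion position, `1 <= at <= length + 1`.
#' @return A new [genome_record()].
#' @export
insert_tandem <- function(record, motif, copies, at) {
  stopifnot(inherits(record, "genome_record"))
  insert_block(record, strrep(toupper(motif), copies), at)
}

#' @rdname insert_tandem
#' @param run_length Number of Ns to insert.
#' @export
insert_n_run <- function(record, run_length, at) {
  stopifnot(inherits(record, "genome_record"))
  insert_block(record, strrep("N", run_length), at)
}

insert_block <- function(record, block, at) {
  if (at < 1 || at > record$length + 1) {
    stop("insertion position out of bounds", call. = FALSE)
  }
  genome_record(record$id,
                paste0(substr(record$seq, 1L, at - 1L), block,
                       substr(record$seq, at, record$length)),
                record$description)
}

#' Build an antecedent / descendent assembly pair
#'
#' Models two releases of the same assembly where the later one gained a
#' composition-biased tandem block (the situation the straight-line detector
#' and PRED-deletion address): the descendent is the antecedent with
#' `copies` copies of `motif` inserted at `at`.
#'
#' @param length Antecedent length in bases.
#' @param gc GC fraction of the antecedent.
#' @param seed Integer seed.
#' @param motif Tandem motif inserted into the descendent (default GAATG, a
#'   pericentromeric satellite unit).
#' @param copies Number of copies (default 10000, a 50-kb block).
#' @param at Insertion position (default 100001).
#' @return A list with `antecedent` and `descendent` ([genome_record()]s) and
#'   `truth`, the inserted block's interval in descendent (cleaned)
#'   coordinates.
#' @export
make_assembly_pair <- function(length = 200000L, gc = 0.5, seed = 1L,
                               motif = "GAATG", copies = 10000L,
                               at = 100001L) {
  ant <- random_genome(length, gc = gc, seed = seed, id = "antecedent")
  block_len <- nchar(motif) * copies
  desc <- insert_tandem(ant, motif, copies, at)
  desc$id <- "descendent"
  list(antecedent = ant, descendent = desc,
       truth = genome_interval("descendent", at, at + block_len - 1))
}

#' Point-mutate a genome at a fixed substitution rate
#'
#' Each base is independently substituted with probability `rate`, drawing
#' uniformly from the three alternative bases. Non-ACGT characters (Ns) are
#' left untouched.
#'
#' @param record A [genome_record()].
#' @param rate Substitution probability per base in `[0, 1]`.
#' @param seed Integer seed.
#' @return A new [genome_record()] of the same length.
#' @export
mutate_genome <- function(record, rate, seed = 1L) {
  stopifnot(inherits(record, "genome_record"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (rate == 0) return(record)
  bases <- strsplit(record$seq, "", fixed = TRUE)[[1L]]
  alphabet <- c("A", "C", "G", "T")
  new_bases <- with_seed(seed, {
    eligible <- bases %in% alphabet
    hit <- eligible & (stats::runif(length(bases)) < rate)
    if (any(hit)) {
      # Uniform over the three alternatives: offset the current base's index
      # by 1..3 (mod 4).
      cur <- match(bases[hit], alphabet)
      off <- sample.int(3L, sum(hit), replace = TRUE)
      bases[hit] <- alphabet[((cur - 1L + off) %% 4L) + 1L]
    }
    bases
  })
  genome_record(record$id, paste(new_bases, collapse = ""),
                record$description)
}

#' Write a fixture (FASTA plus JSON truth sidecar)
#'
#' @param pair A [make_assembly_pair()] result.
#' @param dir Output directory (created if missing).
#' @return Paths of the written files, invisibly.
#' @export
write_fixture <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa_ant <- file.path(dir, "antecedent.fa")
  fa_desc <- file.path(dir, "descendent.fa")
  sidecar <- file.path(dir, "truth.json")
  write_fasta(pair$antecedent, fa_ant)
  write_fasta(pair$descendent, fa_desc)
  jsonlite::write_json(
    list(truth = list(seq_id = pair$truth$seq_id, start = pair$truth$start,
                      end = pair$truth$end)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(fa_ant, fa_desc, sidecar))
}
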
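test_that("GGFM downsampling keeps every stride-th point plus endpoints", {
  tr <- random_circ_track(100, seed = 1)
  g1 <- build_ggfm(tr, stride = 1)
  expect_equal(nrow(g1$polylines[[1]]), 100)
  expect_equal(g1$panels[7], "X-Y-Z")
  expect_length(g1$panels, 7)

  g10 <- build_ggfm(tr, stride = 10)
  expect_equal(nrow(g10$polylines[[1]]), 11)  # 10 sampled + final point
  expect_equal(g10$polylines[[1]]$n, c(seq(1, 91, by = 10), 100))

  tr2 <- tr; tr2$seq_id <- "copy"
  gg <- build_ggfm(list(tr, tr2), stride = 5)
  expect_equal(gg$polylines[[1]][, -1], gg$polylines[[2]][, -1])

  expect_error(build_ggfm(tr, stride = 0), "stride")
})

test_that("contour grids bin conservatively and match a brute-force mean", {
  hp <- circularise(compute_track("AAAAAA"))
  cg <- contour_grid(hp, bin_count = 8)
  expect_equal(cg$bin_count, 1L)  # degenerate cloud collapses to one cell
  expect_equal(cg$cells[1, 1], 0)
  expect_equal(sum(cg$counts), hp$n_points)

  tr <- random_circ_track(1000, seed = 14)
  grid <- contour_grid(tr, bin_count = 16)
  expect_equal(sum(grid$counts), tr$n_points)

  # Brute-force per-cell mean.
  ix <- findInterval(tr$coords[, "X"], grid$x_edges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(tr$coords[, "Y"], grid$y_edges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  for (cell in list(c(4, 7), c(8, 8), c(16, 1))) {
    members <- which(ix == cell[1] & iy == cell[2])
    if (length(members) == 0) {
      expect_true(is.na(grid$cells[cell[1], cell[2]]))
    } else {
      expect_equal(grid$cells[cell[1], cell[2]],
                   mean(tr$coords[members, "Z"]))
    }
  }
})

test_that("the detector is silent on uniform random sequence", {
  tr <- random_circ_track(200000, seed = 99)
  seg <- detect_bias_segments(tr)
  expect_equal(nrow(seg), 0)
  expect_error(detect_bias_segments(random_circ_track(5000, seed = 1),
                                    window = 10000), "window")
})

test_that("an inserted tandem block appears as a sharp straight line", {
  pair <- make_assembly_pair(seed = 7)  # (GAATG) x 10000 at 100001
  cg <- clean_ns(pair$descendent)
  tr <- circularise(compute_track(cg))
  seg <- detect_bias_segments(tr, cleaned = cg)
  xseg <- seg[seg$axis == "X", ]
  expect_equal(nrow(xseg), 1)
  expect_lte(abs(xseg$start_cleaned - pair$truth$start), 2000)
  expect_lte(abs(xseg$end_cleaned - pair$truth$end), 2000)
  # GAATG steps +3 in X per 5 bases; circularisation subtracts the global
  # trend, so the detected slope is 0.6 minus roughly 50k*0.6/250k.
  expect_gt(xseg$slope, 0.4)
  expect_lt(xseg$slope, 0.6)
  expect_gt(xseg$r2, 0.98)

  # The same insert drifts Y at -1 per 5 bases: visible at a laxer slope cut.
  yseg <- detect_bias_segments(tr, cleaned = cg, min_abs_slope = 0.1)
  yseg <- yseg[yseg$axis == "Y", ]
  expect_equal(nrow(yseg), 1)
  expect_lt(yseg$slope, 0)
  expect_lte(abs(yseg$start_cleaned - pair$truth$start), 2000)
})

test_that("plot downsampling never changes detection results", {
  pair <- make_assembly_pair(seed = 15)
  tr <- circularise(compute_track(clean_ns(pair$descendent)))
  before <- detect_bias_segments(tr)
  invisible(build_ggfm(tr, stride = 100))
  expect_identical(detect_bias_segments(tr), before)
})

test_that("pred_delete excises an interval with full provenance", {
  cg <- clean_ns(genome_record("x", "ACGTACGT"))
  out <- pred_delete(cg, genome_interval("x", 3, 6))
  expect_equal(out$record$seq, "ACGT")
  expect_length(out$deletions, 1)
  expect_equal(out$deletions[[1]]$seq, "GTAC")
  expect_equal(out$ledger$cleaned_length + sum(out$ledger$gaps$length),
               out$ledger$original_length)

  expect_error(pred_delete(cg, genome_interval("x", 1, 8)), "empty")
  expect_error(pred_delete(cg, genome_interval("x", 5, 9)), "range")

  # Deleting across an N gap absorbs it into one ledger entry.
  cgn <- clean_ns(genome_record("x", "ACGNNNTACGT"))
  outn <- pred_delete(cgn, genome_interval("x", 3, 6))  # cleaned GTAC
  expect_equal(outn$record$seq, "ACGT")
  pred <- outn$ledger$gaps[outn$ledger$gaps$kind == "pred", ]
  expect_equal(nrow(pred), 1)
  expect_equal(c(pred$start, pred$end), c(3, 9))
  expect_equal(outn$ledger$cleaned_length, 4)
})

test_that("detect then delete rescues the landscape of an assembly pair", {
  pair <- make_assembly_pair(seed = 23)
  cg <- clean_ns(pair$descendent)
  tr <- circularise(compute_track(cg))
  seg <- detect_bias_segments(tr, cleaned = cg)
  best <- seg[which.max(seg$length), ]
  reass <- pred_delete(cg, genome_interval("descendent", best$start_cleaned,
                                           best$end_cleaned))
  s_ant <- fingerprint(pair$antecedent)
  s_desc <- summarise_track(tr)
  s_reass <- summarise_track(circularise(compute_track(reass)))
  d_before <- combined_distance(s_ant, s_desc)
  d_after <- combined_distance(s_ant, s_reass)
  expect_gt(d_before, 0)
  expect_lt(d_after, 0.05 * d_before)
})

test_that("map rendering writes one deterministic file per panel", {
  tr1 <- random_circ_track(400, seed = 31)
  tr2 <- random_circ_track(400, seed = 32)
  tr2$seq_id <- "g2"
  gg <- build_ggfm(list(tr1, tr2), stride = 2)
  d1 <- file.path(tempdir(), "maps1")
  paths <- render_maps(gg, d1, format = "svg")
  expect_length(paths, 7)
  expect_true(all(file.exists(paths)))

  d2 <- file.path(tempdir(), "maps2")
  paths2 <- render_maps(gg, d2, format = "svg")
  expect_equal(unname(tools::md5sum(paths)), unname(tools::md5sum(paths2)))

  cp <- render_maps(contour_grid(tr1, bin_count = 16),
                    file.path(tempdir(), "maps3"), format = "png")
  expect_true(file.exists(cp))

  empty <- structure(list(polylines = list(), panels = character(0)),
                     class = "ggfm")
  expect_error(render_maps(empty, tempdir()), "empty")
  expect_error(render_maps(gg, tempdir(), format = "tiff"))
})

test_that("segment reports export as TSV and BED", {
  pair <- make_assembly_pair(seed = 7)
  cg <- clean_ns(pair$descendent)
  seg <- detect_bias_segments(circularise(compute_track(cg)), cleaned = cg)
  tsv <- tempfile(fileext = ".tsv")
  write_segments_tsv(seg, tsv)
  back <- read.delim(tsv)
  expect_equal(back$start_cleaned, seg$start_cleaned)

  bed <- tempfile(fileext = ".bed")
  write_segments_bed(seg, bed, seq_id = "descendent")
  fields <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.numeric(fields[2]), seg$start_original[1] - 1)
  expect_equal(as.numeric(fields[3]), seg$end_original[1])
})
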